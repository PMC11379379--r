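# Mutation catalogues are tibbles with one row per mutation event:
#   strain_id, chrom, pos (1-based), ref, alt, variant_class, impact,
#   depth, allele_freq
# plus attributes n_strains (cohort size, which may exceed the number of
# strains with retained events) and batch_label.

IMPACT_LEVELS <- c("missense", "stop_gain", "splicing", "inframe",
                   "synonymous", "intergenic", "other")
HIGH_IMPACT <- c("stop_gain", "splicing", "missense")

#' Assemble a mutation dataset
#'
#' Validates a per-event table and attaches cohort metadata. Most users get
#' these from [read_mutations()] or the simulators; this constructor is for
#' records built in code.
#'
#' @param records Data frame with columns `strain_id`, `chrom`, `pos`,
#'   `ref`, `alt`; optional `impact`, `depth`, `allele_freq`.
#' @param n_strains Number of strains in the cohort. Defaults to the number
#'   of distinct `strain_id` values. Strains without retained events are
#'   legitimate, so pass the true cohort size when you know it.
#' @param batch_label Free-text batch identifier.
#' @param genome Optional [ems_genome()] used to validate positions and
#'   reference bases; mismatches raise an error naming the record.
#' @return A tibble of class `ems_mutations`.
#' @export
mutation_dataset <- function(records, n_strains = NULL, batch_label = NULL,
                             genome = NULL) {
  records <- as_tibble(records)
  need <- c("strain_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("missing columns: ", toString(miss)))
  records <- records |>
    mutate(
      strain_id = as.character(strain_id),
      chrom = as.character(chrom),
      pos = as.integer(pos),
      ref = toupper(as.character(ref)),
      alt = toupper(as.character(alt))
    )
  if (!"impact" %in% names(records)) records$impact <- NA_character_
  if (!"depth" %in% names(records)) records$depth <- NA_real_
  if (!"allele_freq" %in% names(records)) records$allele_freq <- NA_real_
  records <- records |>
    mutate(variant_class = if_else(
      nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T"),
      "SNV", "InDel"
    )) |>
    select(strain_id, chrom, pos, ref, alt, variant_class, impact,
           depth, allele_freq)
  if (!is.null(genome)) validate_against_genome(records, genome)
  n_obs <- n_distinct(records$strain_id)
  n_strains <- n_strains %||% n_obs
  if (n_strains < 1L) abort("n_strains must be >= 1")
  if (n_obs > n_strains) {
    abort("more distinct strain ids than n_strains")
  }
  structure(records,
            class = c("ems_mutations", class(records)),
            n_strains = as.integer(n_strains),
            batch_label = batch_label)
}

validate_against_genome <- function(records, genome) {
  lens <- chrom_lengths(genome)
  bad_chr <- setdiff(unique(records$chrom), names(lens))
  if (length(bad_chr)) {
    abort(paste0("chromosome not in genome: ", bad_chr[1]))
  }
  over <- records$pos < 1L | records$pos > lens[records$chrom]
  if (any(over)) {
    i <- which(over)[1]
    abort(sprintf("record %s %s:%d beyond chromosome length",
                  records$strain_id[i], records$chrom[i], records$pos[i]))
  }
  snv <- records$variant_class == "SNV"
  if (any(snv)) {
    at <- substring(genome$chromosomes[records$chrom[snv]],
                    records$pos[snv], records$pos[snv])
    mism <- at != records$ref[snv] & at != "N"
    if (any(mism)) {
      i <- which(snv)[which(mism)[1]]
      abort(sprintf("record %s %s:%d ref %s does not match genome (%s)",
                    records$strain_id[i], records$chrom[i], records$pos[i],
                    records$ref[i], at[which(mism)[1]]))
    }
  }
  invisible(records)
}

#' Cohort size of a mutation dataset
#' @param x An `ems_mutations` tibble (or any object with an `n_strains`
#'   attribute).
#' @return Integer cohort size.
#' @export
n_strains <- function(x) {
  n <- attr(x, "n_strains", exact = TRUE)
  if (is.null(n)) n <- n_distinct(x$strain_id)
  as.integer(n)
}

normalize_impact <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    is.na(x0) | x0 == "" ~ NA_character_,
    grepl("missense", x0) ~ "missense",
    grepl("stop.?gain|nonsense", x0) ~ "stop_gain",
    grepl("splic", x0) ~ "splicing",
    grepl("inframe", x0) ~ "inframe",
    grepl("synonymous|silent", x0) ~ "synonymous",
    grepl("intergenic", x0) ~ "intergenic",
    x0 %in% IMPACT_LEVELS ~ x0,
    TRUE ~ "other"
  )
  unk <- !is.na(x0) & out == "other" & !(x0 %in% IMPACT_LEVELS)
  if (any(unk)) {
    inform(paste0(sum(unk), " impact annotation(s) not recognized; ",
                  "kept as class 'other' (e.g. '", x0[unk][1], "')"))
  }
  out
}

#' Read mutation catalogues (MMP-style TSV or per-strain VCF)
#'
#' For VCF input, records must carry read depth (`DP`) and alternate allele
#' frequency (`AF`) in INFO; records failing `depth > min_depth` or
#' `allele_freq > min_af` (strict inequalities) are dropped, as are records
#' with missing DP/AF (with a warning). MMP-style TSV catalogues are treated
#' as already curated and pass through unfiltered.
#'
#' @param path One file (TSV) or a character vector of files (one VCF per
#'   strain).
#' @param format `"mmp_tsv"` or `"vcf"`.
#' @param min_depth Depth threshold; retained records need `depth > min_depth`.
#' @param min_af Allele-frequency threshold; retained records need
#'   `allele_freq > min_af`.
#' @param genome Optional [ems_genome()] for validation.
#' @param n_strains,batch_label Cohort metadata, see [mutation_dataset()].
#' @return An `ems_mutations` tibble.
#' @export
read_mutations <- function(path, format = c("mmp_tsv", "vcf"),
                           min_depth = 5, min_af = 0.8,
                           genome = NULL, n_strains = NULL,
                           batch_label = NULL) {
  format <- match.arg(format)
  if (format == "mmp_tsv") {
    rec <- read_mmp_tsv(path)
  } else {
    rec <- purrr::map(path, read_strain_vcf) |> list_rbind()
    no_meta <- is.na(rec$depth) | is.na(rec$allele_freq)
    if (any(no_meta)) {
      warn(paste0(sum(no_meta),
                  " VCF record(s) missing DP/AF dropped (filter unverifiable)"))
      rec <- rec[!no_meta, , drop = FALSE]
    }
    rec <- filter(rec, depth > min_depth, allele_freq > min_af)
  }
  mutation_dataset(rec, n_strains = n_strains, batch_label = batch_label,
                   genome = genome)
}

read_mmp_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("strain", tolower(first)) || grepl("pos", tolower(first))
  cols <- c("strain_id", "chrom", "pos", "ref", "alt", "impact")
  tab <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE)
  if (has_header) {
    names(tab) <- tolower(names(tab))
    names(tab)[names(tab) %in% c("strain", "sample")] <- "strain_id"
    names(tab)[names(tab) %in% c("chromosome", "chr")] <- "chrom"
    names(tab)[names(tab) %in% c("position")] <- "pos"
    names(tab)[names(tab) %in% c("annotation", "effect")] <- "impact"
  } else {
    names(tab) <- cols[seq_len(ncol(tab))]
  }
  if (!"impact" %in% names(tab)) tab$impact <- NA_character_
  tab$impact <- normalize_impact(tab$impact)
  tab[, intersect(cols, names(tab))]
}

read_strain_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  strain <- NULL
  if (ncol(v@gt) >= 2L) strain <- colnames(v@gt)[2]
  if (is.null(strain) || !nzchar(strain)) {
    strain <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  tibble(
    strain_id = strain,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    depth = dp,
    allele_freq = af
  )
}

#' Apply the depth / allele-frequency quality filter
#'
#' Strict inequalities on both thresholds, matching the curation rule for
#' screen WGS calls. Records with missing depth or allele frequency are
#' dropped with a warning.
#'
#' @param muts An `ems_mutations` tibble with `depth` and `allele_freq`.
#' @param min_depth,min_af Thresholds (`depth > min_depth`,
#'   `allele_freq > min_af`).
#' @return Filtered `ems_mutations` tibble (cohort metadata preserved).
#' @export
filter_variants <- function(muts, min_depth = 5, min_af = 0.8) {
  n0 <- n_strains(muts)
  bl <- attr(muts, "batch_label", exact = TRUE)
  no_meta <- is.na(muts$depth) | is.na(muts$allele_freq)
  if (any(no_meta)) {
    warn(paste0(sum(no_meta), " record(s) missing depth/AF dropped"))
  }
  keep <- !no_meta & muts$depth > min_depth & muts$allele_freq > min_af
  mutation_dataset(muts[keep, , drop = FALSE], n_strains = n0,
                   batch_label = bl)
}

#' Write a cohort as an MMP-style TSV
#' @param muts An `ems_mutations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mmp_tsv <- function(muts, path) {
  out <- muts |>
    transmute(strain = strain_id, chrom, pos, ref, alt,
              annotation = if_else(is.na(impact), "", impact))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a cohort as one minimal VCF per strain
#'
#' Emits uncompressed VCF 4.2 with `DP` and `AF` INFO fields, one file per
#' strain, named `<strain>.vcf`.
#'
#' @param muts An `ems_mutations` tibble. Missing depth/AF default to 20/1.0.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_strain_vcfs <- function(muts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- muts |>
    mutate(depth = if_else(is.na(depth), 20, depth),
           allele_freq = if_else(is.na(allele_freq), 1, allele_freq)) |>
    group_by(strain_id) |>
    group_map(function(df, key) {
      p <- file.path(dir, paste0(key$strain_id, ".vcf"))
      hdr <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               key$strain_id)
      )
      df <- arrange(df, chrom, pos)
      body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f\tGT\t1/1",
                      df$chrom, df$pos, df$ref, df$alt,
                      as.integer(round(df$depth)), df$allele_freq)
      writeLines(c(hdr, body), p)
      p
    }) |>
    unlist()
  invisible(paths)
}

#' @export
print.ems_mutations <- function(x, ...) {
  cat("<ems_mutations> ", nrow(x), " event(s), cohort of ", n_strains(x),
      " strain(s)", sep = "")
  bl <- attr(x, "batch_label", exact = TRUE)
  if (!is.null(bl)) cat(" [", bl, "]", sep = "")
  cat("\n")
  NextMethod()
}
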