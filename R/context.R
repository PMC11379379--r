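# Five-base sequence-context model of EMS mutability. The context table
# records, for every 5-mer w on the reference forward strand:
#   C0      occurrences of w in the genome (N-free, away from edges)
#   C_prime mutation events in the training cohort centered on w
#   P0      C_prime / C0, the per-cohort event frequency of w
# Complementary patterns are deliberately NOT collapsed: all four central
# bases are modeled and e.g. AGGGG and CCCCT are separate rows.

#' Count 5-mer occurrences in a genome
#'
#' Every position whose centered 5-base window lies within the chromosome
#' and contains no N contributes one count to its forward-strand pattern.
#'
#' @param genome An [ems_genome()].
#' @return Tibble with columns `pattern` (all 1024 5-mers) and `C0`.
#' @export
count_genome_patterns <- function(genome) {
  dss <- Biostrings::DNAStringSet(unname(genome$chromosomes))
  cnt <- Biostrings::oligonucleotideFrequency(dss, width = 5L, step = 1L)
  tot <- colSums(cnt)
  tibble(pattern = names(tot), C0 = as.integer(tot)) |>
    arrange(pattern)
}

# 5-mer window strings around SNV positions; NA where window is invalid
snv_windows <- function(genome, snvs) {
  lens <- chrom_lengths(genome)
  bad <- setdiff(unique(snvs$chrom), names(lens))
  if (length(bad)) {
    abort(paste0("catalogue chromosome not in genome: ", bad[1]))
  }
  ok <- snvs$pos >= 3L & snvs$pos <= lens[snvs$chrom] - 2L
  w <- rep(NA_character_, nrow(snvs))
  w[ok] <- substring(genome$chromosomes[snvs$chrom[ok]],
                     snvs$pos[ok] - 2L, snvs$pos[ok] + 2L)
  w[!is.na(w) & grepl("N", w)] <- NA_character_
  w
}

#' Estimate the baseline context table P0 = C'/C0
#'
#' Accumulates mutation events per centered 5-mer over the whole training
#' cohort. InDels and SNVs whose window touches a chromosome edge or an N
#' are excluded from `C_prime` and reported in the `skipped_events`
#' attribute. Recurrent events (the same site mutated in several strains)
#' contribute once per event. P0 is an event frequency over the cohort; the
#' per-strain baseline is `P0 / n_strains`.
#'
#' @param genome An [ems_genome()].
#' @param training An `ems_mutations` training catalogue validated against
#'   `genome`.
#' @return Tibble of class `ems_context` with columns `pattern`, `C0`,
#'   `C_prime`, `P0` (NA for patterns absent from the genome), and
#'   attributes `n_strains` and `skipped_events`.
#' @export
compute_p0 <- function(genome, training) {
  c0 <- count_genome_patterns(genome)
  snvs <- training[training$variant_class == "SNV", , drop = FALSE]
  n_indel <- nrow(training) - nrow(snvs)
  w <- snv_windows(genome, snvs)
  skipped <- n_indel + sum(is.na(w))
  if (skipped > 0) {
    inform(paste0(skipped, " event(s) excluded from context counting (",
                  n_indel, " InDel, ", sum(is.na(w)),
                  " edge/N-window SNV)"))
  }
  cp <- table(w[!is.na(w)])
  tab <- c0 |>
    mutate(C_prime = as.integer(cp[pattern]),
           C_prime = if_else(is.na(C_prime), 0L, C_prime))
  bad <- tab$C0 == 0L & tab$C_prime > 0L
  if (any(bad)) {
    abort(paste0("pattern ", tab$pattern[bad][1],
                 " has mutation events but no genomic occurrence; ",
                 "catalogue inconsistent with genome"))
  }
  tab <- mutate(tab, P0 = if_else(C0 > 0L, C_prime / C0, NA_real_))
  structure(tab,
            class = c("ems_context", class(tab)),
            n_strains = n_strains(training),
            skipped_events = skipped)
}

# marginal event rate per central base: sum C' / sum C0 (plus the overall
# rate under "N", used when the central base itself is unknown)
central_base_marginal <- function(table) {
  cen <- substring(table$pattern, 3L, 3L)
  agg <- tibble(central = cen, C0 = table$C0, C_prime = table$C_prime) |>
    group_by(central) |>
    summarise(rate = sum(C_prime) / sum(C0), .groups = "drop")
  out <- setNames(agg$rate, agg$central)
  out["N"] <- sum(table$C_prime) / sum(table$C0)
  out
}

#' Expand a context table to a per-base baseline track
#'
#' Every base receives the P0 of its centered 5-mer. Bases at chromosome
#' edges, in N windows, or whose pattern has no genomic occurrence in the
#' table fall back to the marginal rate of their central base (the overall
#' rate for N bases) and are flagged.
#'
#' @param genome An [ems_genome()] compatible with `table`.
#' @param table An `ems_context` from [compute_p0()].
#' @return An `ems_p0_track`: list with per-chromosome `values` (cohort-scale
#'   P0) and logical `flags`, plus attribute `n_strains` inherited from the
#'   table.
#' @export
p0_track <- function(genome, table) {
  stopifnot(inherits(table, "ems_context"))
  lookup <- rep(NA_real_, 1024L)
  ord <- all_kmers5()
  lookup[match(table$pattern, ord)] <- table$P0
  marg <- central_base_marginal(table)
  values <- list(); flags <- list()
  for (nm in names(genome$chromosomes)) {
    code <- base_codes(genome$chromosomes[[nm]])
    idx <- kmer_index5(code)
    p <- lookup[idx + 1]
    fl <- is.na(p)
    if (any(fl)) {
      cen <- c("A", "C", "G", "T")[code[fl] + 1L]
      cen[is.na(cen)] <- "N"
      p[fl] <- marg[cen]
    }
    values[[nm]] <- unname(p)
    flags[[nm]] <- fl
  }
  structure(list(values = values, flags = flags),
            class = "ems_p0_track",
            n_strains = attr(table, "n_strains", exact = TRUE))
}

#' @export
print.ems_p0_track <- function(x, ...) {
  cat("<ems_p0_track> ", length(x$values), " chromosome(s), ",
      format(sum(lengths(x$values)), big.mark = ","), " bp (",
      sum(vapply(x$flags, sum, numeric(1))), " flagged fallback base(s))\n",
      sep = "")
  invisible(x)
}

#' Chi-square test of flanking-base composition around mutated sites
#'
#' For a central base and flanking offset, compares the base composition
#' observed at that offset around mutated sites against the genome-wide
#' composition at the same offset around all sites of that base (scaled to
#' the observed total). Pearson chi-square, df = 3, no continuity
#' correction. A systematic shift indicates that the mutagen's efficacy
#' depends on the flanking sequence.
#'
#' @param genome An [ems_genome()].
#' @param training An `ems_mutations` catalogue.
#' @param central_base One of `A`, `C`, `G`, `T`.
#' @param offsets Integer offsets in -4..4 excluding 0 (vectorized).
#' @return Tibble with one row per offset: `central_base`, `offset`, `chi2`,
#'   `df`, `p_value`, and list columns `observed` / `expected` (named counts
#'   for A, C, G, T at that offset).
#' @export
flanking_chisq <- function(genome, training, central_base,
                           offsets = setdiff(-4:4, 0L)) {
  stopifnot(central_base %in% c("A", "C", "G", "T"))
  offsets <- as.integer(offsets)
  if (any(offsets == 0L) || any(abs(offsets) > 4L)) {
    abort("offsets must lie in -4..4, excluding 0")
  }
  snvs <- training[training$variant_class == "SNV" &
                     training$ref == central_base, , drop = FALSE]
  if (nrow(snvs) == 0L) {
    abort(paste0("no SNV events with central base ", central_base))
  }
  codes <- lapply(genome$chromosomes, base_codes)
  target <- match(central_base, c("A", "C", "G", "T")) - 1L
  rows <- lapply(offsets, function(off) {
    # genome-wide composition at this offset around all sites of the base
    exp_counts <- numeric(4)
    for (nm in names(codes)) {
      code <- codes[[nm]]
      at <- which(code == target)
      at <- at[at + off >= 1L & at + off <= length(code)]
      nb <- code[at + off]
      exp_counts <- exp_counts + tabulate(nb + 1L, nbins = 4L)
    }
    # observed composition around mutated sites
    lens <- chrom_lengths(genome)
    ok <- snvs$pos + off >= 1L & snvs$pos + off <= lens[snvs$chrom]
    obs_base <- substring(genome$chromosomes[snvs$chrom[ok]],
                          snvs$pos[ok] + off, snvs$pos[ok] + off)
    obs_counts <- tabulate(match(obs_base, c("A", "C", "G", "T")), nbins = 4L)
    if (any(exp_counts == 0)) {
      abort(paste0("expected cell is zero at offset ", off,
                   " for central base ", central_base))
    }
    expected <- exp_counts / sum(exp_counts) * sum(obs_counts)
    chi2 <- sum((obs_counts - expected)^2 / expected)
    tibble(
      central_base = central_base, offset = off,
      chi2 = chi2, df = 3L,
      p_value = pchisq(chi2, df = 3L, lower.tail = FALSE),
      observed = list(setNames(obs_counts, c("A", "C", "G", "T"))),
      expected = list(setNames(expected, c("A", "C", "G", "T")))
    )
  })
  list_rbind(rows)
}

#' @export
print.ems_context <- function(x, ...) {
  cat("<ems_context> 5-mer context table; cohort of ",
      attr(x, "n_strains", exact = TRUE), " strain(s), ",
      sum(x$C_prime), " event(s) counted, ",
      attr(x, "skipped_events", exact = TRUE) %||% 0L, " skipped\n", sep = "")
  NextMethod()
}
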