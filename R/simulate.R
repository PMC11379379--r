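# Synthetic-data generator: toy genomes, chromatin-like signal tracks, a
# ground-truth per-base mutation probability field (sequence context x
# chromatin factor), Bernoulli-mutagenized cohorts and phenotype-selected
# screen pools. Everything regenerates bitwise-identically from a seed, so
# the whole pipeline is testable without external downloads.
#
# Default geometry mirrors a desk-scale worm experiment: 2 Mb genome, 36%
# GC, 4 tracks, 300 strains at a mean of 3.6e-6 events per base per strain
# (~360 events per 100 Mb genome, so ~2,000 events over 2 Mb x 300 strains).

BASES <- c("A", "C", "G", "T")

#' Generate a random toy genome
#'
#' i.i.d. bases at the stated GC fraction.
#'
#' @param length Total genome length in bp (>= 1000), split evenly across
#'   chromosomes.
#' @param n_chroms Number of chromosomes.
#' @param gc_frac GC fraction in (0, 1); default 0.36 (worm-like).
#' @param seed Integer seed; the same seed regenerates the same genome.
#' @return An [ems_genome()].
#' @export
make_genome <- function(length = 2e6, n_chroms = 1L, gc_frac = 0.36,
                        seed = 1L) {
  if (length < 1000) abort("genome length must be >= 1000")
  if (gc_frac <= 0 || gc_frac >= 1) abort("gc_frac must be in (0,1)")
  per <- diff(floor(seq(0, length, length.out = n_chroms + 1L)))
  probs <- c((1 - gc_frac) / 2, gc_frac / 2, gc_frac / 2, (1 - gc_frac) / 2)
  seqs <- withr::with_seed(seed, {
    lapply(per, function(L) {
      paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
    })
  })
  names(seqs) <- paste0("chr", utils::as.roman(seq_len(n_chroms)))
  ems_genome(seqs)
}

#' Pick chromatin 'silent regions' for a synthetic genome
#'
#' Intervals in which track signal (and hence the true mutation
#' probability) is strongly depressed, emulating inaccessible chromatin.
#'
#' @param genome An [ems_genome()].
#' @param n_per_chrom Silent intervals per chromosome.
#' @param frac Fraction of each chromosome covered by each interval.
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
make_silent_regions <- function(genome, n_per_chrom = 1L, frac = 0.1,
                                seed = 1L) {
  lens <- chrom_lengths(genome)
  withr::with_seed(seed, {
    imap(as.list(lens), function(L, nm) {
      w <- max(1L, floor(frac * L))
      start <- sort(sample.int(L - w, n_per_chrom))
      tibble(chrom = nm, start = start, end = start + w - 1L)
    }) |> list_rbind()
  })
}

#' Generate chromatin-like signal tracks
#'
#' Each track is a log-normal transform of a smooth random field (cubic
#' spline through i.i.d. knots every `knot_spacing` bp), damped inside the
#' silent regions - long-wavelength structure of the kind DNA-binding
#' protein occupancy shows.
#'
#' @param genome An [ems_genome()].
#' @param n_tracks Number of tracks (default 4).
#' @param knot_spacing Spacing of the random-field knots in bp.
#' @param silent_regions Optional tibble from [make_silent_regions()].
#' @param damping Multiplier applied inside silent regions (default 0.05).
#' @param seed Integer seed.
#' @return List of raw (unsmoothed) `ems_track` objects named
#'   `track01`, `track02`, ...
#' @export
make_tracks <- function(genome, n_tracks = 4L, knot_spacing = 25000L,
                        silent_regions = NULL, damping = 0.05, seed = 1L) {
  lens <- chrom_lengths(genome)
  withr::with_seed(seed, {
    lapply(seq_len(n_tracks), function(k) {
      values <- imap(as.list(lens), function(L, nm) {
        kn <- unique(c(seq(1L, L, by = knot_spacing), L))
        z <- rnorm(length(kn))
        zz <- spline(kn, z, xout = seq_len(L))$y
        v <- exp(0.6 * zz)
        if (!is.null(silent_regions)) {
          sr <- silent_regions[silent_regions$chrom == nm, , drop = FALSE]
          for (i in seq_len(nrow(sr))) {
            v[sr$start[i]:sr$end[i]] <- v[sr$start[i]:sr$end[i]] * damping
          }
        }
        v
      })
      signal_track(values, feature_name = sprintf("track%02d", k))
    })
  })
}

#' Random 5-mer context multipliers
#'
#' Assigns each 5-mer a mutability multiplier: a log-uniform spread of
#' roughly `spread`-fold between the most and least mutable patterns, with
#' G/C-centered patterns boosted `gc_bias`-fold (the mutagen alkylates
#' guanine, so G/C sites dominate the spectrum).
#'
#' @param spread Approximate fold range of multipliers within a central
#'   base class (default 10).
#' @param gc_bias Multiplier applied to G/C-centered patterns (default 4).
#' @param seed Integer seed.
#' @return Tibble with `pattern` and `multiplier` (unnormalized; the truth
#'   builder rescales to genome mean 1).
#' @export
default_context_effects <- function(spread = 10, gc_bias = 4, seed = 1L) {
  pat <- all_kmers5()
  central <- substring(pat, 3L, 3L)
  half <- log(spread) / 2
  mult <- withr::with_seed(seed, exp(runif(length(pat), -half, half)))
  mult <- mult * ifelse(central %in% c("C", "G"), gc_bias, 1)
  tibble(pattern = pat, multiplier = mult)
}

#' Assemble the ground-truth mutation probability field
#'
#' `true_p = base_rate x context_multiplier x chromatin_factor`, where the
#' chromatin factor is the per-base mean of the (mean-1 normalized) tracks
#' raised to `chromatin_exponent` and renormalized to mean 1, and the
#' context multipliers are rescaled so their genome-wide mean is 1. The
#' genome-wide mean of `true_p` is therefore `base_rate` up to the
#' (small) correlation between the two factors.
#'
#' @param genome An [ems_genome()].
#' @param tracks Raw tracks from [make_tracks()].
#' @param context_effects Tibble `pattern`/`multiplier`; default
#'   [default_context_effects()].
#' @param base_rate Target mean per-base per-strain event probability
#'   (default 3.6e-6, i.e. ~360 events per strain on a 100 Mb genome).
#' @param chromatin_exponent Exponent sharpening the chromatin factor
#'   (default 1.5).
#' @param silent_regions Optional tibble of intervals (the ones the tracks
#'   were damped in); inside them the chromatin factor is pinned to
#'   `silent_factor`, guaranteeing silent-region truth below 0.1 x the base
#'   rate for every context class.
#' @param silent_factor Chromatin factor inside silent regions (default
#'   0.01).
#' @param seed Integer seed recorded in the truth object.
#' @return An `ems_truth`: list with `genome`, `tracks`, `true_p` (named
#'   per-chromosome list), `context_effects` (rescaled), `chromatin_effect`
#'   parameters, `base_rate`, `seed`.
#' @export
make_truth <- function(genome, tracks, context_effects = NULL,
                       base_rate = 3.6e-6, chromatin_exponent = 1.5,
                       silent_regions = NULL, silent_factor = 0.01,
                       seed = 1L) {
  context_effects <- context_effects %||% default_context_effects(seed = seed)
  lookup <- rep(NA_real_, 1024L)
  lookup[match(context_effects$pattern, all_kmers5())] <-
    context_effects$multiplier

  lens <- chrom_lengths(genome)
  mult <- imap(as.list(lens), function(L, nm) {
    idx <- kmer_index5(base_codes(genome$chromosomes[[nm]]))
    m <- lookup[idx + 1]
    m[is.na(m)] <- 1  # edge / N windows sit at the baseline class
    m
  })
  # rescale context multipliers to genome-wide mean 1
  msc <- mean(unlist(mult, use.names = FALSE))
  mult <- lapply(mult, function(m) m / msc)
  context_effects$multiplier <- context_effects$multiplier / msc

  tr_means <- lapply(tracks, function(t) {
    mean(unlist(t$values, use.names = FALSE))
  })
  factor <- imap(as.list(lens), function(L, nm) {
    comb <- Reduce(`+`, map2(tracks, tr_means,
                             function(t, m) t$values[[nm]] / m)) /
      length(tracks)
    comb^chromatin_exponent
  })
  fsc <- mean(unlist(factor, use.names = FALSE))
  factor <- lapply(factor, function(f) f / fsc)
  if (!is.null(silent_regions)) {
    for (i in seq_len(nrow(silent_regions))) {
      nm <- silent_regions$chrom[i]
      span <- silent_regions$start[i]:silent_regions$end[i]
      factor[[nm]][span] <- silent_factor
    }
  }

  true_p <- map2(mult, factor, function(m, f) base_rate * m * f)
  if (any(unlist(true_p, use.names = FALSE) >= 1)) {
    abort("true_p reaches 1; lower base_rate")
  }
  structure(
    list(genome = genome, tracks = tracks, true_p = true_p,
         context_effects = context_effects,
         chromatin_effect = list(exponent = chromatin_exponent,
                                 normalization = fsc,
                                 silent_factor = if (is.null(silent_regions))
                                   NULL else silent_factor),
         silent_regions = silent_regions,
         base_rate = base_rate, seed = seed),
    class = "ems_truth"
  )
}

#' @export
print.ems_truth <- function(x, ...) {
  p <- unlist(x$true_p, use.names = FALSE)
  cat("<ems_truth> ", format(length(p), big.mark = ","), " bp, ",
      length(x$tracks), " track(s); mean true p = ",
      format(mean(p), digits = 4), " (base rate ",
      format(x$base_rate, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Wrap a truth's probability field as a probability map
#'
#' Useful as the oracle map in calibration experiments.
#'
#' @param truth An `ems_truth`.
#' @param alpha Effectiveness scalar.
#' @return An `ems_prob_map` over the truth's genome.
#' @export
truth_map <- function(truth, alpha = 1) {
  prob_map(lapply(truth$true_p, function(v) v * alpha), alpha = alpha,
           provenance = list(model = "synthetic_truth", seed = truth$seed))
}

#' Tile synthetic gene models over a genome
#'
#' @param genome An [ems_genome()].
#' @param gene_length Gene length in bp.
#' @param gap Intergenic gap in bp.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (strands alternate).
#' @export
make_genes <- function(genome, gene_length = 2000L, gap = 2000L) {
  lens <- chrom_lengths(genome)
  out <- imap(as.list(lens), function(L, nm) {
    starts <- seq(1L, L - gene_length + 1L, by = gene_length + gap)
    tibble(chrom = nm, start = as.integer(starts),
           end = as.integer(starts + gene_length - 1L))
  }) |> list_rbind()
  out |>
    mutate(gene_id = sprintf("gene%04d", row_number()),
           strand = rep_len(c("+", "-"), n())) |>
    select(gene_id, chrom, start, end, strand)
}

# EMS alternate-allele draw: G->A and C->T transitions with probability
# `bias`, otherwise uniform over the remaining bases; A/T refs uniform.
draw_alt <- function(ref, bias = 0.95) {
  vapply(ref, function(b) {
    others <- setdiff(BASES, b)
    trans <- switch(b, G = "A", C = "T", NA_character_)
    if (!is.na(trans) && runif(1) < bias) trans
    else sample(setdiff(others, trans), 1)
  }, character(1), USE.NAMES = FALSE)
}

# Bernoulli mutagenesis across a cohort: per-base event counts are
# Binomial(n_strains, p); given the count, the mutated strains are a
# uniform subset - exactly the independent per-strain Bernoulli model.
draw_cohort_events <- function(truth, n_strains, transition_bias = 0.95) {
  rows <- imap(truth$true_p, function(p, nm) {
    k <- rbinom(length(p), n_strains, p)
    at <- which(k > 0L)
    if (length(at) == 0L) return(NULL)
    pos <- rep(at, k[at])
    strain <- unlist(lapply(at, function(i) {
      sample.int(n_strains, k[i])
    }), use.names = FALSE)
    ref <- strsplit(substring(truth$genome$chromosomes[[nm]],
                              min(at), max(at)), "")[[1]][pos - min(at) + 1L]
    tibble(strain_id = sprintf("S%04d", strain), chrom = nm, pos = pos,
           ref = ref, alt = draw_alt(ref, transition_bias))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(tibble(strain_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character()))
  }
  list_rbind(rows)
}

#' Simulate a mutagenized cohort
#'
#' Independent Bernoulli(true_p) events per base per strain; alternate
#' alleles of mutated G/C bases are the canonical EMS transitions (G->A,
#' C->T) with probability `transition_bias`, otherwise uniform.
#'
#' @param truth An `ems_truth`.
#' @param n_strains Cohort size (>= 1).
#' @param transition_bias Probability of the G->A / C->T transition at G/C
#'   sites (default 0.95).
#' @param seed Integer seed.
#' @param batch_label Batch label stored on the dataset.
#' @return An `ems_mutations` cohort (impact annotations absent).
#' @export
simulate_cohort <- function(truth, n_strains = 300L, transition_bias = 0.95,
                            seed = 1L, batch_label = "synthetic_cohort") {
  if (n_strains < 1L) abort("n_strains must be >= 1")
  rec <- withr::with_seed(seed,
                          draw_cohort_events(truth, n_strains,
                                             transition_bias))
  mutation_dataset(rec, n_strains = n_strains, batch_label = batch_label,
                   genome = truth$genome)
}

#' Simulate a phenotype-selected screen pool
#'
#' Every selected strain carries exactly one implanted high-impact mutation
#' at a random position of the causal gene, on top of Bernoulli passenger
#' mutations drawn from the truth. Passengers are annotated as synonymous
#' (genic) or intergenic - selection acted on the causal gene only, so by
#' construction the high-impact hits in the causal gene are the implanted
#' ones. A configurable set of shared background variants is injected into
#' a fixed fraction of strains to exercise background removal.
#'
#' @param truth An `ems_truth`.
#' @param genes Gene models (tibble `gene_id`, `chrom`, `start`, `end`).
#' @param causal_gene `gene_id` of the causal gene, or `"auto"` to pick the
#'   gene with the highest summed truth probability (well outside silent
#'   chromatin).
#' @param n_selected Number of phenotype-selected strains (default 38).
#' @param high_impact_classes Classes the implanted hits are drawn from.
#' @param n_background Number of shared background variants injected.
#' @param background_share Fraction of strains carrying each background
#'   variant (default 0.5).
#' @param transition_bias See [simulate_cohort()].
#' @param seed Integer seed.
#' @return List with `pool` (an `ems_mutations` with impact annotations)
#'   and `causal_gene` (the gene id used).
#' @export
simulate_screen <- function(truth, genes, causal_gene = "auto",
                            n_selected = 38L,
                            high_impact_classes = c("stop_gain", "missense",
                                                    "splicing", "InDel"),
                            n_background = 5L, background_share = 0.5,
                            transition_bias = 0.95, seed = 1L) {
  genes <- as_tibble(genes)
  if (identical(causal_gene, "auto")) {
    tm <- truth_map(truth)
    psum <- genes |>
      group_by(gene_id) |>
      group_map(function(df, key) {
        tibble(gene_id = key$gene_id,
               p = seq_probability(tm, df[c("chrom", "start", "end")]))
      }) |> list_rbind()
    causal_gene <- psum$gene_id[which.max(psum$p)]
  }
  gi <- genes[genes$gene_id == causal_gene, , drop = FALSE]
  if (nrow(gi) == 0L) abort(paste0("gene not in annotation: ", causal_gene))

  withr::with_seed(seed, {
    # passengers: impacts are non-selective by construction
    pas <- draw_cohort_events(truth, n_selected, transition_bias)
    if (is.null(pas)) {
      pas <- tibble(strain_id = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character())
    }
    genic <- rep(FALSE, nrow(pas))
    if (nrow(pas)) {
      gr_rec <- GenomicRanges::GRanges(pas$chrom,
                                       IRanges::IRanges(pas$pos, pas$pos))
      gr_gen <- GenomicRanges::GRanges(genes$chrom,
                                       IRanges::IRanges(genes$start,
                                                        genes$end))
      genic <- IRanges::overlapsAny(gr_rec, gr_gen)
    }
    pas$impact <- ifelse(genic, "synonymous", "intergenic")
    pas$strain_id <- sprintf("sel%03d",
                             as.integer(sub("^S0*", "", pas$strain_id)))

    # one implanted high-impact causal hit per selected strain
    gene_pos <- unlist(lapply(seq_len(nrow(gi)), function(i) {
      gi$start[i]:gi$end[i]
    }), use.names = FALSE)
    hit_pos <- sample(gene_pos, n_selected, replace = TRUE)
    hit_cls <- sample(high_impact_classes, n_selected, replace = TRUE)
    hit_ref <- substring(truth$genome$chromosomes[[gi$chrom[1]]],
                         hit_pos, hit_pos)
    hit_alt <- ifelse(hit_cls == "InDel",
                      paste0(hit_ref,
                             sample(BASES, n_selected, replace = TRUE)),
                      draw_alt(hit_ref, transition_bias))
    hits <- tibble(
      strain_id = sprintf("sel%03d", seq_len(n_selected)),
      chrom = gi$chrom[1], pos = hit_pos, ref = hit_ref, alt = hit_alt,
      impact = ifelse(hit_cls == "InDel", NA_character_, hit_cls)
    )

    # shared background variants
    bg <- NULL
    if (n_background > 0L) {
      lens <- chrom_lengths(truth$genome)
      bchrom <- sample(names(lens), n_background, replace = TRUE)
      bpos <- vapply(bchrom, function(nm) sample.int(lens[[nm]], 1L),
                     integer(1), USE.NAMES = FALSE)
      bref <- substring(truth$genome$chromosomes[bchrom], bpos, bpos)
      balt <- draw_alt(bref, transition_bias)
      n_carrier <- max(2L, ceiling(background_share * n_selected))
      bg <- list_rbind(lapply(seq_len(n_background), function(i) {
        carriers <- sample.int(n_selected, n_carrier)
        tibble(strain_id = sprintf("sel%03d", carriers),
               chrom = bchrom[i], pos = bpos[i], ref = bref[i],
               alt = balt[i], impact = "other")
      }))
    }

    pool <- bind_rows(pas, hits, bg)
    list(
      pool = mutation_dataset(pool, n_strains = n_selected,
                              batch_label = "synthetic_screen",
                              genome = truth$genome),
      causal_gene = causal_gene
    )
  })
}

#' Write a synthetic study to standard file formats
#'
#' Emits `genome.fa`, one raw bedGraph per track, `genes.gff3`, the
#' cohort as `cohort.tsv` (MMP-style) and optional per-strain VCFs under
#' `vcf/`; everything re-ingests with the package readers.
#'
#' @param truth An `ems_truth`.
#' @param genes Gene models.
#' @param cohort An `ems_mutations` cohort.
#' @param dir Output directory (created).
#' @param vcf Also write per-strain VCFs (default FALSE).
#' @return Named list of written paths, invisibly.
#' @export
write_fixtures <- function(truth, genes, cohort, dir, vcf = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                genes = file.path(dir, "genes.gff3"),
                cohort = file.path(dir, "cohort.tsv"))
  write_fasta(truth$genome, paths$genome)
  write_gff3(genes, paths$genes)
  write_mmp_tsv(cohort, paths$cohort)
  paths$tracks <- vapply(truth$tracks, function(t) {
    p <- file.path(dir, paste0(t$feature_name, ".bedgraph"))
    write_bedgraph(t, p)
    p
  }, character(1))
  if (vcf) paths$vcfs <- write_strain_vcfs(cohort, file.path(dir, "vcf"))
  invisible(paths)
}
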