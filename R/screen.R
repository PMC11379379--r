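# Screen statistics: batch effectiveness normalization, binomial
# expectations over sequence intervals, background-variant removal, and the
# per-gene enrichment test that calls candidate causal genes.

#' Estimate batch mutagen effectiveness
#'
#' Mutagenesis strength drifts with mutagen concentration, developmental
#' stage and temperature. The correction is the ratio of per-strain mean
#' mutation counts: `alpha_1 = (N_bar_1 / N_bar_0) * alpha_0`, with the
#' training (baseline) cohort at `alpha_0 = 1` by convention.
#'
#' @param baseline Baseline cohort: an `ems_mutations` tibble, or directly
#'   the numeric per-strain mean event count.
#' @param batch Batch to analyze: an `ems_mutations` tibble or its numeric
#'   per-strain mean.
#' @param alpha_0 Baseline effectiveness (default 1).
#' @return One-row tibble with `n_bar_0`, `n_bar_1`, `alpha_0`, `alpha_1`.
#' @export
batch_effectiveness <- function(baseline, batch, alpha_0 = 1) {
  mean_of <- function(x, label) {
    if (is.numeric(x) && length(x) == 1L) return(as.numeric(x))
    if (nrow(x) == 0L) abort(paste0(label, " cohort has no events"))
    nrow(x) / n_strains(x)
  }
  n0 <- mean_of(baseline, "baseline")
  n1 <- mean_of(batch, "batch")
  if (n0 <= 0) abort("baseline mean must be positive")
  if (n1 <= 0) abort("batch cohort has no events")
  tibble(n_bar_0 = n0, n_bar_1 = n1, alpha_0 = alpha_0,
         alpha_1 = n1 / n0 * alpha_0)
}

# normalize interval input: tibble(chrom,start,end) (1-based inclusive)
as_intervals <- function(intervals, chrom = NULL, start = NULL, end = NULL) {
  if (is.null(intervals)) {
    return(tibble(chrom = chrom, start = as.integer(start),
                  end = as.integer(end)))
  }
  iv <- as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  iv |> transmute(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end))
}

# reduce to a disjoint union per chromosome
reduce_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv |>
    group_by(chrom) |>
    group_modify(function(df, key) {
      r <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    ungroup()
}

#' Summed mutation probability over a sequence
#'
#' `P_seq = sum of per-base P` over the (union of the) given intervals.
#'
#' @param map An `ems_prob_map`.
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive); overlapping intervals are unioned first.
#' @return Scalar `P_seq` (0 for an empty interval set).
#' @export
seq_probability <- function(map, intervals) {
  iv <- reduce_intervals(as_intervals(intervals))
  if (nrow(iv) == 0L) return(0)
  bad <- setdiff(unique(iv$chrom), names(map$values))
  if (length(bad)) abort(paste0("interval chromosome not in map: ", bad[1]))
  tot <- 0
  for (i in seq_len(nrow(iv))) {
    v <- map$values[[iv$chrom[i]]]
    if (iv$start[i] < 1L || iv$end[i] > length(v) ||
        iv$start[i] > iv$end[i]) {
      abort(sprintf("interval %s:%d-%d outside map",
                    iv$chrom[i], iv$start[i], iv$end[i]))
    }
    tot <- tot + sum(v[iv$start[i]:iv$end[i]])
  }
  tot
}

#' Expected mutation count over a sequence for a cohort
#'
#' Under independent per-base, per-strain Bernoulli(P) events,
#' `E(seq) = n_strains * P_seq`.
#'
#' @param map An `ems_prob_map`.
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @param n_strains Number of strains in the cohort (>= 1).
#' @return Scalar expected event count.
#' @export
expected_count <- function(map, intervals, n_strains) {
  if (n_strains < 1) abort("n_strains must be >= 1")
  n_strains * seq_probability(map, intervals)
}

#' Remove background variants shared across a screen pool
#'
#' Variants present in at least `share_frac` of the pool's strains (keyed on
#' chromosome, position and alternate allele) are pre-existing or clonal
#' rather than phenotype-linked, and are removed from every strain.
#'
#' @param pool An `ems_mutations` screen pool with >= 2 strains.
#' @param share_frac Fraction of strains at or above which a variant counts
#'   as background (default 0.25).
#' @return Filtered `ems_mutations` pool; the removed variant keys are kept
#'   in the `removed_background` attribute.
#' @export
remove_background <- function(pool, share_frac = 0.25) {
  n0 <- n_strains(pool)
  if (n0 < 2L) abort("background removal needs a pool of >= 2 strains")
  shared <- pool |>
    distinct(chrom, pos, alt, strain_id) |>
    count(chrom, pos, alt, name = "n_strain") |>
    filter(n_strain / n0 >= share_frac)
  kept <- anti_join(as_tibble(pool), shared, by = c("chrom", "pos", "alt"))
  if (nrow(shared)) {
    inform(paste0("removed ", nrow(shared), " background variant(s) (",
                  nrow(pool) - nrow(kept), " record(s)) shared by >= ",
                  format(share_frac * 100), "% of strains"))
  }
  out <- mutation_dataset(kept, n_strains = n0,
                          batch_label = attr(pool, "batch_label",
                                             exact = TRUE))
  attr(out, "removed_background") <- shared
  out
}

# exact Poisson-binomial count distribution: pmf of the number of successes
# of independent Bernoulli(p_i) trials, by direct convolution. The final
# bin absorbs all counts >= cap-1, which leaves both tails exact for any
# observed count below the cap.
poisson_binomial_pmf <- function(p, cap = 2000L) {
  pmf <- 1
  for (pi in p) {
    pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
    if (length(pmf) > cap) {
      pmf[cap] <- pmf[cap] + sum(pmf[(cap + 1L):length(pmf)])
      pmf <- pmf[seq_len(cap)]
    }
  }
  pmf
}

# two-sided p: double the smaller tail, capped at 1
two_sided_from_tails <- function(lower, upper) pmin(1, 2 * pmin(lower, upper))

count_pvalue_poisson <- function(obs, e, alternative) {
  lower <- ppois(obs, e)                       # P(X <= obs)
  upper <- ppois(obs - 1, e, lower.tail = FALSE)  # P(X >= obs)
  if (alternative == "greater") upper else two_sided_from_tails(lower, upper)
}

count_pvalue_exact <- function(obs, probs, alternative) {
  pmf <- poisson_binomial_pmf(probs)
  lower <- sum(pmf[seq_len(obs + 1L)])
  # the absorbing final bin keeps the full upper-tail mass, so summing the
  # bins above obs is exact and avoids 1-minus cancellation
  upper <- sum(pmf[(obs + 1L):length(pmf)])
  if (alternative == "greater") upper else two_sided_from_tails(lower, upper)
}

#' Per-gene enrichment of screen mutations over the probability map
#'
#' For every gene with at least one pooled mutation: observed = event count
#' within the gene's intervals across the pool; expected
#' `E = n_strains x P_seq x alpha`; p-value from the null that per-base,
#' per-strain events are independent Bernoulli(P) - computed from the
#' Poisson limit of the Poisson-binomial count by default, or by exact
#' Poisson-binomial convolution (`mode = "exact"`, small genes only).
#' Benjamini-Hochberg q-values are computed across tested genes. Genes
#' without observed mutations are reported but not tested.
#'
#' @param pool Background-removed `ems_mutations` screen pool.
#' @param genes Gene models: tibble with `gene_id`, `chrom`, `start`, `end`
#'   (one row per interval; intervals of a gene are unioned).
#' @param map An `ems_prob_map` (typically at the training batch scale).
#' @param alpha Additional effectiveness multiplier to apply on top of the
#'   map (use `alpha_1` from [batch_effectiveness()] when the map is at
#'   `alpha_0 = 1`).
#' @param n_strains Pool size; defaults to the pool attribute.
#' @param mode `"poisson"` (default) or `"exact"`.
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment
#'   only).
#' @param fdr FDR threshold used for the `significant` flag (default 0.05).
#' @return Tibble of class `ems_enrichment`, one row per gene, sorted by
#'   p-value: `gene_id`, `observed`, `expected`, `fold_change`, `p_value`,
#'   `q_value`, `significant`, `high_impact`, plus per-class impact counts.
#' @export
gene_enrichment <- function(pool, genes, map, alpha = 1, n_strains = NULL,
                            mode = c("poisson", "exact"),
                            alternative = c("two.sided", "greater"),
                            fdr = 0.05) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  n <- n_strains %||% n_strains(pool)
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  bad <- setdiff(unique(genes$chrom), names(map$values))
  if (length(bad)) abort(paste0("gene chromosome not in map: ", bad[1]))

  per_gene <- genes |>
    group_by(gene_id) |>
    group_map(function(df, key) {
      iv <- reduce_intervals(df[c("chrom", "start", "end")])
      e <- expected_count(map, iv, n) * alpha
      hits <- semi_join_events(pool, iv)
      obs <- nrow(hits)
      if (obs > 0L) {
        if (mode == "exact") {
          probs <- unlist(lapply(seq_len(nrow(iv)), function(i) {
            map$values[[iv$chrom[i]]][iv$start[i]:iv$end[i]]
          }))
          probs <- rep(pmin(probs * alpha, 1), n)
          if (length(probs) > 2e5) {
            abort("exact mode is for small genes; use mode = 'poisson'")
          }
          p <- count_pvalue_exact(obs, probs, alternative)
        } else {
          p <- count_pvalue_poisson(obs, e, alternative)
        }
      } else {
        p <- NA_real_
      }
      imp <- impact_counts(hits)
      tibble(gene_id = key$gene_id, observed = obs, expected = e,
             fold_change = obs / e, p_value = p) |>
        bind_cols(imp)
    }) |>
    list_rbind()

  per_gene <- per_gene |>
    mutate(q_value = {
      q <- rep(NA_real_, n())
      tested <- !is.na(p_value)
      q[tested] <- p.adjust(p_value[tested], method = "BH")
      q
    },
    significant = !is.na(q_value) & q_value <= fdr) |>
    relocate(q_value, significant, .after = p_value) |>
    arrange(p_value)

  structure(per_gene,
            class = c("ems_enrichment", class(per_gene)),
            n_strains = n, alpha = alpha, mode = mode,
            alternative = alternative, fdr = fdr)
}

# events of `pool` falling inside the (disjoint) interval set
semi_join_events <- function(pool, iv) {
  if (nrow(pool) == 0L || nrow(iv) == 0L) return(pool[0, , drop = FALSE])
  gr_rec <- GenomicRanges::GRanges(pool$chrom,
                                   IRanges::IRanges(pool$pos, pool$pos))
  gr_iv <- GenomicRanges::GRanges(iv$chrom,
                                  IRanges::IRanges(iv$start, iv$end))
  hit <- IRanges::overlapsAny(gr_rec, gr_iv)
  pool[hit, , drop = FALSE]
}

# per-impact-class counts of a record set; InDels count as their own class
# and as high impact (alongside stop-gain, splicing, missense)
impact_counts <- function(records) {
  cls <- if_else(records$variant_class == "InDel", "InDel",
                 if_else(is.na(records$impact), "other", records$impact))
  lv <- c("InDel", IMPACT_LEVELS)
  cnt <- table(factor(cls, levels = lv))
  out <- as_tibble(as.list(setNames(as.integer(cnt), paste0("n_", lv))))
  out$high_impact <- sum(records$variant_class == "InDel" |
                           (!is.na(records$impact) &
                              records$impact %in% HIGH_IMPACT))
  out
}

#' Impact profile of screen mutations in candidate genes
#'
#' Tallies mutation impact classes per gene and the per-strain incidence of
#' high-impact events (InDel, stop-gain, splicing, missense) - the pattern
#' expected of a causal gene is (at least) one high-impact hit per selected
#' strain across the candidate set.
#'
#' @param pool An `ems_mutations` screen pool with impact annotations.
#' @param genes Gene models (`gene_id`, `chrom`, `start`, `end`); usually
#'   the candidate subset.
#' @return List of class `ems_impact_profile` with `counts` (per gene:
#'   per-class counts and `high_impact`) and `incidence` (per strain x gene:
#'   high-impact event count).
#' @export
impact_profile <- function(pool, genes) {
  genes <- as_tibble(genes)
  per_gene <- genes |>
    group_by(gene_id) |>
    group_map(function(df, key) {
      hits <- semi_join_events(pool, reduce_intervals(
        df[c("chrom", "start", "end")]))
      counts <- bind_cols(tibble(gene_id = key$gene_id), impact_counts(hits))
      hi <- hits[hits$variant_class == "InDel" |
                   (!is.na(hits$impact) & hits$impact %in% HIGH_IMPACT), ,
                 drop = FALSE]
      inc <- if (nrow(hi)) {
        hi |> count(strain_id, name = "n_high_impact") |>
          mutate(gene_id = key$gene_id, .before = 1)
      } else {
        tibble(gene_id = character(), strain_id = character(),
               n_high_impact = integer())
      }
      list(counts = counts, incidence = inc)
    })
  structure(
    list(counts = list_rbind(lapply(per_gene, `[[`, "counts")),
         incidence = list_rbind(lapply(per_gene, `[[`, "incidence"))),
    class = "ems_impact_profile"
  )
}

#' @export
print.ems_impact_profile <- function(x, ...) {
  cat("<ems_impact_profile>\n")
  print(x$counts)
  invisible(x)
}

#' @export
print.ems_enrichment <- function(x, ...) {
  cat("<ems_enrichment> pool of ", attr(x, "n_strains", exact = TRUE),
      " strain(s), alpha = ", format(attr(x, "alpha", exact = TRUE),
                                     digits = 4),
      ", ", sum(!is.na(x$p_value)), " gene(s) tested, ",
      sum(x$significant), " significant at FDR ",
      attr(x, "fdr", exact = TRUE), "\n", sep = "")
  NextMethod()
}

#' Tidy an enrichment result
#' @param x An `ems_enrichment`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.ems_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' Glance at an enrichment result
#' @param x An `ems_enrichment`.
#' @param ... Unused.
#' @return One-row tibble summarizing the screen test.
#' @export
glance.ems_enrichment <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(x$significant),
    n_strains = attr(x, "n_strains", exact = TRUE),
    alpha = attr(x, "alpha", exact = TRUE),
    fdr = attr(x, "fdr", exact = TRUE)
  )
}
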