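# Per-base feature matrix for the random-forest regressor: one row per
# retained genomic base, columns = smoothed protein tracks + the baseline
# context column p0, target y = (events at the base across the training
# cohort) / n_strains, i.e. the per-strain per-base event probability.

#' Build the per-base feature matrix
#'
#' One row per base, excluding bases flagged by the baseline track (N
#' windows, chromosome edges, patterns unseen in the genome table). Feature
#' columns are the smoothed tracks (named by their `feature_name`) plus
#' `p0`; the target `y` counts training events at the base divided by the
#' training cohort size, so a forest fitted on `y` predicts the per-strain
#' mutation probability directly.
#'
#' @param genome An [ems_genome()].
#' @param tracks List of smoothed `ems_track` objects covering all
#'   chromosomes.
#' @param p0track An `ems_p0_track` from [p0_track()].
#' @param training An `ems_mutations` training catalogue.
#' @return Tibble of class `ems_features` with columns `chrom`, `pos`,
#'   features, `y`; attributes `column_order` and `n_strains`.
#' @export
build_features <- function(genome, tracks, p0track, training) {
  stopifnot(inherits(p0track, "ems_p0_track"))
  if (length(tracks) == 0L) abort("at least one track required")
  nms <- vapply(tracks, function(t) t$feature_name, character(1))
  if (anyDuplicated(nms)) abort("duplicate track feature names")
  for (t in tracks) {
    if (!isTRUE(t$smoothed)) {
      abort(paste0("track ", t$feature_name,
                   " is not smoothed; run smooth_track() first"))
    }
    missing_chr <- setdiff(names(genome$chromosomes), names(t$values))
    if (length(missing_chr)) {
      abort(paste0("track ", t$feature_name, " missing chromosome ",
                   missing_chr[1]))
    }
  }
  n0 <- n_strains(training)
  lens <- chrom_lengths(genome)
  per_chrom <- lapply(names(lens), function(nm) {
    keep <- which(!p0track$flags[[nm]])
    if (length(keep) == 0L) return(NULL)
    cols <- c(
      list(chrom = rep(nm, length(keep)), pos = keep),
      setNames(lapply(tracks, function(t) t$values[[nm]][keep]), nms),
      list(p0 = p0track$values[[nm]][keep])
    )
    ev <- training[training$chrom == nm, , drop = FALSE]
    m <- integer(lens[[nm]])
    if (nrow(ev)) {
      tb <- tabulate(ev$pos, nbins = lens[[nm]])
      m <- tb
    }
    cols$y <- m[keep] / n0
    as_tibble(cols)
  })
  out <- list_rbind(per_chrom)
  structure(out,
            class = c("ems_features", class(out)),
            column_order = c(nms, "p0"),
            n_strains = n0)
}

feature_columns <- function(features) {
  attr(features, "column_order", exact = TRUE) %||%
    setdiff(names(features), c("chrom", "pos", "y"))
}

#' @export
print.ems_features <- function(x, ...) {
  cat("<ems_features> ", nrow(x), " base(s) x ",
      length(feature_columns(x)), " feature(s); training cohort of ",
      attr(x, "n_strains", exact = TRUE), " strain(s)\n", sep = "")
  NextMethod()
}
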