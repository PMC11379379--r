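# The mutation probability map: per-strain per-base mutation probability
# for every base of the genome, with the batch-effectiveness scalar alpha
# already applied, serialized as run-length-merged bedGraph.

#' Construct a mutation probability map
#'
#' @param values Named list of per-base numeric vectors (per-strain
#'   mutation probability), one per chromosome.
#' @param alpha Effectiveness scalar already applied to `values`.
#' @param provenance Free-form list describing how the map was produced.
#' @param flags Optional named list of logical vectors marking fallback
#'   bases.
#' @return An `ems_prob_map`.
#' @export
prob_map <- function(values, alpha = 1, provenance = NULL, flags = NULL) {
  if (is.null(names(values))) abort("map values need chromosome names")
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(v < 0), logical(1)))) {
    abort("map probabilities must be non-negative")
  }
  structure(list(values = values, alpha = alpha,
                 provenance = provenance, flags = flags),
            class = "ems_prob_map")
}

#' Rescale a probability map to a new effectiveness
#'
#' @param map An `ems_prob_map` (at its current `alpha`).
#' @param alpha New effectiveness scalar; values are multiplied by
#'   `alpha / map$alpha`.
#' @return Rescaled `ems_prob_map`.
#' @export
scale_map <- function(map, alpha) {
  stopifnot(inherits(map, "ems_prob_map"))
  f <- alpha / map$alpha
  prob_map(lapply(map$values, function(v) v * f), alpha = alpha,
           provenance = map$provenance, flags = map$flags)
}

#' Write a probability map as run-length-merged bedGraph
#'
#' Adjacent bases with equal values collapse into one interval; a
#' write-then-read round trip reproduces the values to at least six
#' decimals.
#'
#' @param map An `ems_prob_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "ems_prob_map"))
  write_bedgraph(map$values, path)
}

#' Read a probability map from bedGraph
#'
#' @param path bedGraph file written by [write_probability_map()].
#' @param genome [ems_genome()] giving chromosome lengths.
#' @param alpha Effectiveness the stored values correspond to.
#' @return An `ems_prob_map`.
#' @export
read_probability_map <- function(path, genome, alpha = 1) {
  tr <- read_track(path, genome, format = "bedgraph")
  prob_map(tr$values, alpha = alpha,
           provenance = list(source = path))
}

#' @export
print.ems_prob_map <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat("<ems_prob_map> ", length(x$values), " chromosome(s), ",
      format(length(v), big.mark = ","), " bp; alpha = ",
      format(x$alpha, digits = 4),
      "; mean P = ", format(mean(v), digits = 4), "\n", sep = "")
  invisible(x)
}
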