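# DNA-binding-protein signal tracks: dense per-base numeric vectors per
# chromosome, plus smoothing. Import goes through rtracklayer (bedGraph and
# fixedStep/variableStep wiggle); uncovered bases are 0.

#' Construct a signal track
#'
#' @param values Named list of per-base numeric vectors, one per chromosome.
#' @param feature_name Identifier for the protein / feature.
#' @param smoothed Whether `values` are already smoothed.
#' @param window Smoothing window (bp) if smoothed.
#' @return An `ems_track` object.
#' @export
signal_track <- function(values, feature_name = "feature",
                         smoothed = FALSE, window = NA_integer_) {
  if (is.null(names(values))) abort("track values need chromosome names")
  values <- lapply(values, as.numeric)
  structure(list(values = values, feature_name = feature_name,
                 smoothed = smoothed, window = window),
            class = "ems_track")
}

#' Read a signal track from bedGraph or wiggle
#'
#' Produces a dense per-base array for every genome chromosome; uncovered
#' bases are 0. bedGraph intervals are 0-based half-open; wiggle positions
#' 1-based, per the format specs. Overlapping or unsorted intervals are an
#' error.
#'
#' @param path File path (`.bedgraph`/`.bg` or `.wig`; or set `format`).
#' @param genome [ems_genome()] providing chromosome lengths.
#' @param format `"auto"`, `"bedgraph"`, or `"wiggle"`.
#' @param feature_name Feature identifier; defaults to the file stem.
#' @return An `ems_track`.
#' @export
read_track <- function(path, genome, format = c("auto", "bedgraph", "wiggle"),
                       feature_name = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig(\\.gz)?$", path)) "wiggle" else "bedgraph"
  }
  fmt <- if (format == "wiggle") "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  lens <- chrom_lengths(genome)
  bad <- setdiff(as.character(unique(GenomicRanges::seqnames(gr))),
                 names(lens))
  if (length(bad)) abort(paste0("track chromosome not in genome: ", bad[1]))
  # per-chromosome ordering + overlap check
  spl <- GenomicRanges::split(gr, GenomicRanges::seqnames(gr))
  for (nm in names(spl)) {
    g <- spl[[nm]]
    if (length(g) == 0L) next
    st <- GenomicRanges::start(g)
    if (is.unsorted(st)) abort(paste0("unsorted intervals on ", nm))
    if (!IRanges::isDisjoint(IRanges::ranges(g))) {
      abort(paste0("overlapping intervals on ", nm))
    }
  }
  values <- lapply(names(lens), function(nm) {
    v <- numeric(lens[[nm]])
    if (!nm %in% names(spl)) return(v)
    g <- spl[[nm]]
    if (length(g) == 0L) return(v)
    if (max(GenomicRanges::end(g)) > lens[[nm]]) {
      abort(paste0("interval beyond chromosome end on ", nm))
    }
    cov <- IRanges::coverage(IRanges::ranges(g), weight = g$score,
                             width = lens[[nm]])
    as.numeric(cov)
  })
  names(values) <- names(lens)
  signal_track(values,
               feature_name = feature_name %||%
                 sub("\\.(bedgraph|bg|wig)(\\.gz)?$", "", basename(path)))
}

#' Write per-base values as bedGraph
#'
#' Runs of adjacent equal values are merged into single intervals
#' (0-based half-open coordinates).
#'
#' @param values Named list of per-base numeric vectors, an `ems_track`,
#'   or an `ems_prob_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path) {
  if (inherits(values, "ems_track") || inherits(values, "ems_prob_map")) {
    values <- values$values
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(values)) {
    r <- rle(values[[nm]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based starts
    writeLines(sprintf("%s\t%d\t%d\t%.10g", nm, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Smooth a track with a centered moving average
#'
#' Centered window of `window` bases (for even windows one extra base on the
#' right). At chromosome edges the window shrinks to the available span. A
#' window at least as long as the chromosome yields the chromosome-wide mean
#' everywhere.
#'
#' @param track An `ems_track`.
#' @param window Window size in bases (default 100).
#' @return A smoothed `ems_track` of identical dimensions.
#' @export
smooth_track <- function(track, window = 100L) {
  stopifnot(inherits(track, "ems_track"))
  window <- as.integer(window)
  if (window < 1L) abort("window must be >= 1")
  hl <- (window - 1L) %/% 2L
  hr <- window %/% 2L
  sm <- lapply(track$values, function(v) {
    L <- length(v)
    if (window >= L) return(rep(mean(v), L))
    cs <- c(0, cumsum(v))
    i <- seq_len(L)
    lo <- pmax(i - hl, 1L)
    hi <- pmin(i + hr, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  signal_track(sm, feature_name = track$feature_name,
               smoothed = TRUE, window = window)
}

#' @export
print.ems_track <- function(x, ...) {
  cat("<ems_track> ", x$feature_name,
      if (isTRUE(x$smoothed)) paste0(" (smoothed, window ", x$window, ")"),
      ": ", length(x$values), " chromosome(s), ",
      format(sum(lengths(x$values)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}
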