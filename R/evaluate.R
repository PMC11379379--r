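# Model evaluation: coefficient of determination, block-level validation of
# expected vs observed mutation counts, GC correlation, and permutation
# feature importance with min-max normalization.

#' Coefficient of determination R-squared = 1 - MSE / Var
#'
#' Uses the population variance of `y` (plain mean of squared deviations),
#' so a constant predictor at `mean(y)` scores exactly 0 and predictors
#' worse than the mean go negative.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return Scalar R-squared (<= 1).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L) {
    abort("y and yhat must be equal-length, non-empty")
  }
  v <- mean((y - mean(y))^2)
  if (v == 0) abort("Var(y) is zero; R-squared undefined")
  1 - mean((y - yhat)^2) / v
}

#' Block-level validation of a probability map
#'
#' Compares the expected mutation count `n x sum(P)` against the observed
#' event count in genomic blocks. Blocks are tiled positionally from the
#' start of each chromosome (default), or - after sorting bases by their
#' predicted rate - formed as consecutive chunks of `block_size` bases of
#' the sorted order (`sort_by_prediction = TRUE`).
#'
#' @param map An `ems_prob_map`.
#' @param dataset An `ems_mutations` cohort on the same genome.
#' @param block_size Block size in bases (e.g. 1e5 or 3e5; use 1e4 on toy
#'   genomes).
#' @param sort_by_prediction Sort bases by predicted rate before chunking.
#' @param n_strains Cohort size; defaults to the dataset attribute.
#' @return List of class `ems_block_validation`: `blocks` tibble
#'   (`block`, `chrom`, `expected`, `observed`), `pearson_r` (NA with a
#'   warning when degenerate), `block_size`, `mode`.
#' @export
block_validation <- function(map, dataset, block_size = 100000L,
                             sort_by_prediction = FALSE, n_strains = NULL) {
  n <- n_strains %||% n_strains(dataset)
  block_size <- as.integer(block_size)
  ev <- lapply(names(map$values), function(nm) {
    L <- length(map$values[[nm]])
    pos <- dataset$pos[dataset$chrom == nm]
    tabulate(pos, nbins = L)
  })
  names(ev) <- names(map$values)
  if (!sort_by_prediction) {
    blocks <- imap(map$values, function(v, nm) {
      L <- length(v)
      blk <- (seq_len(L) - 1L) %/% block_size
      tibble(
        chrom = nm,
        block = seq_len(max(blk) + 1L),
        expected = n * as.numeric(tapply(v, blk, sum)),
        observed = as.integer(tapply(ev[[nm]], blk, sum))
      )
    }) |> list_rbind() |> mutate(block = row_number())
  } else {
    p_all <- unlist(map$values, use.names = FALSE)
    e_all <- unlist(ev, use.names = FALSE)
    ord <- order(p_all)
    blk <- (seq_along(ord) - 1L) %/% block_size
    blocks <- tibble(
      chrom = NA_character_,
      block = seq_len(max(blk) + 1L),
      expected = n * as.numeric(tapply(p_all[ord], blk, sum)),
      observed = as.integer(tapply(e_all[ord], blk, sum))
    )
  }
  r <- if (nrow(blocks) < 2L || sd(blocks$expected) == 0 ||
           sd(blocks$observed) == 0) {
    warn("block validation degenerate (constant blocks); Pearson r undefined")
    NA_real_
  } else {
    cor(blocks$expected, blocks$observed)
  }
  structure(list(blocks = blocks, pearson_r = r,
                 block_size = block_size,
                 mode = if (sort_by_prediction) "sorted" else "positional"),
            class = "ems_block_validation")
}

#' @export
print.ems_block_validation <- function(x, ...) {
  cat("<ems_block_validation> ", nrow(x$blocks), " block(s) of ",
      format(x$block_size, big.mark = ","), " bp (", x$mode,
      "); Pearson r = ", format(x$pearson_r, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Glance at a block validation
#' @param x An `ems_block_validation`.
#' @param ... Unused.
#' @return One-row tibble with `pearson_r`, `r2`, `n_blocks`, `block_size`,
#'   `mode`; `r2` is [r_squared()] of observed counts against expected.
#' @export
glance.ems_block_validation <- function(x, ...) {
  tibble(
    pearson_r = x$pearson_r,
    r2 = tryCatch(r_squared(x$blocks$observed, x$blocks$expected),
                  error = function(e) NA_real_),
    n_blocks = nrow(x$blocks),
    block_size = x$block_size,
    mode = x$mode
  )
}

#' Per-chromosome correlation between GC content and mutation counts
#'
#' Windows are tiled from the first base of each chromosome; per window the
#' number of C/G bases and the number of mutation events are counted and
#' their Pearson correlation is reported per chromosome.
#'
#' @param genome An [ems_genome()].
#' @param dataset An `ems_mutations` cohort.
#' @param window Window size in bp (default 1e5).
#' @return Tibble with `chrom`, `pearson_r` (NA when degenerate),
#'   `n_windows`. Chromosomes shorter than one window are skipped with a
#'   warning.
#' @export
gc_correlation <- function(genome, dataset, window = 100000L) {
  window <- as.integer(window)
  rows <- lapply(names(genome$chromosomes), function(nm) {
    s <- genome$chromosomes[[nm]]
    L <- nchar(s)
    if (L < window) {
      warn(paste0("chromosome ", nm, " shorter than one window; skipped"))
      return(NULL)
    }
    blk <- ((seq_len(L) - 1L) %/% window)
    is_gc <- as.integer(charToRaw(s) %in% charToRaw("CG"))
    gc <- as.numeric(tapply(is_gc, blk, sum))
    evt <- tabulate(dataset$pos[dataset$chrom == nm], nbins = L)
    mut <- as.numeric(tapply(evt, blk, sum))
    r <- if (length(gc) < 2L || sd(gc) == 0 || sd(mut) == 0) {
      warn(paste0("GC or mutation counts constant on ", nm,
                  "; correlation undefined"))
      NA_real_
    } else {
      cor(gc, mut)
    }
    tibble(chrom = nm, pearson_r = r, n_windows = length(gc))
  })
  list_rbind(rows[!vapply(rows, is.null, logical(1))])
}

#' Permutation feature importance
#'
#' Replaces one feature column at a time by a draw that preserves its
#' marginal value distribution, re-scores the model, and reports
#' `i_j = R2 - mean over shuffles of permuted R2`. The default replacement
#' is a within-column permutation (which preserves the empirical
#' distribution exactly); `mode = "noise"` instead samples with replacement.
#' For reporting, importances are min-max normalized to \[0, 1\]
#' (`importance_scaled`); with a single feature the normalization is
#' undefined and raw values are returned with a warning.
#'
#' @param model An `ems_rf` (or any object with a [predict_rf()]-compatible
#'   `predict_fn`).
#' @param features `ems_features` rows to evaluate on (held-out rows are the
#'   honest choice).
#' @param n_shuffles Number of shuffles per feature (default 10).
#' @param seed Integer seed; permutations are drawn feature by feature,
#'   shuffle by shuffle, reproducibly.
#' @param mode `"permute"` (default) or `"noise"`.
#' @param predict_fn Function `(model, features) -> yhat`; defaults to
#'   [predict_rf()].
#' @return Tibble with `feature`, `importance` (raw `i_j`) and
#'   `importance_scaled` (min-max V), attribute `r2` = unpermuted
#'   R-squared.
#' @export
permutation_importance <- function(model, features, n_shuffles = 10L,
                                   seed = 1L,
                                   mode = c("permute", "noise"),
                                   predict_fn = predict_rf) {
  mode <- match.arg(mode)
  if (n_shuffles < 1L) abort("n_shuffles must be >= 1")
  cols <- if (inherits(model, "ems_rf")) model$column_order else
    feature_columns(features)
  base_r2 <- r_squared(features$y, predict_fn(model, features))
  n <- nrow(features)
  imp <- withr::with_seed(seed, {
    map_dbl(cols, function(j) {
      r2s <- vapply(seq_len(n_shuffles), function(s) {
        idx <- if (mode == "permute") sample.int(n) else
          sample.int(n, replace = TRUE)
        perm <- features
        perm[[j]] <- perm[[j]][idx]
        r_squared(features$y, predict_fn(model, perm))
      }, numeric(1))
      base_r2 - mean(r2s)
    })
  })
  scaled <- if (length(cols) < 2L || diff(range(imp)) == 0) {
    warn("min-max normalization undefined; returning raw importances")
    rep(NA_real_, length(cols))
  } else {
    (imp - min(imp)) / (max(imp) - min(imp))
  }
  out <- tibble(feature = cols, importance = imp,
                importance_scaled = scaled) |>
    arrange(desc(importance))
  attr(out, "r2") <- base_r2
  attr(out, "n_shuffles") <- n_shuffles
  out
}
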