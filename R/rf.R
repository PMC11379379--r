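# Random-forest regressor of per-strain per-base mutation probability.
# Forest mechanics come from ranger; the model contract mirrors the mapping
# design: regression trees whose every leaf holds at least `min_leaf`
# training rows, each split drawing from at most floor(max_feature_frac *
# n_features) features, forest prediction = mean over trees, map value =
# alpha * prediction.

#' Split a feature matrix into training and test rows
#'
#' @param features An `ems_features` tibble.
#' @param test_frac Fraction of rows held out (default 0.2).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with `train` and `test` tibbles (attributes preserved).
#' @export
train_test_split <- function(features, test_frac = 0.2, seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1) abort("test_frac must be in (0,1)")
  n <- nrow(features)
  n_test <- round(test_frac * n)
  test_idx <- sort(withr::with_seed(seed, sample.int(n, n_test)))
  keep_attrs <- function(df) {
    structure(df, class = class(features),
              column_order = feature_columns(features),
              n_strains = attr(features, "n_strains", exact = TRUE))
  }
  list(train = keep_attrs(features[-test_idx, , drop = FALSE]),
       test = keep_attrs(features[test_idx, , drop = FALSE]))
}

#' Train the mutation-probability random forest
#'
#' Defaults are the production-scale settings (600 trees, minimum leaf of
#' 30,000 rows, at most 70% of features per split); for toy genomes use
#' e.g. `trees = 100, min_leaf = 200`. Each tree is grown on a bootstrap
#' sample (`bootstrap_frac` of the rows, with replacement by default), and
#' a leaf predicts the mean target of its training rows.
#'
#' @param features An `ems_features` tibble from [build_features()].
#' @param trees Number of trees.
#' @param min_leaf Hard minimum number of training rows per leaf.
#' @param max_feature_frac Fraction of features considered per split;
#'   `mtry = max(1, floor(max_feature_frac * n_features))`.
#' @param bootstrap_frac Fraction of rows drawn per tree.
#' @param replace Sample rows with replacement (standard bootstrap).
#' @param seed Integer seed threaded to the forest.
#' @return An `ems_rf` model object.
#' @export
train_rf <- function(features, trees = 600L, min_leaf = 30000L,
                     max_feature_frac = 0.7, bootstrap_frac = 1,
                     replace = TRUE, seed = 1L) {
  cols <- feature_columns(features)
  x <- as.data.frame(features[cols])
  yv <- features$y
  if (min_leaf >= nrow(x)) abort("min_leaf must be smaller than the row count")
  mtry <- max(1L, floor(max_feature_frac * length(cols)))
  fit <- ranger::ranger(
    x = x, y = yv,
    num.trees = trees,
    mtry = mtry,
    min.bucket = min_leaf,
    sample.fraction = bootstrap_frac,
    replace = replace,
    seed = seed,
    num.threads = 1L,
    keep.inbag = TRUE,
    importance = "impurity",
    verbose = FALSE
  )
  structure(
    list(forest = fit,
         column_order = cols,
         params = list(trees = trees, min_leaf = min_leaf,
                       max_feature_frac = max_feature_frac, mtry = mtry,
                       bootstrap_frac = bootstrap_frac, replace = replace),
         seed = seed,
         training_n_strains = attr(features, "n_strains", exact = TRUE),
         training_y_var = stats::var(yv) * (length(yv) - 1) / length(yv)),
    class = "ems_rf"
  )
}

#' Predict per-strain mutation probabilities for feature rows
#'
#' @param model An `ems_rf`.
#' @param features An `ems_features` tibble (columns must include the
#'   model's feature columns).
#' @return Numeric vector of per-row predictions (mean over trees).
#' @export
predict_rf <- function(model, features) {
  stopifnot(inherits(model, "ems_rf"))
  miss <- setdiff(model$column_order, names(features))
  if (length(miss)) {
    abort(paste0("feature column(s) missing: ", toString(miss)))
  }
  x <- as.data.frame(features[model$column_order])
  predict(model$forest, data = x, num.threads = 1L)$predictions
}

#' In-bag leaf sizes of a fitted forest
#'
#' Audits the minimum-leaf-size constraint: for every tree, counts the
#' bootstrap (in-bag) training rows assigned to each terminal node.
#'
#' @param model An `ems_rf` fitted with the training matrix `features`.
#' @param features The training `ems_features` used to fit `model`.
#' @return Tibble with columns `tree`, `node`, `n_inbag`.
#' @export
rf_leaf_sizes <- function(model, features) {
  x <- as.data.frame(features[model$column_order])
  tn <- predict(model$forest, data = x, type = "terminalNodes",
                num.threads = 1L)$predictions
  inbag <- model$forest$inbag.counts
  if (is.null(inbag)) abort("model was not fitted with keep.inbag")
  rows <- lapply(seq_len(ncol(tn)), function(t) {
    cnt <- tapply(inbag[[t]], tn[, t], sum)
    tibble(tree = t, node = as.integer(names(cnt)),
           n_inbag = as.integer(cnt))
  })
  list_rbind(rows)
}

#' Emit the genome-wide per-base probability map
#'
#' Map value = `alpha` x forest prediction at every base in `features`;
#' bases absent from the matrix (flagged fallback bases of the baseline
#' track) are filled with `alpha` x the central-base marginal per-strain
#' rate, i.e. the baseline track value divided by the training cohort size.
#'
#' @param model An `ems_rf`.
#' @param features An `ems_features` covering the bases to predict.
#' @param p0track The `ems_p0_track` used to build `features` (supplies
#'   chromosome lengths and fallback values).
#' @param alpha Batch effectiveness scalar (1 for the training batch).
#' @return An `ems_prob_map`.
#' @export
predict_map <- function(model, features, p0track, alpha = 1) {
  stopifnot(inherits(p0track, "ems_p0_track"))
  n0 <- attr(p0track, "n_strains", exact = TRUE) %||%
    model$training_n_strains
  pred <- predict_rf(model, features)
  values <- lapply(names(p0track$values), function(nm) {
    v <- p0track$values[[nm]] / n0  # per-strain fallback everywhere
    v
  })
  names(values) <- names(p0track$values)
  rows <- split(seq_len(nrow(features)), features$chrom)
  for (nm in names(rows)) {
    i <- rows[[nm]]
    values[[nm]][features$pos[i]] <- pred[i]
  }
  values <- lapply(values, function(v) pmax(alpha * v, 0))
  prob_map(values, alpha = alpha,
           provenance = list(model = "ems_rf", seed = model$seed,
                             params = model$params,
                             columns = model$column_order),
           flags = p0track$flags)
}

#' @export
print.ems_rf <- function(x, ...) {
  p <- x$params
  cat("<ems_rf> ", p$trees, " trees, min leaf ", p$min_leaf,
      ", mtry ", p$mtry, "/", length(x$column_order),
      ", seed ", x$seed, "\n", sep = "")
  cat("  features: ", toString(x$column_order), "\n", sep = "")
  cat("  OOB MSE: ", format(x$forest$prediction.error, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mutation forest: per-feature impurity importance
#' @param x An `ems_rf`.
#' @param ... Unused.
#' @return Tibble with `feature` and `importance` (impurity decrease).
#' @export
tidy.ems_rf <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(desc(importance))
}

#' Glance at a fitted mutation forest
#' @param x An `ems_rf`.
#' @param ... Unused.
#' @return One-row tibble with forest parameters, out-of-bag MSE and the
#'   corresponding out-of-bag R-squared.
#' @export
glance.ems_rf <- function(x, ...) {
  oob <- x$forest$prediction.error
  tibble(
    trees = x$params$trees,
    min_leaf = x$params$min_leaf,
    mtry = x$params$mtry,
    n_rows = x$forest$num.samples,
    oob_mse = oob,
    oob_r2 = 1 - oob / x$training_y_var
  )
}
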