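# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a gene-enrichment result
#'
#' @param object An `ems_enrichment`.
#' @param label_top Number of top genes to label.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ems_enrichment <- function(object, label_top = 5L, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(p_value)) |>
    mutate(log2fc = log2(fold_change), nlp = -log10(pmax(p_value, 1e-300)))
  top <- head(arrange(df, p_value), label_top)
  ggplot(df, aes(x = .data$log2fc, y = .data$nlp,
                 color = .data$significant)) +
    geom_point(alpha = 0.7) +
    geom_text(data = top, aes(label = .data$gene_id),
              vjust = -0.6, size = 3, show.legend = FALSE) +
    scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    labs(x = "log2 fold change (observed / expected)",
         y = "-log10 p-value", color = "significant") +
    theme_minimal()
}

#' Scatter plot of a block validation
#'
#' @param object An `ems_block_validation`.
#' @param ... Unused.
#' @return A ggplot of observed vs expected block counts with the identity
#'   line.
#' @export
autoplot.ems_block_validation <- function(object, ...) {
  ggplot(object$blocks, aes(x = expected, y = observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    geom_point(alpha = 0.6, color = "steelblue") +
    labs(x = "expected mutation count", y = "observed mutation count",
         title = sprintf("%s blocks of %s bp, Pearson r = %.3f",
                         object$mode, format(object$block_size,
                                             big.mark = ","),
                         object$pearson_r)) +
    theme_minimal()
}

#' Line plot of a probability map region
#'
#' @param object An `ems_prob_map`.
#' @param chrom Chromosome to draw.
#' @param start,end Region bounds (1-based inclusive; defaults to the whole
#'   chromosome).
#' @param ... Unused.
#' @return A ggplot of per-base probability along the region.
#' @export
autoplot.ems_prob_map <- function(object, chrom = names(object$values)[1],
                                  start = 1L,
                                  end = length(object$values[[chrom]]),
                                  ...) {
  v <- object$values[[chrom]][start:end]
  ggplot(tibble(pos = start:end, P = v), aes(x = pos, y = P)) +
    geom_line(color = "steelblue", linewidth = 0.3) +
    labs(x = paste0(chrom, " position (bp)"),
         y = "per-strain mutation probability") +
    theme_minimal()
}

#' Distribution of 5-mer baseline rates by central base
#'
#' @param object An `ems_context`.
#' @param ... Unused.
#' @return A ggplot: P0 of each observed pattern, grouped by central base.
#' @export
autoplot.ems_context <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(C0 > 0L) |>
    mutate(central = substring(pattern, 3L, 3L))
  ggplot(df, aes(x = .data$central, y = .data$P0)) +
    geom_jitter(width = 0.2, alpha = 0.3, size = 0.6) +
    geom_boxplot(outlier.shape = NA, fill = NA, color = "firebrick") +
    labs(x = "central base", y = "P0 (events per pattern occurrence)") +
    theme_minimal()
}

#' Bar plot of permutation importances
#'
#' @param importances Tibble from [permutation_importance()].
#' @return A ggplot of min-max normalized importances.
#' @export
plot_importance <- function(importances) {
  ggplot(importances,
         aes(x = stats::reorder(.data$feature, .data$importance),
             y = .data$importance_scaled)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "permutation importance (min-max scaled)") +
    theme_minimal()
}
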