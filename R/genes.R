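# Gene models as a tidy interval table: one row per (gene, interval),
# 1-based inclusive coordinates. A gene's territory is the union of its
# intervals (gene body by default; supply exon rows for exonic-only
# analyses).

#' Read gene models from GFF3
#'
#' @param path GFF3 file.
#' @param feature_type Feature type(s) to keep (default `"gene"`).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) abort(paste0("no '", feature_type,
                                     "' features in ", path))
  id <- gr$ID %||% gr$Name
  if (is.null(id) || any(is.na(id))) {
    id <- paste0("feature_", seq_along(gr))
  }
  tibble(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    mutate(strand = if_else(strand %in% c("+", "-"), strand, "+")) |>
    arrange(chrom, start)
}

#' Write gene models as GFF3
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, optional
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  genes <- as_tibble(genes)
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = strand
  )
  gr$type <- "gene"
  gr$source <- "emsmap"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
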