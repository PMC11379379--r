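# Reference genome container: a named list of uppercase chromosome strings
# over {A,C,G,T,N}. Kept as plain character vectors; Biostrings objects are
# built transiently where its counters are faster.

#' Construct a reference genome object
#'
#' @param seqs Named character vector or list of chromosome sequences
#'   (alphabet `A`, `C`, `G`, `T`, `N`; lower case is accepted and folded).
#' @return An `ems_genome`: list with element `chromosomes` (named character
#'   vector) and attribute-free length accessors via [chrom_lengths()].
#' @export
ems_genome <- function(seqs) {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) == 0L) abort("genome has no chromosomes")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("every chromosome needs a name")
  }
  if (anyDuplicated(names(seqs))) {
    abort(paste0("duplicate chromosome name: ",
                 names(seqs)[duplicated(names(seqs))][1]))
  }
  if (any(nchar(seqs) == 0L)) abort("empty chromosome sequence")
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    abort(paste0("chromosome ", names(seqs)[bad][1],
                 " contains letters outside {A,C,G,T,N}"))
  }
  structure(list(chromosomes = seqs), class = "ems_genome")
}

#' Read a FASTA reference genome
#'
#' Sequence names are truncated at the first whitespace; sequences are
#' uppercased. Wrapped sequence lines are concatenated.
#'
#' @param path Path to a FASTA file.
#' @return An [ems_genome()] object.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) abort(paste0("no sequences in ", path))
  nm <- sub("\\s.*$", "", names(dss))
  seqs <- setNames(toupper(as.character(dss)), nm)
  ems_genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome An [ems_genome()].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome An [ems_genome()].
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "ems_genome"))
  vapply(genome$chromosomes, nchar, integer(1))
}

#' Total genome length
#' @param genome An [ems_genome()].
#' @return Total base pairs across chromosomes.
#' @export
genome_length <- function(genome) sum(chrom_lengths(genome))

#' @export
print.ems_genome <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("<ems_genome> ", length(len), " chromosome(s), ",
      format(sum(len), big.mark = ","), " bp\n", sep = "")
  for (nm in names(len)) {
    cat("  ", nm, ": ", format(len[[nm]], big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

# integer base codes A=0 C=1 G=2 T=3, NA for N; fast raw-byte lookup
base_codes <- function(seq) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[as.integer(charToRaw(seq)) + 1L]
}

# centered 5-mer index (base-4, first base most significant) for every
# position; NA at edges and wherever the window touches an N
kmer_index5 <- function(code) {
  L <- length(code)
  idx <- rep(NA_real_, L)
  if (L < 5L) return(idx)
  idx[3:(L - 2)] <- code[1:(L - 4)] * 256 + code[2:(L - 3)] * 64 +
    code[3:(L - 2)] * 16 + code[4:(L - 1)] * 4 + code[5:L]
  idx
}

# all 4^5 patterns in the order of kmer_index5 (index 0 .. 1023)
all_kmers5 <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
}
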