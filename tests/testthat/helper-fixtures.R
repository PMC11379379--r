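# Shared fixtures, built in code. Small genomes keep unit tests fast; the
# heavier simulation experiments live in test-acceptance.R.

fixture_genome <- function(seqs = c(chrI = "ACGTACGTACGTACGTACGT",
                                    chrII = "GGGGCCCCAAAATTTTGGGG")) {
  ems_genome(seqs)
}

fixture_mutations <- function(genome, df, n_strains = NULL) {
  mutation_dataset(df, n_strains = n_strains, genome = genome)
}

# deterministic small synthetic study shared by several test files
fixture_study <- function(length = 1e5, n_chroms = 1, n_strains = 200,
                          seed = 101) {
  g <- make_genome(length, n_chroms = n_chroms, seed = seed)
  sil <- make_silent_regions(g, frac = 0.1, seed = seed)
  trks <- make_tracks(g, n_tracks = 3, knot_spacing = 5000,
                      silent_regions = sil, seed = seed)
  truth <- make_truth(g, trks, silent_regions = sil, seed = seed)
  cohort <- simulate_cohort(truth, n_strains = n_strains, seed = seed + 1)
  list(genome = g, silent = sil, tracks = trks, truth = truth,
       cohort = cohort)
}

# brute-force 5-mer window scan: the independent oracle for context counts
brute_force_windows <- function(genome) {
  out <- character(0)
  for (s in genome$chromosomes) {
    L <- nchar(s)
    if (L < 5) next
    for (i in 3:(L - 2)) {
      w <- substr(s, i - 2, i + 2)
      if (!grepl("N", w)) out <- c(out, w)
    }
  }
  out
}

brute_force_c0 <- function(genome) {
  w <- brute_force_windows(genome)
  tab <- table(w)
  tibble::tibble(pattern = names(tab), C0 = as.integer(tab))
}
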