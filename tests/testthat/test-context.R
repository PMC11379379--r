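# The 5-mer context model: genome pattern counts, P0 estimation, the
# per-base baseline track and the flanking-composition chi-square test.

test_that("genome pattern counting enumerates interior N-free windows", {
  g <- ems_genome(c(chrI = "AACGTT"))
  c0 <- count_genome_patterns(g)
  nz <- c0[c0$C0 > 0, ]
  expect_equal(sort(nz$pattern), c("AACGT", "ACGTT"))
  expect_equal(nz$C0, c(1L, 1L))

  g2 <- ems_genome(c(chrI = "AAAAAA"))
  c02 <- count_genome_patterns(g2)
  expect_equal(c02$C0[c02$pattern == "AAAAA"], 2L)

  g3 <- ems_genome(c(chrI = "AANAAAAA"))  # only the window at pos 6 is N-free
  c03 <- count_genome_patterns(g3)
  expect_equal(c03$C0[c03$pattern == "AAAAA"], 1L)
})

test_that("pattern counts match the brute-force window scan on random genomes", {
  for (seed in 1:3) {
    g <- make_genome(2000 + 811 * seed, n_chroms = 2, seed = seed)
    fast <- count_genome_patterns(g)
    slow <- brute_force_c0(g)
    merged <- dplyr::left_join(fast, slow, by = "pattern",
                               suffix = c("_fast", "_slow")) |>
      dplyr::mutate(C0_slow = dplyr::coalesce(C0_slow, 0L))
    expect_identical(merged$C0_fast, merged$C0_slow)
  }
})

test_that("P0 = C'/C0 on a hand-enumerable genome", {
  g <- ems_genome(c(chrI = "AAAAAA"))
  muts <- mutation_dataset(
    tibble::tibble(strain_id = "s1", chrom = "chrI", pos = 3L,
                   ref = "A", alt = "T"),
    genome = g
  )
  ctx <- compute_p0(g, muts)
  expect_equal(ctx$P0[ctx$pattern == "AAAAA"], 1 / 2)
  expect_equal(sum(ctx$C_prime), 1L)
})

test_that("a cohort with no mutations gives P0 = 0 for observed patterns", {
  g <- make_genome(3000, seed = 2)
  empty <- mutation_dataset(
    tibble::tibble(strain_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character()),
    n_strains = 5
  )
  ctx <- compute_p0(g, empty)
  expect_true(all(ctx$P0[ctx$C0 > 0] == 0))
  expect_true(all(is.na(ctx$P0[ctx$C0 == 0])))
})

test_that("compute_p0 matches an independent per-window accumulation", {
  st <- fixture_study(length = 20000, n_strains = 50, seed = 31)
  ctx <- suppressMessages(compute_p0(st$genome, st$cohort))
  # oracle: accumulate windows record by record with substr
  snv <- st$cohort[st$cohort$variant_class == "SNV", ]
  expected <- table(vapply(seq_len(nrow(snv)), function(i) {
    s <- st$genome$chromosomes[[snv$chrom[i]]]
    p <- snv$pos[i]
    if (p < 3 || p > nchar(s) - 2) return(NA_character_)
    w <- substr(s, p - 2, p + 2)
    if (grepl("N", w)) NA_character_ else w
  }, character(1)))
  for (pat in names(expected)) {
    expect_equal(ctx$C_prime[ctx$pattern == pat],
                 as.integer(expected[[pat]]))
  }
  expect_equal(sum(ctx$C_prime), sum(expected))
  # determinism: identical inputs give identical tables
  ctx2 <- suppressMessages(compute_p0(st$genome, st$cohort))
  expect_identical(as.data.frame(ctx), as.data.frame(ctx2))
})

test_that("recurrent events count once per event and InDels are skipped", {
  g <- ems_genome(c(chrI = "AAAAAA"))
  muts <- mutation_dataset(
    tibble::tibble(strain_id = c("s1", "s2", "s3"), chrom = "chrI",
                   pos = c(3L, 3L, 4L), ref = c("A", "A", "A"),
                   alt = c("T", "T", "AT")),
    genome = g
  )
  ctx <- suppressMessages(compute_p0(g, muts))
  expect_equal(ctx$C_prime[ctx$pattern == "AAAAA"], 2L)  # InDel excluded
  expect_equal(attr(ctx, "skipped_events"), 1L)
  expect_equal(ctx$P0[ctx$pattern == "AAAAA"], 1)        # 2 events / C0 = 2
})

test_that("p0 track assigns each base its centered 5-mer rate", {
  g <- ems_genome(c(chrI = strrep("A", 10)))
  muts <- mutation_dataset(
    tibble::tibble(strain_id = "s1", chrom = "chrI", pos = 5L,
                   ref = "A", alt = "T"),
    genome = g
  )
  ctx <- compute_p0(g, muts)
  pt <- p0_track(g, ctx)
  inner <- 3:8
  expect_equal(pt$values$chrI[inner], rep(1 / 6, 6))  # C0(AAAAA)=6, C'=1
  expect_false(any(pt$flags$chrI[inner]))
  # edge bases fall back to the central-base marginal and are flagged
  expect_true(all(pt$flags$chrI[c(1, 2, 9, 10)]))
  expect_equal(pt$values$chrI[1], 1 / 6)  # marginal for A = 1/6 here
})

test_that("p0 track conserves total expected events", {
  st <- fixture_study(length = 30000, n_strains = 50, seed = 33)
  ctx <- suppressMessages(compute_p0(st$genome, st$cohort))
  pt <- p0_track(st$genome, ctx)
  interior <- sum(unlist(purrr::map2(pt$values, pt$flags,
                                     function(v, f) sum(v[!f]))))
  expect_equal(interior, sum(ctx$C_prime), tolerance = 1e-9)
})

test_that("flanking chi-square: proportional observed gives 0, hand case 30", {
  # null case: observed composition proportional to genome expectation
  g <- make_genome(5000, seed = 41)
  # place a mutation at every interior G so observed == genome composition
  chars <- strsplit(g$chromosomes[["chrI"]], "")[[1]]
  at <- which(chars == "G")
  at <- at[at > 4 & at < length(chars) - 4]
  muts <- mutation_dataset(
    tibble::tibble(strain_id = "s1", chrom = "chrI", pos = at,
                   ref = "G", alt = "A"),
    genome = g
  )
  res <- flanking_chisq(g, muts, "G", offsets = c(-1L, 1L))
  expect_equal(res$chi2, c(0, 0), tolerance = 1e-9)
  expect_equal(res$p_value, c(1, 1), tolerance = 1e-9)

  # hand-computed Pearson statistic: observed (10,0,0,0) vs uniform genome
  obs <- c(10, 0, 0, 0)
  expd <- rep(2.5, 4)
  expect_equal(sum((obs - expd)^2 / expd), 30)
})

test_that("flanking chi-square detects a planted +1 preference", {
  # random genome, but mutations placed only at G bases followed by A:
  # the +1 composition around mutated sites departs from the genome-wide
  # +1 composition around G
  g <- make_genome(6000, seed = 42)
  chars <- strsplit(g$chromosomes[["chrI"]], "")[[1]]
  at <- which(chars == "G" & c(chars[-1], "N") == "A")
  at <- at[at > 4 & at < length(chars) - 4]
  muts <- mutation_dataset(
    tibble::tibble(strain_id = "s1", chrom = "chrI", pos = at,
                   ref = "G", alt = "A"),
    genome = g
  )
  res <- flanking_chisq(g, muts, "G", offsets = 1L)
  expect_gt(res$chi2, qchisq(0.999, df = 3))
  expect_lt(res$p_value, 0.001)
  expect_equal(sum(res$observed[[1]]), sum(res$expected[[1]]))
})

test_that("a catalogue inconsistent with the genome is rejected", {
  g <- ems_genome(c(chrI = "AAAAAA"))
  muts <- mutation_dataset(
    tibble::tibble(strain_id = "s1", chrom = "chrX", pos = 3L,
                   ref = "A", alt = "T")
  )
  expect_error(compute_p0(g, muts), "not in genome")
})
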