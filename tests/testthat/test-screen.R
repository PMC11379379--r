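# Screen statistics: effectiveness normalization, sequence expectations,
# background removal, the gene-burden test and impact profiling.

test_that("batch effectiveness is the ratio of per-strain means", {
  eff <- batch_effectiveness(360, 360)
  expect_equal(eff$alpha_1, 1)

  eff2 <- batch_effectiveness(360, 272)
  expect_equal(eff2$alpha_1, 272 / 360, tolerance = 1e-12)
  expect_equal(eff2$alpha_1, 0.7556, tolerance = 1e-4)

  # dataset interface: means computed as events / cohort size
  rec <- tibble::tibble(strain_id = rep(c("a", "b"), c(3, 1)),
                        chrom = "chrI", pos = 1:4, ref = "A", alt = "T")
  base <- mutation_dataset(rec, n_strains = 2)
  batch <- mutation_dataset(rec[1:2, ], n_strains = 2)
  eff3 <- batch_effectiveness(base, batch)
  expect_equal(eff3$n_bar_0, 2)
  expect_equal(eff3$n_bar_1, 1)
  expect_equal(eff3$alpha_1, 0.5)

  empty <- mutation_dataset(rec[0, ], n_strains = 2)
  expect_error(batch_effectiveness(base, empty), "no events")
})

test_that("sequence probability sums per-base P over interval unions", {
  map <- prob_map(list(chrI = rep(0.001, 1000), chrII = rep(0.002, 500)))
  iv <- tibble::tibble(chrom = "chrI", start = 1, end = 1000)
  expect_equal(seq_probability(map, iv), 1.0)
  expect_equal(seq_probability(map, iv[0, ]), 0)

  # split intervals sum like their union scanned base by base
  split_iv <- tibble::tibble(chrom = c("chrI", "chrI", "chrII"),
                             start = c(1, 501, 10), end = c(500, 1000, 20))
  union_manual <- sum(map$values$chrI[1:1000]) + sum(map$values$chrII[10:20])
  expect_equal(seq_probability(map, split_iv), union_manual)

  # overlap within a gene is not double counted
  ov <- tibble::tibble(chrom = "chrI", start = c(1, 400), end = c(500, 600))
  expect_equal(seq_probability(map, ov), sum(map$values$chrI[1:600]))

  expect_error(seq_probability(
    map, tibble::tibble(chrom = "chrI", start = 900, end = 1100)),
    "outside map")
})

test_that("expected count is n_strains x P_seq and additive over intervals", {
  map <- prob_map(list(chrI = rep(0.001, 1000)))
  iv <- tibble::tibble(chrom = "chrI", start = 1, end = 1000)
  expect_equal(expected_count(map, iv, 38), 38)
  expect_equal(expected_count(map, iv, 1), 1)
  expect_error(expected_count(map, iv, 0), "n_strains")

  parts <- list(
    tibble::tibble(chrom = "chrI", start = 1, end = 300),
    tibble::tibble(chrom = "chrI", start = 301, end = 1000)
  )
  expect_equal(sum(vapply(parts, expected_count, numeric(1), map = map,
                          n_strains = 7)),
               expected_count(map, iv, 7), tolerance = 1e-12)
})

test_that("Monte-Carlo mean of simulated counts matches E within 3 SE", {
  st <- fixture_study(length = 20000, n_strains = 10, seed = 61)
  tm <- truth_map(st$truth)
  iv <- tibble::tibble(chrom = "chrI", start = 2001, end = 6000)
  E <- expected_count(tm, iv, 10)
  p <- tm$values$chrI[2001:6000]
  n_rep <- 1000
  counts <- withr::with_seed(62, {
    vapply(seq_len(n_rep), function(i) {
      sum(rbinom(length(p), 10, p))
    }, numeric(1))
  })
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - E), 3 * se)
})

test_that("background removal thresholds on the shared-strain fraction", {
  mk <- function(n_share, n_total = 38) {
    shared <- tibble::tibble(strain_id = sprintf("s%02d", seq_len(n_share)),
                             chrom = "chrI", pos = 100L, ref = "G",
                             alt = "A")
    lone <- tibble::tibble(strain_id = "s01", chrom = "chrI", pos = 200L,
                           ref = "C", alt = "T")
    mutation_dataset(dplyr::bind_rows(shared, lone), n_strains = n_total)
  }
  # 10/38 >= 0.25: removed; the private variant survives
  out <- suppressMessages(remove_background(mk(10), share_frac = 0.25))
  expect_equal(out$pos, 200L)
  expect_equal(n_strains(out), 38L)
  # 1/38 < 0.25: kept
  out2 <- suppressMessages(remove_background(mk(1), share_frac = 0.25))
  expect_equal(sort(out2$pos), c(100L, 200L))
  # share_frac 1: only variants in every strain removed
  out3 <- suppressMessages(remove_background(mk(38), share_frac = 1))
  expect_equal(out3$pos, 200L)
  out4 <- suppressMessages(remove_background(mk(37), share_frac = 1))
  expect_equal(sort(out4$pos), c(rep(100L, 37), 200L))
})

test_that("Poisson tail p-values match the exact Poisson-binomial on a toy gene", {
  set.seed(63)
  L <- 400
  p <- runif(L, 1e-4, 4e-4)
  map <- prob_map(list(chrI = p))
  genes <- tibble::tibble(gene_id = "g1", chrom = "chrI",
                          start = 1L, end = L)
  n <- 15L
  obs <- 9L
  pool <- mutation_dataset(
    tibble::tibble(strain_id = sprintf("s%02d", seq_len(obs)),
                   chrom = "chrI", pos = sample.int(L, obs),
                   ref = "G", alt = "A"),
    n_strains = n
  )
  exact <- gene_enrichment(pool, genes, map, n_strains = n, mode = "exact")
  pois <- gene_enrichment(pool, genes, map, n_strains = n, mode = "poisson")
  # small-p, many-trials regime: Poisson approximates the exact tail well
  expect_equal(exact$p_value, pois$p_value, tolerance = 0.05)

  # independent brute-force Poisson-binomial summation for the same gene
  pmf <- Reduce(function(acc, pi) {
    c(acc * (1 - pi), 0) + c(0, acc * pi)
  }, rep(p, n), accumulate = FALSE, init = 1)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  upper <- sum(pmf[(obs + 1):length(pmf)])
  lower <- sum(pmf[1:(obs + 1)])
  expect_equal(exact$p_value, min(1, 2 * min(lower, upper)),
               tolerance = 1e-12)
  # matches the Poisson two-sided doubled tail at the same expectation
  E <- exact$expected
  expect_equal(pois$p_value,
               min(1, 2 * min(ppois(obs, E),
                              ppois(obs - 1, E, lower.tail = FALSE))),
               tolerance = 1e-12)
})

test_that("enrichment bookkeeping: folds, identities, untested genes", {
  map <- prob_map(list(chrI = rep(1e-4, 4000)))
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chrI",
                          start = c(1L, 1001L, 2001L),
                          end = c(1000L, 2000L, 3000L))
  pool <- mutation_dataset(
    tibble::tibble(strain_id = sprintf("s%02d", 1:5), chrom = "chrI",
                   pos = c(10L, 20L, 30L, 40L, 1500L), ref = "G", alt = "A",
                   impact = c("missense", "missense", "stop_gain",
                              "synonymous", "missense")),
    n_strains = 10
  )
  enr <- gene_enrichment(pool, genes, map, n_strains = 10)
  expect_equal(enr$expected, rep(1e-4 * 1000 * 10, 3))
  expect_equal(enr$fold_change * enr$expected, enr$observed,
               tolerance = 1e-12)
  g3 <- enr[enr$gene_id == "g3", ]
  expect_equal(g3$observed, 0L)
  expect_true(is.na(g3$p_value))        # untested: no observed mutations
  expect_true(all(enr$q_value >= enr$p_value, na.rm = TRUE))
  g1 <- enr[enr$gene_id == "g1", ]
  expect_equal(g1$high_impact, 3L)      # 2 missense + 1 stop_gain

  # alpha doubles expectations, observed untouched
  enr2 <- gene_enrichment(pool, genes, map, alpha = 2, n_strains = 10)
  expect_equal(enr2$expected, 2 * enr$expected)
  expect_equal(enr2$observed, enr$observed)
})

test_that("observed equal to expected gives fold 1 and p near 1", {
  map <- prob_map(list(chrI = rep(1e-3, 1000)))
  genes <- tibble::tibble(gene_id = "g1", chrom = "chrI", start = 1L,
                          end = 1000L)
  pool <- mutation_dataset(
    tibble::tibble(strain_id = sprintf("s%02d", 1:10), chrom = "chrI",
                   pos = sample.int(1000, 10), ref = "G", alt = "A"),
    n_strains = 10
  )  # E = 10, observed = 10
  enr <- gene_enrichment(pool, genes, map, n_strains = 10)
  expect_equal(enr$fold_change, 1)
  expect_gt(enr$p_value, 0.8)
})

test_that("BH q-values match a brute-force implementation", {
  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(64)
  map <- prob_map(list(chrI = rep(2e-5, 50000)))
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:50), chrom = "chrI",
                          start = seq(1L, 49001L, by = 1000L),
                          end = seq(1000L, 50000L, by = 1000L))
  pool <- mutation_dataset(
    tibble::tibble(strain_id = sample(sprintf("s%02d", 1:20), 120,
                                      replace = TRUE),
                   chrom = "chrI", pos = sample.int(50000, 120),
                   ref = "G", alt = "A"),
    n_strains = 20
  )
  enr <- gene_enrichment(pool, genes, map, n_strains = 20)
  tested <- !is.na(enr$p_value)
  expect_equal(enr$q_value[tested], brute_bh(enr$p_value[tested]),
               tolerance = 1e-12)
})

test_that("impact profile counts classes and per-strain incidence", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chrI",
                          start = c(1L, 1001L), end = c(1000L, 2000L))
  pool <- mutation_dataset(
    tibble::tibble(
      strain_id = c("s1", "s1", "s2", "s3"),
      chrom = "chrI", pos = c(10L, 500L, 600L, 1500L),
      ref = c("G", "C", "G", "A"),
      alt = c("A", "T", "GA", "T"),
      impact = c("missense", "synonymous", NA, "stop_gain")
    ),
    n_strains = 3
  )
  prof <- impact_profile(pool, genes)
  g1 <- prof$counts[prof$counts$gene_id == "g1", ]
  expect_equal(g1$n_missense, 1L)
  expect_equal(g1$n_synonymous, 1L)
  expect_equal(g1$n_InDel, 1L)
  expect_equal(g1$high_impact, 2L)  # missense + InDel
  g2 <- prof$counts[prof$counts$gene_id == "g2", ]
  expect_equal(g2$high_impact, 1L)  # stop_gain
  inc <- prof$incidence
  expect_setequal(inc$strain_id[inc$gene_id == "g1"], c("s1", "s2"))

  # empty gene gives all-zero counts
  empty <- impact_profile(pool, tibble::tibble(gene_id = "g9",
                                               chrom = "chrI",
                                               start = 5000L, end = 6000L))
  expect_equal(empty$counts$high_impact, 0L)
  expect_equal(sum(dplyr::select(empty$counts, -gene_id)), 0L)
})
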