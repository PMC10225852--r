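test_that("the convergence correlation behaves as a correlation", {
  d <- c(0.1, -0.2, 0.3)
  expect_equal(conv_cor(d, d), 1.0)
  expect_equal(conv_cor(d, -d), -1.0)
  # frozen value from an independent step-by-step computation of
  # cov/sqrt(var*var) with n-1 denominators
  expect_equal(conv_cor(c(0.10, 0.00, -0.10, 0.20),
                        c(0.05, 0.10, -0.20, 0.10)),
               0.764093177458, tolerance = 1e-10)
  # audit flag: the literal printed form divides by var*var
  expect_equal(conv_cor(c(0.10, 0.00, -0.10, 0.20),
                        c(0.05, 0.10, -0.20, 0.10), literal = TRUE),
               41.2121212121, tolerance = 1e-8)
  expect_error(conv_cor(c(0, 0, 0), d), "degenerate")
  expect_error(conv_cor(0.1, 0.2), "at least 2")
  # symmetry in arguments
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(conv_cor(x, y), conv_cor(y, x))
})

test_that("conv_cor equals the Pearson correlation on random vectors", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:200, 1)
    x <- rnorm(n, sd = runif(1, 0.01, 1))
    y <- 0.3 * x + rnorm(n)
    expect_equal(conv_cor(x, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("conv_cor is invariant to common permutation and positive scaling", {
  set.seed(8)
  x <- rnorm(100); y <- rnorm(100) + 0.5 * x
  base <- conv_cor(x, y)
  for (rep in 1:5) {
    p <- sample(100)
    expect_equal(conv_cor(x[p], y[p]), base)
    a <- runif(1, 0.1, 10)
    expect_equal(conv_cor(a * x, a * y), base)
  }
})

test_that("percentile bootstrap interval is seeded, bounded and sane", {
  set.seed(13)
  x <- rnorm(200); y <- 0.4 * x + rnorm(200)
  ci1 <- conv_cor_boot(x, y, n_boot = 100, seed = 42)
  ci2 <- conv_cor_boot(x, y, n_boot = 100, seed = 42)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["ci_low"]], ci1[["ci_high"]])
  expect_length(attr(ci1, "boot"), 100)
  # perfectly correlated vectors collapse to [1, 1]
  ci3 <- conv_cor_boot(x, x, n_boot = 50, seed = 1)
  expect_equal(c(ci3[["ci_low"]], ci3[["ci_high"]]), c(1, 1))
})

test_that("bootstrap interval covers 0 for independent vectors at ~95%", {
  set.seed(77)
  n_reps <- 60
  cover <- vapply(seq_len(n_reps), function(i) {
    x <- rnorm(300); y <- rnorm(300)
    ci <- conv_cor_boot(x, y, n_boot = 100, seed = i)
    ci[["ci_low"]] <= 0 && ci[["ci_high"]] >= 0
  }, logical(1))
  # 3 binomial SEs around 0.95 with n = 60
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / n_reps))
})

test_that("the four canonical comparisons use the right cohort pairings", {
  # identical tables are degenerate by contract
  f <- allele_frequencies(toy_gm(matrix(sample(0:2, 30, TRUE), 10, 3)))
  same <- list(a_hist = f, a_mod1 = f, a_mod2 = f, b_hist = f, b_mod = f)
  expect_error(canonical_convcors(same, n_boot = 0), "degenerate")
  # synthetic parallel selection: cross-population statistics positive,
  # negative control near zero
  cfg <- synthetic_config(n_loci = 4000, Ne = 1e5, gens = 12, pi_sel = 1,
                          s_bar = 0.6, n_sample = 50, seed = 101)
  g <- synth_generate(cfg)
  cc <- canonical_convcors(g$freqs, n_boot = 100, seed = 5)
  est <- setNames(cc$estimate, cc$name)
  expect_gt(est[["ConvCor_1"]], 0.3)
  expect_gt(est[["ConvCor_2"]], 0.3)
  expect_lt(abs(est[["ConvCor_4"]]), 0.1)
  expect_equal(cc$n_loci, rep(4000L, 4))
  expect_true(all(cc$ci_low <= cc$ci_high))
})

test_that("null replicates centre the statistic at zero and ConvCor_3 at 0.5", {
  # independent drift, no selection: conv_cor over replicates centred at 0
  vals <- vapply(1:200, function(i) {
    g <- synth_generate(synthetic_config(n_loci = 400, Ne = 2000, gens = 10,
                                         seed = 1000 + i))
    conv_cor(freq_delta(g$freqs$b_hist, g$freqs$b_mod),
             freq_delta(g$freqs$a_hist, g$freqs$a_mod1))
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 1e-8)
  # shared-baseline control: corr -> var0/(var0+var1) = 0.5 with equal
  # sampling variances and negligible drift between the modern pair
  g <- synth_generate(synthetic_config(n_loci = 1e5, Ne = 1e6, gens = 2,
                                       seed = 31))
  cc3 <- conv_cor(freq_delta(g$freqs$a_hist, g$freqs$a_mod1),
                  freq_delta(g$freqs$a_hist, g$freqs$a_mod2))
  expect_equal(cc3, 0.5, tolerance = 0.03)
})

test_that("stratified statistics equal direct Pearson on the subsets", {
  set.seed(17)
  n <- 60
  calls0 <- matrix(sample(0:2, n * 6, TRUE), n, 6)
  calls1 <- matrix(sample(0:2, n * 6, TRUE), n, 6)
  chrom <- rep(c("LG01", "LG02"), each = n / 2)
  g0 <- toy_gm(calls0); g1 <- toy_gm(calls1)
  g0$loci$chrom <- g1$loci$chrom <- chrom
  g0$loci$locus_id <- g1$loci$locus_id <-
    paste0(chrom, ":", g0$loci$pos)
  rownames(g0$calls) <- rownames(g1$calls) <- g0$loci$locus_id
  d1 <- freq_delta(allele_frequencies(g0), allele_frequencies(g1))
  set.seed(18)
  calls2 <- matrix(sample(0:2, n * 6, TRUE), n, 6)
  d2 <- freq_delta(allele_frequencies(g0),
                   allele_frequencies({g2 <- g0; g2$calls <- calls2
                                       storage.mode(g2$calls) <- "integer"
                                       g2}))
  res <- stratified_convcor(d1, d2, chrom_strata(g0$loci), n_boot = 0)
  expect_equal(res$stratum, c("genome-wide", "LG01", "LG02"))
  for (lg in c("LG01", "LG02")) {
    sel <- d1$chrom == lg
    expect_equal(res$estimate[res$stratum == lg],
                 cor(d1$delta[sel], d2$delta[sel]))
  }
  # all loci in one region: inside equals genome-wide, outside undefined
  rg <- data.frame(chrom = c("LG01", "LG02"), start = 0L,
                   end = max(g0$loci$pos) + 1L, label = "inv")
  st <- region_strata(g0$loci, rg)
  res2 <- stratified_convcor(d1, d2, st[c("inside", "outside")], n_boot = 0)
  expect_equal(res2$estimate[res2$stratum == "inside"],
               res2$estimate[res2$stratum == "genome-wide"])
  expect_true(is.na(res2$estimate[res2$stratum == "outside"]))
  expect_equal(res2$n_loci[res2$stratum == "outside"], 0L)
})
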