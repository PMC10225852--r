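test_that("rescaling preserves compound parameters and applies the guard", {
  cfg <- demography_config()
  mod <- mutation_model("three_type")
  # identity at Q = 1
  r1 <- rescale_scenario(cfg, mod, 1)
  expect_identical(r1$config, cfg)
  # arithmetic at Q = 10 on the defaults
  r10 <- rescale_scenario(cfg, mod, 10)
  expect_equal(r10$config$N_anc, 700L)
  expect_equal(r10$config$T_burn, 5740L)
  expect_equal(r10$config$N_final, 3500L)
  expect_equal(r10$config$mu, 1.64e-7)
  expect_equal(r10$config$r, 1.5e-6)
  expect_equal(r10$config$m, 1e-3)
  expect_equal(r10$model$dfe_mean, -0.5)
  # theta per site identical to 8 significant figures
  th <- function(c) 4 * c$N_anc * c$mu
  expect_equal(signif(th(r10$config), 8), signif(th(cfg), 8))
  expect_equal(4 * r10$config$N_anc * r10$config$r,
               4 * cfg$N_anc * cfg$r)
  # over-rescaling guard
  expect_error(rescale_scenario(cfg, mod, 1000), "below 50")
})

test_that("fitness is recessive for deleterious loci and Gaussian in the QTL phenotype", {
  mod <- mutation_model("three_type", omega = 5)
  # no mutations -> fitness 1
  expect_equal(sim_fitness(integer(), character(), numeric(), mod), 1)
  # completely recessive s = -0.5: heterozygote unaffected, homozygote 0.5
  expect_equal(sim_fitness(1L, "deleterious", -0.5, mod),
               exp(0)) # phenotype 0 -> stabilizing factor 1
  expect_equal(sim_fitness(2L, "deleterious", -0.5, mod), 0.5)
  # two opposite QTL effects cancel at the optimum
  expect_equal(sim_fitness(c(2L, 2L), c("qtl", "qtl"), c(1, -1), mod), 1)
  # a single heterozygous QTL effect pays the Gaussian cost
  expect_equal(sim_fitness(1L, "qtl", 1, mod), exp(-1 / (2 * 25)))
  # dominance h > 0 penalizes heterozygotes
  mod_h <- mutation_model("three_type", dominance = 0.5)
  expect_equal(sim_fitness(1L, "deleterious", -0.5, mod_h), 0.75)
  # fitness floored at zero for s < -1 homozygotes
  expect_equal(sim_fitness(2L, "deleterious", -1.5, mod), 0)
})

test_that("identical seeds reproduce a run bit-for-bit", {
  cfg <- tiny_config()
  mod <- mutation_model("neutral_only")
  s1 <- run_scenario(cfg, mod, seed = 5)
  s2 <- run_scenario(cfg, mod, seed = 5)
  expect_identical(s1$registry, s2$registry)
  for (nm in names(s1$cohorts))
    expect_identical(s1$cohorts[[nm]]$calls, s2$cohorts[[nm]]$calls)
  s3 <- run_scenario(cfg, mod, seed = 6)
  expect_false(identical(s1$registry, s3$registry))
})

test_that("census sizes follow the demographic schedule exactly when m = 0", {
  cfg <- tiny_config(m = 0)
  s <- run_scenario(cfg, mutation_model("neutral_only"), seed = 9)
  g <- (cfg$N_final / cfg$N_anc)^(1 / cfg$T_growth)
  sched <- pmin(cfg$N_final, floor(cfg$N_anc * g^(1:cfg$T_post) + 0.5))
  sched[(1:cfg$T_post) >= cfg$T_growth] <- cfg$N_final
  expect_equal(s$census[, 1], sched)
  expect_equal(s$census[, 2], sched)
})

test_that("without migration the subpopulations share only pre-split variants", {
  cfg <- tiny_config(m = 0)
  s <- run_scenario(cfg, mutation_model("neutral_only"), seed = 13)
  reg <- classify_origin(s$registry, s$split_gen)
  shared <- !is.na(reg$freq_pop1) & !is.na(reg$freq_pop2) &
    reg$freq_pop1 > 0 & reg$freq_pop2 > 0 & !reg$fixed
  expect_true(all(reg$epoch[shared] == "before"))
})

test_that("panmixia drives contemporary spatial Fst to zero", {
  vals <- vapply(1:3, function(i) {
    s <- run_scenario(tiny_config(m = 0.5), mutation_model("neutral_only"),
                      seed = 16 + i)
    summarize_replicate(s)$fst_spatial_mod
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.04)
})

test_that("single-population neutral diversity matches theta/(1+theta)", {
  # per-site pairwise diversity at mutation-drift equilibrium
  cfg <- demography_config(N_anc = 50, T_burn = 1500, T_growth = 1,
                           N_final = 50, m = 0, L = 2e4, r = 5e-4,
                           mu = 1e-5, t_hist1 = 1, t_hist2 = 1, t_mod = 1,
                           n_sample = 20)
  cohorts <- data.frame(name = "anc", pop = 0L, time = cfg$T_burn,
                        n_sample = 20L)
  pis <- vapply(1:3, function(i) {
    s <- run_scenario(cfg, mutation_model("neutral_only"), seed = 100 + i,
                      cohorts = cohorts)
    calls <- s$cohorts$anc$calls
    n <- 2 * ncol(calls)
    p <- rowSums(calls) / n
    sum(2 * p * (1 - p) * n / (n - 1)) / cfg$L
  }, numeric(1))
  theta <- 4 * cfg$N_anc * cfg$mu
  expect_equal(mean(pis), theta / (1 + theta), tolerance = 0.3)
})

test_that("exported VCF frequencies equal registry-tracked sample tallies", {
  s <- cached_sim("tiny_neutral", {
    run_scenario(tiny_config(), mutation_model("neutral_only"), seed = 3)
  })
  dir <- tempfile()
  paths <- export_vcf(s, dir)
  expect_true(file.exists(paths[["registry"]]))
  gm <- s$cohorts$b_mod
  back <- read_vcf(paths[["b_mod"]], list(gm$cohort))[[1]]
  expect_equal(unname(back$calls), unname(gm$calls))
  # per-locus sample tallies equal dosage sums in the original object
  ft <- allele_frequencies(back)
  expect_equal(ft$alt_count, unname(rowSums(gm$calls)))
})
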