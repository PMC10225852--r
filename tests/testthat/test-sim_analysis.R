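test_that("origin-epoch classification follows the split boundary and origin pop", {
  reg <- data.frame(mut_id = 1:4,
                    origin_gen = c(99L, 100L, 50L, 120L),
                    origin_pop = c("ancestral", "ancestral", "subpop1",
                                   "subpop2"),
                    stringsAsFactors = FALSE)
  out <- classify_origin(reg, split_gen = 100L)
  # origin_gen = split - 1 -> before; at split -> after
  expect_equal(out$epoch, c("before", "after", "after", "after"))
  # subpopulation origin is "after" regardless of the clock
  expect_equal(out$epoch[3], "after")
})

test_that("toy registry counts match hand enumeration", {
  set.seed(41)
  reg <- data.frame(mut_id = 1:10,
                    origin_gen = c(10L, 20L, 99L, 100L, 101L, 30L, 40L,
                                   150L, 160L, 70L),
                    origin_pop = c(rep("ancestral", 5), "ancestral",
                                   "ancestral", "subpop1", "subpop2",
                                   "ancestral"),
                    stringsAsFactors = FALSE)
  out <- classify_origin(reg, 100L)
  expect_equal(sum(out$epoch == "before"), 6L)
})

test_that("origin summary matches a spreadsheet oracle on six variants", {
  reg <- data.frame(
    mut_id = 1:6,
    type = c("neutral", "neutral", "deleterious", "qtl", "qtl", "neutral"),
    coeff = c(0, 0, -0.2, 0.8, -1.1, 0),
    origin_gen = c(10L, 150L, 20L, 30L, 160L, 40L),
    origin_pop = c("ancestral", "subpop1", "ancestral", "ancestral",
                   "subpop2", "ancestral"),
    fixed = FALSE,
    freq_pooled = c(0.30, 0.02, 0.10, 0.60, 0.04, 0.00),
    stringsAsFactors = FALSE)
  os <- origin_summary(reg, split_gen = 100L, maf_cut = 0.05)
  bt <- os$by_type
  # locus 6 is lost (freq 0) -> not segregating
  expect_equal(bt$n_segregating[bt$type == "all"], 5L)
  expect_equal(bt$fraction_before_split[bt$type == "all"], 3 / 5)
  expect_equal(bt$n_segregating[bt$type == "neutral"], 2L)
  expect_equal(bt$fraction_before_split[bt$type == "neutral"], 1 / 2)
  expect_equal(bt$mean_freq_before[bt$type == "neutral"], 0.30)
  expect_equal(bt$mean_freq_after[bt$type == "neutral"], 0.02)
  expect_equal(bt$mean_freq_before[bt$type == "qtl"], 0.60)
  expect_equal(bt$mean_freq_after[bt$type == "qtl"], 0.04)
  # variants with freq > 0.05: loci 1, 3, 4, all pre-split
  expect_equal(os$frac_before_highfreq, 1)
  # registries where everything predates the split
  reg2 <- reg[reg$origin_pop == "ancestral" & reg$origin_gen < 100, ]
  os2 <- origin_summary(reg2, 100L)
  expect_true(all(os2$by_type$fraction_before_split[
    os2$by_type$n_segregating > 0] == 1))
})

test_that("older segregating variants sit at higher frequencies in real runs", {
  s <- cached_sim("tiny_three_type", {
    run_scenario(tiny_config(m = 1e-3),
                 mutation_model("three_type"), seed = 19)
  })
  os <- origin_summary(s$registry, s$split_gen)
  bt <- os$by_type
  ok <- !is.na(bt$mean_freq_before) & !is.na(bt$mean_freq_after)
  expect_true(any(ok))
  expect_true(all(bt$mean_freq_before[ok] > bt$mean_freq_after[ok]))
})

test_that("grid summaries keep replicate bookkeeping and grouping keys", {
  reps <- cached_sim("tiny_grid", {
    unlist(lapply(c(1e-3, 1e-1), function(m)
      lapply(1:3, function(i)
        run_scenario(tiny_config(m = m), mutation_model("neutral_only"),
                     seed = 300 + 10 * i + round(1000 * m)))),
      recursive = FALSE)
  })
  gs <- migration_grid_summary(reps)
  expect_equal(nrow(gs$per_replicate), 6L)
  expect_setequal(unique(gs$per_replicate$m), c(1e-3, 1e-1))
  expect_equal(nrow(gs$per_scenario), 2L)
  expect_true(all(c("fst_spatial_mod_mean", "convcor_1_mean",
                    "convcor_3_q25") %in% names(gs$per_scenario)))
  # well-mixed scenario: spatial differentiation vanishes and the four
  # statistics are all defined
  hi <- gs$per_scenario[gs$per_scenario$m == 1e-1, ]
  expect_lt(hi$fst_spatial_mod_mean, 0.02)
  expect_true(all(is.finite(unlist(
    hi[paste0("convcor_", 1:4, "_mean")]))))
})

test_that("summaries computed from exported VCFs match in-memory summaries", {
  s <- cached_sim("tiny_neutral", {
    run_scenario(tiny_config(), mutation_model("neutral_only"), seed = 3)
  })
  direct <- summarize_replicate(s)
  dir <- tempfile()
  export_vcf(s, dir)
  back <- lapply(names(s$cohorts), function(nm)
    read_vcf(file.path(dir, paste0(nm, ".vcf")),
             list(s$cohorts[[nm]]$cohort))[[1]])
  names(back) <- names(s$cohorts)
  s2 <- s
  s2$cohorts <- back
  rt <- summarize_replicate(s2)
  expect_equal(rt[, -(1:2)], direct[, -(1:2)], tolerance = 1e-12)
})
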