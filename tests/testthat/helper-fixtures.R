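# fixtures built in code: toy genotype matrices, a multi-sample VCF writer
# and small cached simulation runs shared across test files

toy_loci <- function(n, chrom = "LG01") {
  data.frame(chrom = chrom, pos = seq_len(n) * 100L, ref = "A", alt = "T",
             locus_id = paste0(chrom, ":", seq_len(n) * 100L),
             multiallelic = FALSE, stringsAsFactors = FALSE)
}

toy_gm <- function(calls, population = "pop", time_label = 2000,
                   qualities = NULL, chrom = "LG01") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  loci <- toy_loci(nrow(calls), chrom)
  ids <- paste0(population, time_label, "_i", seq_len(ncol(calls)))
  colnames(calls) <- ids
  genotype_matrix(loci, cohort_spec(population, time_label, ids), calls,
                  qualities)
}

# one multi-sample VCF containing all five toy cohorts (2 individuals each)
write_toy_study_vcf <- function(path, n_loci = 40, seed = 99,
                                with_gq = TRUE) {
  set.seed(seed)
  n_ind <- 10L
  p <- runif(n_loci, 0.15, 0.85)
  calls <- sapply(seq_len(n_ind), function(i) rbinom(n_loci, 2, p))
  storage.mode(calls) <- "integer"
  qual <- if (with_gq)
    matrix(sample(c(20L, 40L, 50L), n_loci * n_ind, TRUE,
                  prob = c(0.1, 0.5, 0.4)), n_loci) else NULL
  ids <- paste0("s", seq_len(n_ind))
  gm <- genotype_matrix(toy_loci(n_loci), cohort_spec("all", NA, ids),
                        calls, qual)
  write_vcf(gm, path)
  roles <- c("a_hist", "a_mod1", "a_mod2", "b_hist", "b_mod")
  design <- lapply(seq_along(roles), function(k)
    cohort_spec(if (k <= 3) "A" else "B", roles[k],
                ids[c(2 * k - 1, 2 * k)]))
  names(design) <- roles
  design
}

# tiny neutral scenario that runs in well under a second
tiny_config <- function(m = 1e-3, ...) {
  demography_config(N_anc = 60, T_burn = 240, T_growth = 24, N_final = 120,
                    m = m, L = 1e5, r = 1e-6, mu = 1e-6, t_hist1 = 20,
                    t_hist2 = 24, t_mod = 30, n_sample = 10, ...)
}

# cached desk-scale runs shared across test files (computed at most once
# per test session)
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

desk_replicates <- function(m, n_reps, seed_base, model = NULL, Q = 50) {
  key <- paste0("m", m, "_n", n_reps, "_s", seed_base, "_",
                if (is.null(model)) "neutral" else model$mode, "_Q", Q)
  cached_sim(key, {
    model <- model %||% mutation_model("neutral_only")
    sc <- desk_scenario(m = m, model = model, Q = Q)
    lapply(seq_len(n_reps), function(i)
      run_scenario(sc$config, sc$model, seed = seed_base + i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar step-by-step transcription of the Weir & Cockerham (1984)
# two-population variance components, used as an independent oracle
wc_oracle_locus <- function(geno1, geno2) {
  n1 <- sum(!is.na(geno1)); n2 <- sum(!is.na(geno2))
  p1 <- sum(geno1, na.rm = TRUE) / (2 * n1)
  p2 <- sum(geno2, na.rm = TRUE) / (2 * n2)
  h1 <- sum(geno1 == 1, na.rm = TRUE) / n1
  h2 <- sum(geno2 == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}
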