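#' Demographic parameters for the two-population forward simulation
#'
#' Defaults mirror the Atlantic-cod history used throughout: an ancestral
#' population of 7000 diploids simulated for 57 400 burn-in generations,
#' splitting into two subpopulations that grow at a constant multiplicative
#' rate over 6530 generations to 35 000 each, with symmetric per-individual
#' migration after the split; a single 5 Mb chromosome with per-base
#' recombination 1.5e-7 and mutation 1.64e-8; cohorts of 20 diploids sampled
#' at 6525 (subpop1 historic), 6530 (subpop2 historic) and 6540 generations
#' post-split (two subpop1 + one subpop2 contemporary samples).
#'
#' @param N_anc ancestral diploid size.
#' @param T_burn burn-in generations before the split.
#' @param T_growth post-split growth duration (generations).
#' @param N_final final diploid size per subpopulation.
#' @param m per-individual per-generation migration probability.
#' @param L chromosome length (bases).
#' @param r per-base per-generation recombination rate.
#' @param mu per-base per-generation mutation rate.
#' @param t_hist1,t_hist2,t_mod sampling generations (post-split) for the
#'   subpop1 historic, subpop2 historic and the three contemporary cohorts.
#' @param n_sample diploid individuals per cohort.
#' @param Q rescaling factor already applied (bookkeeping; see
#'   [rescale_scenario()]).
#' @param linear_growth use linear instead of exponential growth.
#' @param prune_every generations between fixed-mutation sweeps (an
#'   implementation interval, not a biological parameter).
#' @return an object of class `demography_config`.
#' @export
demography_config <- function(N_anc = 7000, T_burn = 57400, T_growth = 6530,
                              N_final = 35000, m = 1e-4, L = 5e6,
                              r = 1.5e-7, mu = 1.64e-8,
                              t_hist1 = 6525, t_hist2 = 6530, t_mod = 6540,
                              n_sample = 20, Q = 1,
                              linear_growth = FALSE, prune_every = 20) {
  cfg <- list(N_anc = as.integer(N_anc), T_burn = as.integer(T_burn),
              T_growth = as.integer(T_growth), N_final = as.integer(N_final),
              m = m, L = L, r = r, mu = mu,
              t_hist1 = as.integer(t_hist1), t_hist2 = as.integer(t_hist2),
              t_mod = as.integer(t_mod), n_sample = as.integer(n_sample),
              Q = Q, linear_growth = linear_growth,
              prune_every = as.integer(prune_every))
  if (any(unlist(cfg[c("N_anc", "N_final", "L", "mu")]) <= 0))
    stop("sizes and rates must be positive")
  if (cfg$m < 0 || cfg$m > 1) stop("migration probability must be in [0, 1]")
  t_end <- max(cfg$t_hist1, cfg$t_hist2, cfg$t_mod)
  if (cfg$t_mod < cfg$t_hist1 || cfg$t_mod < cfg$t_hist2)
    stop("contemporary samples must not precede historic samples")
  cfg$T_post <- t_end
  structure(cfg, class = "demography_config")
}

#' Mutation-class parameters for the forward simulation
#'
#' In `"three_type"` mode each new mutation is (with equal default
#' probabilities) neutral, recessive deleterious with selection coefficient
#' drawn from a gamma distribution (default mean -0.05, shape 0.5), or a QTL
#' with additive phenotypic effect drawn from N(0, 1) under Gaussian
#' stabilizing selection toward an optimum of 0. `"neutral_only"` makes all
#' mutations neutral.
#'
#' @param mode `"neutral_only"` or `"three_type"`.
#' @param type_probs length-3 probabilities (neutral, deleterious, qtl);
#'   must sum to 1.
#' @param dfe_mean mean selection coefficient of the deleterious class
#'   (negative).
#' @param dfe_shape gamma shape of the deleterious class.
#' @param dominance dominance coefficient h of deleterious mutations
#'   (0 = completely recessive: heterozygotes unaffected).
#' @param qtl_sd standard deviation of QTL phenotypic effects.
#' @param optimum phenotypic optimum of stabilizing selection.
#' @param omega width of the Gaussian fitness function
#'   (`w = exp(-(z - optimum)^2 / (2 omega^2))`).
#' @return an object of class `mutation_model`.
#' @export
mutation_model <- function(mode = c("neutral_only", "three_type"),
                           type_probs = c(1, 1, 1) / 3,
                           dfe_mean = -0.05, dfe_shape = 0.5,
                           dominance = 0, qtl_sd = 1,
                           optimum = 0, omega = 5) {
  mode <- match.arg(mode)
  if (abs(sum(type_probs) - 1) > 1e-8) stop("type_probs must sum to 1")
  if (dfe_shape <= 0 || qtl_sd <= 0 || omega <= 0)
    stop("dfe_shape, qtl_sd and omega must be positive")
  if (dfe_mean >= 0) stop("dfe_mean must be negative")
  structure(list(mode = mode, type_probs = type_probs, dfe_mean = dfe_mean,
                 dfe_shape = dfe_shape, dominance = dominance,
                 qtl_sd = qtl_sd, optimum = optimum, omega = omega),
            class = "mutation_model")
}

#' Rescale a scenario for desk-scale runs
#'
#' Standard population rescaling by a factor `Q`: population sizes and
#' generation counts are divided by `Q` (rounded), while mutation,
#' recombination and migration rates and selection coefficients are
#' multiplied by `Q`, preserving theta = 4 N mu, rho = 4 N r, N m and N s.
#' QTL effect variance is unchanged; the stabilizing-selection width is
#' divided by `sqrt(Q)` so the per-generation selection load on a given
#' phenotype scales by `Q` as well.
#'
#' @param config a [demography_config()].
#' @param model a [mutation_model()].
#' @param Q rescaling factor (`>= 1`); rescaled sizes must stay `>= 50`.
#' @return list with rescaled `config` and `model`.
#' @export
rescale_scenario <- function(config, model, Q) {
  stopifnot(inherits(config, "demography_config"),
            inherits(model, "mutation_model"))
  if (Q < 1) stop("Q must be >= 1")
  if (Q == 1) return(list(config = config, model = model))
  rnd <- function(x) as.integer(floor(x / Q + 0.5))
  N_anc <- rnd(config$N_anc * 1)
  N_final <- rnd(config$N_final * 1)
  if (N_anc < 50 || N_final < 50)
    stop("rescaled population sizes fall below 50; choose a smaller Q")
  cfg <- demography_config(
    N_anc = N_anc, T_burn = max(1L, rnd(config$T_burn)),
    T_growth = max(1L, rnd(config$T_growth)), N_final = N_final,
    m = min(1, config$m * Q), L = config$L, r = config$r * Q,
    mu = config$mu * Q,
    t_hist1 = max(1L, rnd(config$t_hist1)),
    t_hist2 = max(1L, rnd(config$t_hist2)),
    t_mod = max(1L, rnd(config$t_mod)),
    n_sample = config$n_sample, Q = config$Q * Q,
    linear_growth = config$linear_growth, prune_every = config$prune_every)
  mod <- model
  mod$dfe_mean <- model$dfe_mean * Q
  mod$omega <- model$omega / sqrt(Q)
  list(config = cfg, model = mod)
}

#' Desk-scale scenario profile
#'
#' The default reduced-cost profile: the 5 Mb chromosome is cut to `L`
#' (default 0.5 Mb) with the recombination rate raised to keep the
#' chromosome-level rho, then the whole scenario is rescaled by `Q`
#' (default 50).
#'
#' @param m full-scale migration probability (rescaling multiplies it by
#'   `Q`).
#' @param model a [mutation_model()] at full scale.
#' @param Q rescaling factor.
#' @param L reduced chromosome length (bases).
#' @param ... further arguments to [demography_config()] (full scale).
#' @return list with rescaled `config` and `model`.
#' @export
desk_scenario <- function(m = 1e-4, model = mutation_model("neutral_only"),
                          Q = 50, L = 5e5, ...) {
  full <- demography_config(m = m, L = L, r = 1.5e-7 * (5e6 / L), ...)
  rescale_scenario(full, model, Q)
}

default_cohort_table <- function(config) {
  data.frame(
    name = c("a_hist", "b_hist", "a_mod1", "a_mod2", "b_mod"),
    pop = c(1L, 2L, 1L, 1L, 2L),
    time = c(config$t_hist1, config$t_hist2, config$t_mod, config$t_mod,
             config$t_mod),
    n_sample = config$n_sample,
    stringsAsFactors = FALSE)
}

#' Run one forward-simulation scenario
#'
#' Discrete-generation Wright-Fisher life cycle: fitness evaluation, parent
#' sampling proportional to fitness within each subpopulation, meiosis with
#' Poisson(L r) crossovers, Poisson(L mu) new mutations per gamete (typed
#' and recorded in a registry with origin generation and origin
#' subpopulation), post-split migration of each offspring with probability
#' `m`, and sampling of the configured cohorts. Fully reproducible given
#' `seed`.
#'
#' @param config a [demography_config()] (rescaled or full scale).
#' @param model a [mutation_model()].
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG stream).
#' @param cohorts cohort table (columns `name`, `pop` in \{0 ancestral, 1,
#'   2\}, `time` — post-split generation for pops 1-2, absolute burn-in
#'   generation for pop 0 —, `n_sample`); defaults to the five-cohort
#'   design.
#' @return an object of class `sim_sample_set`: list with `cohorts` (named
#'   list of [genotype_matrix()] sharing one locus table), `registry` (data
#'   frame of every mutation that ever arose: `mut_id`, `pos`, `type`,
#'   `coeff`, `origin_gen`, `origin_pop`, `fixed`, final per-subpopulation
#'   and pooled frequencies), `split_gen` (absolute generation of the first
#'   post-split generation), `census`, and scenario metadata.
#' @export
run_scenario <- function(config, model, seed = NULL,
                         cohorts = default_cohort_table(config)) {
  stopifnot(inherits(config, "demography_config"),
            inherits(model, "mutation_model"))
  mem_haps <- 2 * (config$N_anc + 2 * config$N_final) *
    max(1, 4 * config$N_anc * config$mu * config$L)
  if (mem_haps > 5e9)
    stop("requested scale is infeasible in memory; rescale with rescale_scenario()")
  demog <- list(N_anc = config$N_anc, T_burn = config$T_burn,
                T_growth = config$T_growth, T_post = config$T_post,
                N_final = config$N_final, m = config$m, L = config$L,
                r = config$r, mu = config$mu,
                linear_growth = config$linear_growth,
                prune_every = config$prune_every)
  tp <- model$type_probs
  mod <- list(three_type = model$mode == "three_type",
              p_del = tp[2], p_qtl = tp[3],
              del_shape = model$dfe_shape,
              del_scale = abs(model$dfe_mean) / model$dfe_shape,
              dominance = model$dominance, qtl_sd = model$qtl_sd,
              optimum = model$optimum, omega = model$omega)
  res <- with_seed(seed, .run_scenario_cpp(demog, mod, cohorts))

  reg <- res$registry
  reg$type <- c("neutral", "deleterious", "qtl")[reg$type + 1]
  reg$origin_pop <- c("ancestral", "subpop1", "subpop2")[reg$origin_pop + 1]

  # shared locus table over the union of sampled mutations
  all_ids <- sort(unique(unlist(lapply(res$cohorts, `[[`, "mut_id"))))
  pos <- reg$pos[all_ids] + 1L # 1-based
  ord <- order(pos, all_ids)
  all_ids <- all_ids[ord]; pos <- pos[ord]
  loci <- data.frame(chrom = "sim1", pos = pos, ref = "A", alt = "T",
                     locus_id = paste0("m", all_ids),
                     multiallelic = pos %in% pos[duplicated(pos)],
                     stringsAsFactors = FALSE)
  gms <- lapply(seq_len(nrow(cohorts)), function(i) {
    co <- res$cohorts[[i]]
    nm <- cohorts$name[i]
    ns <- cohorts$n_sample[i]
    calls <- matrix(0L, nrow = length(all_ids), ncol = ns)
    calls[match(co$mut_id, all_ids), ] <- co$dosage
    pop_label <- c("ancestral", "subpop1", "subpop2")[cohorts$pop[i] + 1]
    spec <- cohort_spec(pop_label, cohorts$time[i],
                        paste0(nm, "_ind", seq_len(ns)))
    genotype_matrix(loci, spec, calls)
  })
  names(gms) <- cohorts$name
  structure(list(cohorts = gms, registry = reg,
                 split_gen = config$T_burn + 1L,
                 census = res$census, config = config, model = model,
                 seed = seed, m = config$m, Q = config$Q),
            class = "sim_sample_set")
}

#' @export
print.sim_sample_set <- function(x, ...) {
  cat(sprintf(
    "sim_sample_set: %d cohorts over %d sampled loci; %d mutations in registry (m = %g, Q = %g)\n",
    length(x$cohorts), n_loci(x$cohorts[[1]]), nrow(x$registry), x$m, x$Q))
  invisible(x)
}

#' Multiplicative fitness of one diploid genotype
#'
#' Reference implementation of the simulator's fitness model, usable on a
#' plain table of mutations: deleterious mutations act multiplicatively with
#' heterozygote factor `1 + h s` and homozygote factor `1 + s` (floored at
#' 0; `h = 0` makes them completely recessive), QTL effects add
#' dosage-weighted into a phenotype `z` which enters a Gaussian stabilizing
#' component `exp(-(z - optimum)^2 / (2 omega^2))`.
#'
#' @param dosage integer vector of per-mutation dosages in \{0, 1, 2\}.
#' @param type character vector: `"neutral"`, `"deleterious"` or `"qtl"`.
#' @param coeff numeric vector: s for deleterious, beta for QTL.
#' @param model a [mutation_model()].
#' @param z_fixed phenotype offset contributed by fixed QTLs.
#' @return positive scalar fitness.
#' @export
sim_fitness <- function(dosage, type, coeff, model, z_fixed = 0) {
  stopifnot(length(dosage) == length(type), length(type) == length(coeff))
  w <- 1
  z <- z_fixed
  for (i in seq_along(dosage)) {
    d <- dosage[i]
    if (d == 0) next
    if (type[i] == "deleterious") {
      f <- if (d == 2) 1 + coeff[i] else 1 + model$dominance * coeff[i]
      w <- w * max(f, 0)
    } else if (type[i] == "qtl") {
      z <- z + d * coeff[i]
    }
  }
  w <- w * exp(-(z - model$optimum)^2 / (2 * model$omega^2))
  max(w, 0)
}

#' Export a simulated sample set as VCFs plus a registry table
#'
#' Writes one VCF per cohort (positions 1-based, ancestral allele as REF)
#' and a registry TSV (`mut_id`, `pos`, `type`, `coeff`, `origin_gen`,
#' `origin_pop`, final frequencies per subpopulation). A site carrying more
#' than one distinct derived allele in a cohort is emitted as one record per
#' derived allele sharing the position (and flagged multi-allelic in the
#' locus table, so the standard biallelic filter removes it).
#'
#' @param simset a `sim_sample_set`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
export_vcf <- function(simset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(simset$cohorts)) {
    p <- file.path(out_dir, paste0(nm, ".vcf"))
    write_vcf(simset$cohorts[[nm]], p)
    paths[nm] <- p
  }
  rp <- file.path(out_dir, "registry.tsv")
  write_tsv_file(simset$registry, rp)
  paths["registry"] <- rp
  invisible(paths)
}
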