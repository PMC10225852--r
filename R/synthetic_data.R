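#' Configuration for the fast synthetic five-cohort generator
#'
#' A statistical stand-in for the forward simulator: independent loci with a
#' known truth, emulating the five-cohort design (two populations, historic
#' and contemporary samples). Each locus starts from a shared frequency
#' drawn from a MAF-filtered neutral-like spectrum, optionally shifts
#' deterministically under shared directional selection on an additive
#' trait, drifts binomially, and is finally observed through binomial
#' sampling noise of `2 * n_sample` chromosomes per cohort. The two
#' contemporary cohorts of population A are drawn within the same
#' generation (zero drift apart, independent sampling only), which is what
#' makes the fourth canonical comparison a negative control and the third
#' converge to about 0.5 under the null.
#'
#' @param n_loci number of independent loci.
#' @param Ne effective diploid size used for drift.
#' @param gens generations between historic and contemporary samples.
#' @param pi_sel fraction of loci under shared selection.
#' @param s_bar per-generation selection intensity scale.
#' @param effect_sd standard deviation of per-locus effect sizes.
#' @param n_sample diploids per cohort (default 20).
#' @param init initial frequency spectrum: `"one_over_x"` (density
#'   proportional to 1/x truncated to `[maf_bound, 1 - maf_bound]`) or
#'   `"uniform"`.
#' @param maf_bound truncation bound of the initial spectrum.
#' @param shared_frac fraction of selected loci whose effect direction is
#'   shared between the populations (1 = fully parallel).
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_loci = 10000, Ne = 5000, gens = 15,
                             pi_sel = 0, s_bar = 0, effect_sd = 1,
                             n_sample = 20,
                             init = c("one_over_x", "uniform"),
                             maf_bound = 0.05, shared_frac = 1,
                             seed = NULL) {
  init <- match.arg(init)
  stopifnot(n_loci >= 1, Ne >= 1, gens >= 0, pi_sel >= 0, pi_sel <= 1,
            s_bar >= 0, effect_sd > 0, n_sample >= 1,
            shared_frac >= 0, shared_frac <= 1)
  structure(list(n_loci = as.integer(n_loci), Ne = as.integer(Ne),
                 gens = as.integer(gens), pi_sel = pi_sel, s_bar = s_bar,
                 effect_sd = effect_sd, n_sample = as.integer(n_sample),
                 init = init, maf_bound = maf_bound,
                 shared_frac = shared_frac, seed = seed),
            class = "synthetic_config")
}

#' Generate one synthetic five-cohort data set with known truth
#'
#' @param config a [synthetic_config()].
#' @return list with `freqs` (named list of five `freq_table`s: `a_hist`,
#'   `a_mod1`, `a_mod2`, `b_hist`, `b_mod`) and `truth` (list: `p0`,
#'   `selected`, `beta`, per-population terminal frequencies `pA`, `pB`,
#'   and `n_clamped`, the count of deterministic shifts clamped at the
#'   frequency boundary).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_loci
    p0 <- if (config$init == "one_over_x")
      exp(stats::runif(n, log(config$maf_bound), log(1 - config$maf_bound)))
    else stats::runif(n, config$maf_bound, 1 - config$maf_bound)
    selected <- stats::rbinom(n, 1, config$pi_sel) == 1
    beta <- ifelse(selected, stats::rnorm(n, 0, config$effect_sd), 0)
    shared <- stats::rbinom(n, 1, config$shared_frac) == 1
    betaB <- ifelse(shared, beta,
                    ifelse(selected, stats::rnorm(n, 0, config$effect_sd), 0))
    n_clamped <- 0L
    evolve <- function(p, b) {
      for (g in seq_len(config$gens)) {
        shift <- config$s_bar * b * p * (1 - p)
        p2 <- p + shift
        clamped <- p2 < 0 | p2 > 1
        n_clamped <<- n_clamped + sum(clamped)
        p2 <- pmin(pmax(p2, 0), 1)
        p <- stats::rbinom(n, 2 * config$Ne, p2) / (2 * config$Ne)
      }
      p
    }
    pA <- evolve(p0, beta)
    pB <- evolve(p0, betaB)
    chroms <- 2L * config$n_sample
    loci <- data.frame(chrom = "syn", pos = seq_len(n),
                       locus_id = paste0("s", seq_len(n)),
                       stringsAsFactors = FALSE)
    draw <- function(p, population, time_label) {
      alt <- stats::rbinom(n, chroms, p)
      out <- data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
                        pos = loci$pos, alt_count = alt,
                        called_chroms = chroms, freq = alt / chroms,
                        stringsAsFactors = FALSE)
      attr(out, "population") <- population
      attr(out, "time_label") <- time_label
      class(out) <- c("freq_table", "data.frame")
      out
    }
    freqs <- list(a_hist = draw(p0, "A", "historic"),
                  a_mod1 = draw(pA, "A", "modern1"),
                  a_mod2 = draw(pA, "A", "modern2"),
                  b_hist = draw(p0, "B", "historic"),
                  b_mod = draw(pB, "B", "modern"))
    list(freqs = freqs,
         truth = list(p0 = p0, selected = selected, beta = beta,
                      betaB = betaB, pA = pA, pB = pB,
                      n_clamped = n_clamped))
  })
}

#' Type-I error and power of the bootstrap-interval detection rule
#'
#' Operationalizes the inference rule "the convergence correlation's
#' bootstrap interval excludes zero" over Monte-Carlo replicates of the
#' synthetic generator: the rejection fraction under a null configuration
#' estimates the type-I error, under an alternative configuration the
#' power.
#'
#' @param config_null,config_alt [synthetic_config()]s (their `seed`
#'   fields are ignored; per-replicate seeds are derived from `seed`).
#' @param n_reps Monte-Carlo replicates per configuration (>= 50).
#' @param alpha nominal level; the bootstrap interval uses `1 - alpha`.
#' @param n_boot bootstrap replicates per interval.
#' @param seed root seed.
#' @return list: `type1`, `power`, binomial standard errors `se_type1`,
#'   `se_power`, and `n_reps`.
#' @export
evaluate_detection <- function(config_null, config_alt, n_reps = 100,
                               alpha = 0.05, n_boot = 100, seed = NULL) {
  if (n_reps < 50) stop("n_reps must be >= 50")
  rate <- function(config, seeds) {
    rej <- vapply(seq_len(n_reps), function(i) {
      cfg <- config
      cfg$seed <- seeds[2 * i - 1]
      g <- synth_generate(cfg)
      dB <- freq_delta(g$freqs$b_hist, g$freqs$b_mod)
      dA <- freq_delta(g$freqs$a_hist, g$freqs$a_mod1)
      ci <- conv_cor_boot(dB, dA, n_boot = n_boot, conf = 1 - alpha,
                          seed = seeds[2 * i])
      ci[["ci_low"]] > 0 || ci[["ci_high"]] < 0
    }, logical(1))
    mean(rej)
  }
  seeds <- child_seeds(seed %||% 1L, 4 * n_reps)
  type1 <- rate(config_null, seeds[seq_len(2 * n_reps)])
  power <- rate(config_alt, seeds[2 * n_reps + seq_len(2 * n_reps)])
  list(type1 = type1, power = power,
       se_type1 = sqrt(type1 * (1 - type1) / n_reps),
       se_power = sqrt(power * (1 - power) / n_reps),
       n_reps = n_reps, alpha = alpha)
}
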