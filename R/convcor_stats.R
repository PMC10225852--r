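#' Convergent correlation between two allele-frequency-change vectors
#'
#' The convergence correlation of two per-locus change vectors,
#' `cov(d1, d2) / sqrt(var(d1) * var(d2))`, i.e. the Pearson correlation of
#' paired per-locus changes. Positive values indicate shared (parallel)
#' directional change across the two comparisons. Sample moments use
#' mean-centering and the n-1 denominator; `centered = FALSE` gives the
#' uncentered second-moment version for audit, and `literal = TRUE` divides
#' by the raw variance product without the square root (the statistic as
#' sometimes printed, unbounded and reported only for audit).
#'
#' @param d1,d2 `delta_vector`s (auto-aligned on common loci) or plain
#'   numeric vectors of equal length.
#' @param literal divide by `var*var` instead of `sqrt(var*var)`.
#' @param centered mean-center the changes (default) or use raw moments.
#' @return the correlation (dimensionless scalar).
#' @export
conv_cor <- function(d1, d2, literal = FALSE, centered = TRUE) {
  v <- convcor_pair(d1, d2)
  x <- v$x; y <- v$y
  if (length(x) < 2) stop("need at least 2 paired loci")
  if (centered) {
    cxy <- stats::cov(x, y); vx <- stats::var(x); vy <- stats::var(y)
  } else {
    n <- length(x)
    cxy <- sum(x * y) / (n - 1)
    vx <- sum(x * x) / (n - 1)
    vy <- sum(y * y) / (n - 1)
  }
  if (vx <= 0 || vy <= 0) stop("degenerate delta vector (zero variance)")
  if (literal) cxy / (vx * vy) else cxy / sqrt(vx * vy)
}

convcor_pair <- function(d1, d2) {
  if (inherits(d1, "delta_vector") && inherits(d2, "delta_vector")) {
    al <- align_deltas(d1, d2)
    list(x = al$d1$delta, y = al$d2$delta)
  } else {
    x <- as.numeric(if (is.data.frame(d1)) d1$delta else d1)
    y <- as.numeric(if (is.data.frame(d2)) d2$delta else d2)
    if (length(x) != length(y)) stop("vectors must be equal length")
    list(x = x, y = y)
  }
}

#' Percentile bootstrap interval for a convergence correlation
#'
#' Loci are the resampling unit: paired changes are resampled together with
#' replacement `n_boot` times and the statistic recomputed; the interval is
#' the percentile interval of the resampled statistics. Degenerate resamples
#' (zero variance) are redrawn up to `max_retry` times each.
#'
#' @inheritParams conv_cor
#' @param n_boot bootstrap replicates (default 100).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer; same seed gives an identical interval.
#' @param max_retry bounded redraws per degenerate resample.
#' @return named numeric `c(ci_low, ci_high)`, with the resampled statistics
#'   in `attr(, "boot")`.
#' @export
conv_cor_boot <- function(d1, d2, n_boot = 100, conf = 0.95, seed = NULL,
                          max_retry = 100) {
  v <- convcor_pair(d1, d2)
  x <- v$x; y <- v$y
  n <- length(x)
  if (n < 2) stop("need at least 2 paired loci")
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (k in seq_len(max_retry)) {
        idx <- sample.int(n, n, replace = TRUE)
        vx <- stats::var(x[idx]); vy <- stats::var(y[idx])
        if (vx > 0 && vy > 0)
          return(stats::cov(x[idx], y[idx]) / sqrt(vx * vy))
      }
      stop("bootstrap resamples persistently degenerate")
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  structure(c(ci_low = ci[1], ci_high = ci[2]), boot = boot)
}

#' The four canonical convergence correlations of the five-cohort design
#'
#' The design has population A sampled once historically and twice
#' contemporaneously (within roughly one generation of each other) and
#' population B sampled once historically and once contemporaneously. In
#' the cod study A is Norway (1907; 2011, 2014) and B is Canada (1940;
#' 2013). The four statistics are:
#' \describe{
#'   \item{ConvCor_1}{B hist->mod vs A hist->mod1 (cross-population test)}
#'   \item{ConvCor_2}{B hist->mod vs A hist->mod2 (cross-population test)}
#'   \item{ConvCor_3}{A hist->mod1 vs A hist->mod2 (positive control; the
#'     shared historic sample makes this large even without selection)}
#'   \item{ConvCor_4}{B hist->mod vs A mod1->mod2 (negative control;
#'     the A change is essentially sampling noise)}
#' }
#'
#' @param freqs named list of five `freq_table`s sharing one locus table:
#'   `a_hist`, `a_mod1`, `a_mod2`, `b_hist`, `b_mod`.
#' @param n_boot bootstrap replicates per statistic (0 skips the interval).
#' @param conf confidence level.
#' @param seed root seed; per-comparison child seeds are derived from it.
#' @return data frame with one row per statistic: `name`, `stratum`,
#'   `n_loci`, `estimate`, `ci_low`, `ci_high`.
#' @export
canonical_convcors <- function(freqs, n_boot = 100, conf = 0.95,
                               seed = NULL) {
  need <- c("a_hist", "a_mod1", "a_mod2", "b_hist", "b_mod")
  if (!all(need %in% names(freqs)))
    stop("freqs must be named: ", paste(need, collapse = ", "))
  dB <- freq_delta(freqs$b_hist, freqs$b_mod)
  dA1 <- freq_delta(freqs$a_hist, freqs$a_mod1)
  dA2 <- freq_delta(freqs$a_hist, freqs$a_mod2)
  dA12 <- freq_delta(freqs$a_mod1, freqs$a_mod2)
  pairs <- list(ConvCor_1 = list(dB, dA1), ConvCor_2 = list(dB, dA2),
                ConvCor_3 = list(dA1, dA2), ConvCor_4 = list(dB, dA12))
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else
    as.list(child_seeds(seed, 4))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    al <- align_deltas(p[[1]], p[[2]])
    est <- conv_cor(al$d1$delta, al$d2$delta)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0)
      ci <- conv_cor_boot(al$d1$delta, al$d2$delta, n_boot = n_boot,
                          conf = conf, seed = seeds[[i]])
    data.frame(name = names(pairs)[i], stratum = "genome-wide",
               n_loci = nrow(al$d1), estimate = est,
               ci_low = ci[[1]], ci_high = ci[[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convergence correlations within genomic strata
#'
#' Recomputes the statistic within locus strata (e.g. inside/outside
#' inversions, per linkage group, coding SNPs), bootstrapping within each
#' stratum. Strata with fewer than 2 loci, or degenerate changes, are
#' recorded as `NA` rather than failing.
#'
#' @param d1,d2 `delta_vector`s.
#' @param strata named list of character vectors of locus ids.
#' @param include_genomewide prepend a `"genome-wide"` stratum over all
#'   aligned loci (default `TRUE`).
#' @inheritParams conv_cor_boot
#' @return data frame with one row per stratum: `stratum`, `n_loci`,
#'   `estimate`, `ci_low`, `ci_high`.
#' @export
stratified_convcor <- function(d1, d2, strata, include_genomewide = TRUE,
                               n_boot = 100, conf = 0.95, seed = NULL) {
  al <- align_deltas(d1, d2)
  ids <- al$d1$locus_id
  if (include_genomewide)
    strata <- c(list(`genome-wide` = ids), strata)
  seeds <- if (is.null(seed)) rep(list(NULL), length(strata)) else
    as.list(child_seeds(seed, length(strata)))
  rows <- lapply(seq_along(strata), function(i) {
    sel <- ids %in% strata[[i]]
    x <- al$d1$delta[sel]; y <- al$d2$delta[sel]
    est <- ci_lo <- ci_hi <- NA_real_
    if (sum(sel) >= 2) {
      est <- tryCatch(conv_cor(x, y), error = function(e) NA_real_)
      if (!is.na(est) && n_boot > 0) {
        ci <- tryCatch(conv_cor_boot(x, y, n_boot = n_boot, conf = conf,
                                     seed = seeds[[i]]),
                       error = function(e) c(NA_real_, NA_real_))
        ci_lo <- ci[[1]]; ci_hi <- ci[[2]]
      }
    }
    data.frame(stratum = names(strata)[i], n_loci = sum(sel),
               estimate = est, ci_low = ci_lo, ci_high = ci_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build inversion / region strata from a region table
#'
#' @param loci locus table (`chrom`, `pos`, `locus_id`).
#' @param regions data frame from [read_regions()].
#' @return named list of locus-id vectors: one stratum per region label,
#'   plus `"inside"` (union of all regions) and `"outside"`.
#' @export
region_strata <- function(loci, regions) {
  strata <- lapply(split(regions, regions$label), function(rg)
    loci$locus_id[loci_in_regions(loci, rg)])
  inside <- loci_in_regions(loci, regions)
  c(strata, list(inside = loci$locus_id[inside],
                 outside = loci$locus_id[!inside]))
}

#' Per-chromosome strata
#'
#' @param loci locus table.
#' @return named list of locus-id vectors, one per chromosome/linkage group.
#' @export
chrom_strata <- function(loci) {
  split(loci$locus_id, loci$chrom)
}
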