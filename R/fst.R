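#' Weir-Cockerham F_ST between two cohorts
#'
#' The Weir & Cockerham (1984) two-population diploid estimator, computed
#' per locus from the variance components a (among populations), b (among
#' individuals within populations) and c (within individuals). The
#' genome-wide summary is the weighted ratio-of-sums `sum(a) / sum(a+b+c)`
#' (the "weighted Fst" of the standard tools); the unweighted mean of
#' per-locus ratios is also reported. Negative per-locus estimates are an
#' estimator property and are retained in the sums. "Spatial" F_ST compares
#' two populations at one time; "temporal" F_ST is obtained by passing the
#' two time points of one population as the two cohorts.
#'
#' @param gm1,gm2 [genotype_matrix()] cohorts sharing one locus table. A
#'   locus contributes only where both cohorts have at least 2 called
#'   individuals.
#' @return an object of class `fst_result`: list with `per_locus` (data
#'   frame `locus_id`, `chrom`, `pos`, `n1`, `n2`, `a`, `b`, `c`, `theta`),
#'   `weighted` (ratio of sums), `mean_theta`, and `n_loci` (loci entering
#'   the sums).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(gm1, gm2) {
  if (!identical(gm1$loci$locus_id, gm2$loci$locus_id))
    stop("cohorts do not share a locus table")
  if (nrow(gm1$loci) == 0) stop("no shared loci")
  n1 <- rowSums(!is.na(gm1$calls))
  n2 <- rowSums(!is.na(gm2$calls))
  p1 <- ifelse(n1 > 0, rowSums(gm1$calls, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, rowSums(gm2$calls, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, rowSums(gm1$calls == 1, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, rowSums(gm2$calls == 1, na.rm = TRUE) / n2, NA_real_)

  use <- n1 >= 2 & n2 >= 2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!use] <- b[!use] <- cc[!use] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)

  per_locus <- data.frame(locus_id = gm1$loci$locus_id,
                          chrom = gm1$loci$chrom, pos = gm1$loci$pos,
                          n1 = n1, n2 = n2, a = a, b = b, c = cc,
                          theta = theta, stringsAsFactors = FALSE)
  contributing <- use & !is.na(denom)
  if (!any(contributing)) stop("no loci with enough called individuals")
  weighted <- sum(a[contributing]) / sum(denom[contributing])
  structure(list(per_locus = per_locus,
                 weighted = weighted,
                 mean_theta = mean(theta, na.rm = TRUE),
                 n_loci = sum(contributing)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST over %d loci: weighted = %.5f, mean = %.5f\n",
              x$n_loci, x$weighted, x$mean_theta))
  invisible(x)
}
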