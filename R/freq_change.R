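#' Sample allele frequencies for one cohort
#'
#' Simple sample proportions of the alternate allele, computed from
#' non-missing calls only; orientation is fixed by the shared locus table so
#' the same allele is counted in every cohort.
#'
#' @param gm a [genotype_matrix()].
#' @return a `freq_table` data frame with columns `locus_id`, `chrom`,
#'   `pos`, `alt_count`, `called_chroms`, `freq` (`NA` where no calls);
#'   population and time attributes carried in `attr(, "population")` and
#'   `attr(, "time_label")`.
#' @export
allele_frequencies <- function(gm) {
  alt <- rowSums(gm$calls, na.rm = TRUE)
  called <- 2L * rowSums(!is.na(gm$calls))
  freq <- ifelse(called > 0, alt / called, NA_real_)
  out <- data.frame(locus_id = gm$loci$locus_id, chrom = gm$loci$chrom,
                    pos = gm$loci$pos, alt_count = alt,
                    called_chroms = called, freq = freq,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "population") <- gm$cohort$population
  attr(out, "time_label") <- gm$cohort$time_label
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Per-locus allele-frequency change between two time points
#'
#' The change vector is restricted to complete cases: loci with a defined
#' frequency (at least one called chromosome) at both time points.
#'
#' @param f0,f1 `freq_table`s sharing a locus table (earlier, later).
#' @param population population label (default taken from `f0`).
#' @param t0,t1 time labels (defaults taken from the tables).
#' @return a `delta_vector` data frame with columns `locus_id`, `chrom`,
#'   `pos`, `delta` (= `freq(t1) - freq(t0)`, alternate-allele orientation).
#' @export
freq_delta <- function(f0, f1, population = NULL, t0 = NULL, t1 = NULL) {
  common <- intersect(f0$locus_id[!is.na(f0$freq)],
                      f1$locus_id[!is.na(f1$freq)])
  if (length(common) == 0)
    stop("no loci with defined frequencies at both time points")
  i0 <- match(common, f0$locus_id)
  i1 <- match(common, f1$locus_id)
  out <- data.frame(locus_id = common, chrom = f0$chrom[i0],
                    pos = f0$pos[i0],
                    delta = f1$freq[i1] - f0$freq[i0],
                    stringsAsFactors = FALSE)
  ord <- order(out$chrom, out$pos, out$locus_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "population") <- population %||% attr(f0, "population")
  attr(out, "t0") <- t0 %||% attr(f0, "time_label")
  attr(out, "t1") <- t1 %||% attr(f1, "time_label")
  class(out) <- c("delta_vector", "data.frame")
  out
}

#' Align two change vectors on their common loci
#'
#' Both outputs are ordered identically (by chromosome, position, locus id)
#' over the locus intersection, so downstream covariances act on paired
#' loci. The result is invariant to the input row order.
#'
#' @param d1,d2 `delta_vector`s.
#' @return list with elements `d1` and `d2`, equal-length and co-ordered.
#' @export
align_deltas <- function(d1, d2) {
  common <- intersect(d1$locus_id, d2$locus_id)
  if (length(common) == 0) stop("no loci shared between the change vectors")
  a1 <- d1[match(common, d1$locus_id), , drop = FALSE]
  ord <- order(a1$chrom, a1$pos, a1$locus_id)
  common <- common[ord]
  take <- function(d) {
    out <- d[match(common, d$locus_id), , drop = FALSE]
    rownames(out) <- NULL
    for (at in c("population", "t0", "t1")) attr(out, at) <- attr(d, at)
    class(out) <- class(d)
    out
  }
  list(d1 = take(d1), d2 = take(d2))
}
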