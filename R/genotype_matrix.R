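#' Define a sampling cohort
#'
#' A cohort is one population sampled at one time point; the study design
#' here is five cohorts over two populations (two historic samples and
#' three contemporary samples of 20 diploids each).
#'
#' @param population population label (e.g. `"Canada"`, `"Norway"`).
#' @param time_label sampling time (e.g. `1907`, `2013`).
#' @param individual_ids character vector of sample names, unique, non-empty.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(population, time_label, individual_ids) {
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) == 0) stop("cohort has no individuals")
  if (anyDuplicated(individual_ids))
    stop("duplicated individual ids in cohort ", population, "/", time_label)
  structure(list(population = as.character(population),
                 time_label = time_label,
                 individual_ids = individual_ids),
            class = "cohort_spec")
}

#' @export
format.cohort_spec <- function(x, ...) {
  sprintf("<cohort %s/%s: %d individuals>", x$population,
          as.character(x$time_label), length(x$individual_ids))
}

#' @export
print.cohort_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Construct a genotype matrix for one cohort
#'
#' Container for per-locus x per-individual diploid alternate-allele dosages
#' in \{0, 1, 2\} (NA = missing call), with an optional matching matrix of
#' Phred-scaled genotype qualities.
#'
#' @param loci data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `locus_id` (unique) and logical `multiallelic`.
#' @param cohort a [cohort_spec()].
#' @param calls integer matrix, `nrow(loci)` x `length(individual_ids)`.
#' @param qualities optional numeric matrix of per-call GQ, same shape.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, cohort, calls, qualities = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"), is.matrix(calls))
  n_ind <- length(cohort$individual_ids)
  if (nrow(calls) != nrow(loci) || ncol(calls) != n_ind)
    stop("calls dimensions do not match loci x individuals")
  if (anyDuplicated(loci$locus_id)) stop("locus ids not unique")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing calls must be diploid dosages in {0, 1, 2}")
  if (!is.null(qualities) &&
      (!is.matrix(qualities) || !all(dim(qualities) == dim(calls))))
    stop("qualities must be a matrix matching calls")
  if (!"multiallelic" %in% names(loci)) loci$multiallelic <- FALSE
  rownames(calls) <- loci$locus_id
  colnames(calls) <- cohort$individual_ids
  if (!is.null(qualities)) dimnames(qualities) <- dimnames(calls)
  structure(list(loci = loci, cohort = cohort, calls = calls,
                 qualities = qualities),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d individuals (%s/%s)%s\n",
              nrow(x$loci), length(x$cohort$individual_ids),
              x$cohort$population, as.character(x$cohort$time_label),
              if (is.null(x$qualities)) "" else ", with GQ"))
  invisible(x)
}

#' Number of loci in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer locus count.
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' Restrict a genotype matrix to a locus subset
#'
#' @param gm a `genotype_matrix`.
#' @param keep character vector of locus ids (order preserved from `gm`)
#'   or logical/integer index.
#' @return the subset `genotype_matrix`.
#' @export
subset_loci <- function(gm, keep) {
  idx <- if (is.character(keep)) which(gm$loci$locus_id %in% keep) else keep
  genotype_matrix(gm$loci[idx, , drop = FALSE], gm$cohort,
                  gm$calls[idx, , drop = FALSE],
                  if (is.null(gm$qualities)) NULL
                  else gm$qualities[idx, , drop = FALSE])
}

#' Per-locus missing-call fraction
#' @param gm a `genotype_matrix`.
#' @return numeric vector in `[0, 1]`, one entry per locus.
#' @export
missing_fraction <- function(gm) {
  rowMeans(is.na(gm$calls))
}
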