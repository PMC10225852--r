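#' Read a multi-sample VCF into per-cohort genotype matrices
#'
#' Parses GT (and, when present, GQ) FORMAT fields with vcfR and splits the
#' samples into the requested cohorts. All cohorts share one locus table;
#' multi-allelic records are retained but flagged (they are removed later by
#' [filter_biallelic_maf()], so raw parsing is lossless).
#'
#' @param path VCF file (plain or gzipped).
#' @param cohorts list of [cohort_spec()]; if `NULL`, all samples form one
#'   cohort labelled `"all"`.
#' @return named list of [genotype_matrix()] (names from
#'   `population.time_label`), all sharing an identical locus table.
#' @export
read_vcf <- function(path, cohorts = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"],
                     alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  key <- paste(loci$chrom, loci$pos, sep = ":")
  loci$locus_id <- make.unique(key)
  # a record is multi-allelic if its ALT lists several alleles or if the
  # site appears as several split records at one position
  loci$multiallelic <- grepl(",", loci$alt, fixed = TRUE) |
    key %in% key[duplicated(key)]
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL

  gt <- vcfR::extract.gt(vcf, element = "GT")[ord, , drop = FALSE]
  samples <- colnames(gt)
  if (is.null(cohorts))
    cohorts <- list(cohort_spec("all", NA, samples))
  for (co in cohorts) {
    missing_ids <- setdiff(co$individual_ids, samples)
    if (length(missing_ids))
      stop("sample(s) not in VCF header: ", paste(missing_ids, collapse = ", "))
  }

  calls <- gt_to_dosage(gt)

  gq <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("(^|:)GQ(:|$)", fmt))) {
    gq <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))[ord, , drop = FALSE]
  }

  out <- lapply(cohorts, function(co) {
    cc <- calls[, co$individual_ids, drop = FALSE]
    qq <- if (is.null(gq)) NULL else gq[, co$individual_ids, drop = FALSE]
    genotype_matrix(loci, co, cc, qq)
  })
  names(out) <- vapply(cohorts, function(co)
    paste(co$population, as.character(co$time_label), sep = "."), "")
  out
}

# genotype strings -> dosage of allele "1"; any missing allele -> NA
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  dose1 <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_integer_)
    if (!all(grepl("^[0-9]+$", al)))
      stop("unparseable genotype string: '", g, "'")
    sum(al == "1")
  }, integer(1))
  m <- matrix(dose1[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  storage.mode(m) <- "integer"
  m
}

#' Mask low-quality genotype calls
#'
#' Sets every call with Phred-scaled genotype quality below `min_gq` to
#' missing (the conventional threshold removes GQ < 30); calls at or above the
#' threshold are untouched and the locus table is unchanged. Calls whose GQ
#' is itself missing are masked too, since they carry no quality evidence.
#'
#' @param gm a [genotype_matrix()] with qualities present.
#' @param min_gq minimum Phred GQ retained (default 30). `min_gq = 0`
#'   disables the filter explicitly and is the only way to run without GQ.
#' @return the masked `genotype_matrix`.
#' @export
mask_low_quality <- function(gm, min_gq = 30) {
  if (min_gq == 0) return(gm)
  if (is.null(gm$qualities))
    stop("genotype qualities absent; pass min_gq = 0 to skip this filter explicitly")
  drop <- is.na(gm$qualities) | gm$qualities < min_gq
  gm$calls[drop] <- NA_integer_
  gm
}

#' Keep loci with low missingness in a reference cohort
#'
#' Missing-data structure differs between historic and contemporary samples,
#' so loci are screened in the worst (reference) cohort: only loci with a
#' missing-call fraction strictly below `max_missing` there are kept, and the
#' same locus subset is applied to every cohort.
#'
#' @param gms named list of [genotype_matrix()] sharing one locus table.
#' @param reference_cohort name (in `names(gms)`) or index of the reference
#'   cohort.
#' @param max_missing strict upper bound on the missing fraction
#'   (default 0.40).
#' @return list of genotype matrices restricted to the surviving loci.
#' @export
filter_reference_missingness <- function(gms, reference_cohort,
                                         max_missing = 0.40) {
  if (is.character(reference_cohort) && !reference_cohort %in% names(gms))
    stop("reference cohort '", reference_cohort, "' not among cohorts")
  ref <- gms[[reference_cohort]]
  keep <- missing_fraction(ref) < max_missing
  if (!any(keep))
    stop("no loci survive the missingness filter (threshold too aggressive?)")
  lapply(gms, subset_loci, keep = which(keep))
}

#' Keep biallelic loci above a minor-allele-frequency bound
#'
#' Drops multi-allelic records and loci whose minor allele frequency is
#' strictly below `maf`. By default the MAF is pooled across all individuals
#' of all cohorts (the same filter applied to whole simulated sample sets);
#' `mode = "per_cohort"` instead requires the bound in every cohort.
#'
#' @param gms named list of [genotype_matrix()] sharing one locus table.
#' @param maf minimum minor allele frequency retained (default 0.05).
#' @param mode `"pooled"` (default) or `"per_cohort"`.
#' @return list of genotype matrices restricted to the surviving loci
#'   (possibly zero loci; that is allowed and reported via a message).
#' @export
filter_biallelic_maf <- function(gms, maf = 0.05,
                                 mode = c("pooled", "per_cohort")) {
  mode <- match.arg(mode)
  loci <- gms[[1]]$loci
  maf_of <- function(gm) {
    alt <- rowSums(gm$calls, na.rm = TRUE)
    called <- 2 * rowSums(!is.na(gm$calls))
    f <- ifelse(called > 0, alt / called, NA_real_)
    pmin(f, 1 - f)
  }
  if (mode == "pooled") {
    alt <- Reduce(`+`, lapply(gms, function(g) rowSums(g$calls, na.rm = TRUE)))
    called <- Reduce(`+`, lapply(gms, function(g) 2 * rowSums(!is.na(g$calls))))
    f <- ifelse(called > 0, alt / called, NA_real_)
    mafv <- pmin(f, 1 - f)
    pass <- !is.na(mafv) & mafv >= maf
  } else {
    per <- vapply(gms, function(g) {
      mv <- maf_of(g)
      !is.na(mv) & mv >= maf
    }, logical(nrow(loci)))
    pass <- rowSums(per) == length(gms)
  }
  keep <- pass & !loci$multiallelic
  if (!any(keep)) message("biallelic/MAF filter removed every locus")
  lapply(gms, subset_loci, keep = which(keep))
}

#' Read genomic strata from a BED file
#'
#' Intervals follow the BED convention (0-based half-open), so a record
#' `chrom 100 200` covers 1-based VCF positions 101..200. Overlapping
#' intervals are retained; membership tests use their union.
#'
#' @param path BED3/BED4 file; column 4, when present, names the region,
#'   otherwise labels default to `region_<k>`.
#' @return data frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  parts <- strsplit(lines, "\t")
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3)
      stop("BED line ", lnum[i], ": fewer than 3 columns")
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end))
      stop("BED line ", lnum[i], ": non-numeric coordinates")
    if (start >= end)
      stop("BED line ", lnum[i], ": start >= end")
    data.frame(chrom = p[1], start = start, end = end,
               label = if (length(p) >= 4) p[4] else NA_character_)
  })
  out <- do.call(rbind, out)
  miss <- is.na(out$label)
  out$label[miss] <- paste0("region_", which(miss))
  out
}

#' Which loci fall inside a region set?
#'
#' @param loci locus table (columns `chrom`, `pos` with 1-based positions).
#' @param regions data frame from [read_regions()].
#' @return logical vector: `TRUE` where a locus falls in the union of the
#'   (0-based half-open) intervals.
#' @export
loci_in_regions <- function(loci, regions) {
  inside <- rep(FALSE, nrow(loci))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (loci$chrom == regions$chrom[i] &
                          loci$pos > regions$start[i] &
                          loci$pos <= regions$end[i])
  }
  inside
}

#' Write one cohort's genotype matrix as a VCF
#'
#' Emits a minimal VCF v4.2 with GT (and GQ when present) FORMAT fields;
#' re-reading the file with [read_vcf()] reproduces the calls exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path; a `.gz` suffix writes a gzipped file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  has_gq <- !is.null(gm$qualities)
  fmt <- if (has_gq) "GT:GQ" else "GT"
  gt_str <- matrix("./.", nrow = nrow(gm$loci),
                   ncol = length(gm$cohort$individual_ids))
  map <- c("0/0", "0/1", "1/1")
  ok <- !is.na(gm$calls)
  gt_str[ok] <- map[gm$calls[ok] + 1]
  if (has_gq) {
    gq_chr <- ifelse(is.na(gm$qualities), ".",
                     format(gm$qualities, trim = TRUE, scientific = FALSE))
    gt_str <- matrix(paste(gt_str, gq_chr, sep = ":"),
                     nrow = nrow(gt_str))
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=convcor",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              if (has_gq)
                '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$cohort$individual_ids),
                    collapse = "\t"))
  body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$locus_id, gm$loci$ref,
                gm$loci$alt, ".", "PASS", ".", fmt,
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a cohort design table
#'
#' The design file is a TSV mapping each sample to its cohort, with columns
#' `sample`, `population`, `time_label` and optionally `role` (one of
#' `a_hist`, `a_mod1`, `a_mod2`, `b_hist`, `b_mod`) naming the slot each
#' cohort takes in the canonical five-cohort comparisons.
#'
#' @param path TSV file.
#' @return named list of [cohort_spec()]; names are roles when given,
#'   otherwise `population.time_label`.
#' @export
read_design <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "population", "time_label")
  if (!all(need %in% names(d)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  key <- paste(d$population, d$time_label, sep = ".")
  groups <- split(d, key)
  specs <- lapply(groups, function(g)
    cohort_spec(g$population[1], g$time_label[1], g$sample))
  if ("role" %in% names(d)) {
    roles <- vapply(groups, function(g) g$role[1], "")
    names(specs) <- roles
  }
  specs
}
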