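#' Run the empirical detection pipeline end to end
#'
#' Composes the full analysis on a multi-sample VCF: genotype-quality
#' masking, reference-cohort missingness filtering, biallelic/MAF
#' filtering, cohort allele frequencies, the four canonical convergence
#' correlations (optionally stratified by regions, chromosome and coding
#' annotation), and spatial plus temporal Weir-Cockerham F_ST. Outputs are
#' identical for identical inputs and seeds.
#'
#' @param vcf path to the VCF.
#' @param design named list of [cohort_spec()] with the five roles
#'   `a_hist`, `a_mod1`, `a_mod2`, `b_hist`, `b_mod` (see
#'   [read_design()]), or a path to a design TSV.
#' @param regions optional region table ([read_regions()]) or BED path
#'   (inversions or other strata).
#' @param coding optional BED path or region table of coding intervals.
#' @param min_gq genotype-quality threshold (0 skips the mask).
#' @param reference_cohort role name used for the missingness filter
#'   (default `"b_hist"`, the cohort with the most missing data in the cod
#'   design; `NULL` skips the filter).
#' @param max_missing missingness bound.
#' @param maf minor-allele-frequency bound.
#' @param n_boot bootstrap replicates.
#' @param seed root seed (fanned out to the bootstrap stages).
#' @param out_dir optional directory; when given, all tables are written
#'   there as TSV.
#' @return list with `convcor`, `convcor_by_chrom`, `convcor_regions`
#'   (when regions given), `fst`, `locus_counts`, and `manifest`.
#' @export
run_empirical <- function(vcf, design, regions = NULL, coding = NULL,
                          min_gq = 30, reference_cohort = "b_hist",
                          max_missing = 0.40, maf = 0.05, n_boot = 100,
                          seed = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(design)) design <- read_design(design)
  need <- c("a_hist", "a_mod1", "a_mod2", "b_hist", "b_mod")
  if (!all(need %in% names(design)))
    stop("design must provide roles: ", paste(need, collapse = ", "))
  if (is.character(regions)) regions <- read_regions(regions)
  if (is.character(coding)) coding <- read_regions(coding)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "': ", conditionMessage(e), call. = FALSE))
  }

  gms <- stage("read_vcf", read_vcf(vcf, design[need]))
  names(gms) <- need # index cohorts by role, not population.time
  counts <- c(input = n_loci(gms[[1]]))
  if (min_gq > 0 && !is.null(gms[[1]]$qualities))
    gms <- stage("mask_low_quality",
                 lapply(gms, mask_low_quality, min_gq = min_gq))
  if (!is.null(reference_cohort)) {
    gms <- stage("filter_reference_missingness",
                 filter_reference_missingness(gms, reference_cohort,
                                              max_missing))
    counts["after_missingness"] <- n_loci(gms[[1]])
  }
  gms <- stage("filter_biallelic_maf", filter_biallelic_maf(gms, maf = maf))
  counts["after_maf"] <- n_loci(gms[[1]])

  freqs <- lapply(gms, allele_frequencies)
  seeds <- child_seeds(seed %||% 1L, 4)
  cc <- stage("canonical_convcors",
              canonical_convcors(freqs, n_boot = n_boot, seed = seeds[1]))

  dB <- freq_delta(freqs$b_hist, freqs$b_mod)
  dA1 <- freq_delta(freqs$a_hist, freqs$a_mod1)
  loci <- gms[[1]]$loci
  cc_chrom <- stage("stratified_convcor_chrom",
                    stratified_convcor(dB, dA1, chrom_strata(loci),
                                       n_boot = n_boot, seed = seeds[2]))
  cc_regions <- NULL
  if (!is.null(regions)) {
    strata <- region_strata(loci, regions)
    if (!is.null(coding))
      strata$coding <- loci$locus_id[loci_in_regions(loci, coding)]
    cc_regions <- stage("stratified_convcor_regions",
                        stratified_convcor(dB, dA1, strata,
                                           n_boot = n_boot,
                                           seed = seeds[3]))
  }
  fst <- stage("wc_fst", data.frame(
    comparison = c("spatial_hist", "spatial_mod",
                   "temporal_a", "temporal_b"),
    weighted = c(wc_fst(gms$a_hist, gms$b_hist)$weighted,
                 wc_fst(gms$a_mod1, gms$b_mod)$weighted,
                 wc_fst(gms$a_hist, gms$a_mod1)$weighted,
                 wc_fst(gms$b_hist, gms$b_mod)$weighted),
    stringsAsFactors = FALSE))

  manifest <- list(
    inputs = c(vcf = unname(tools::md5sum(vcf))),
    seed = seed, min_gq = min_gq, max_missing = max_missing, maf = maf,
    n_boot = n_boot, locus_counts = counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    version = as.character(utils::packageVersion("convcor")))
  out <- list(convcor = cc, convcor_by_chrom = cc_chrom,
              convcor_regions = cc_regions, fst = fst,
              locus_counts = counts, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_file(cc, file.path(out_dir, "convcor.tsv"))
    write_tsv_file(cc_chrom, file.path(out_dir, "convcor_by_chrom.tsv"))
    if (!is.null(cc_regions))
      write_tsv_file(cc_regions, file.path(out_dir, "convcor_regions.tsv"))
    write_tsv_file(fst, file.path(out_dir, "fst.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- list.files(out_dir)
  }
  out
}

#' Run a replicated simulation study over a migration grid
#'
#' Runs `n_reps` forward-simulation replicates for each migration rate,
#' summarizes them ([migration_grid_summary()]), and — for three-type
#' scenarios — aggregates origin-epoch summaries across replicates.
#' Per-replicate failures are logged and skipped; the study continues.
#'
#' @param migration_rates full-scale migration probabilities (the grid).
#' @param n_reps replicates per scenario.
#' @param model full-scale [mutation_model()].
#' @param Q rescaling factor for the desk profile.
#' @param L reduced chromosome length for the desk profile.
#' @param seed root seed; each replicate gets a derived child seed.
#' @param keep_simsets retain the raw `sim_sample_set`s (memory-heavy).
#' @return list with `grid` (as [migration_grid_summary()]), `origin`
#'   (per-replicate `origin_summary` objects, three-type only), `failures`,
#'   and `manifest`.
#' @export
run_simulation_study <- function(migration_rates, n_reps = 5,
                                 model = mutation_model("neutral_only"),
                                 Q = 50, L = 5e5, seed = 1,
                                 keep_simsets = FALSE) {
  t0 <- Sys.time()
  total <- length(migration_rates) * n_reps
  seeds <- child_seeds(seed, total)
  sims <- list(); origin <- list(); failures <- character()
  k <- 0
  for (m in migration_rates) {
    sc <- desk_scenario(m = m, model = model, Q = Q, L = L)
    for (rep in seq_len(n_reps)) {
      k <- k + 1
      res <- tryCatch(
        run_scenario(sc$config, sc$model, seed = seeds[k]),
        error = function(e) {
          msg <- sprintf("m=%g rep %d failed: %s", m, rep,
                         conditionMessage(e))
          warning(msg)
          msg
        })
      if (is.character(res)) { failures <- c(failures, res); next }
      sims[[length(sims) + 1]] <- res
      if (model$mode == "three_type")
        origin[[length(origin) + 1]] <-
          origin_summary(res$registry, res$split_gen)
    }
  }
  grid <- migration_grid_summary(sims)
  manifest <- list(seed = seed, Q = Q, L = L,
                   migration_rates = migration_rates, n_reps = n_reps,
                   mode = model$mode, n_failures = length(failures),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                   version = as.character(utils::packageVersion("convcor")))
  list(grid = grid, origin = if (length(origin)) origin else NULL,
       simsets = if (keep_simsets) sims else NULL,
       failures = failures, manifest = manifest)
}

#' Replicate-averaged origin-epoch numbers from a simulation study
#'
#' Averages the per-replicate [origin_summary()] quantities of a three-type
#' study into the headline numbers: per-type percentage of segregating
#' mutations predating the split, mean pre-/post-split frequencies, and the
#' percentage of common (frequency > cutoff) variants predating the split.
#'
#' @param origins list of `origin_summary` objects.
#' @return list of data frame `by_type` (percentages and mean frequencies,
#'   averaged over replicates, with replicate standard errors) and scalar
#'   `pct_before_highfreq` (+ its SE).
#' @export
aggregate_origin_summaries <- function(origins) {
  if (!length(origins)) stop("no origin summaries supplied")
  tabs <- lapply(origins, `[[`, "by_type")
  types <- unique(unlist(lapply(tabs, `[[`, "type")))
  by_type <- do.call(rbind, lapply(types, function(tp) {
    pick <- function(col) vapply(tabs, function(tb) {
      i <- match(tp, tb$type)
      if (is.na(i)) NA_real_ else tb[[col]][i]
    }, numeric(1))
    fb <- pick("fraction_before_split")
    data.frame(type = tp,
               pct_before_split = 100 * mean(fb, na.rm = TRUE),
               pct_before_se = 100 * stats::sd(fb, na.rm = TRUE) /
                 sqrt(sum(!is.na(fb))),
               mean_freq_before = mean(pick("mean_freq_before"),
                                       na.rm = TRUE),
               mean_freq_after = mean(pick("mean_freq_after"),
                                      na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  hf <- vapply(origins, `[[`, numeric(1), "frac_before_highfreq")
  list(by_type = by_type,
       pct_before_highfreq = 100 * mean(hf, na.rm = TRUE),
       pct_before_highfreq_se = 100 * stats::sd(hf, na.rm = TRUE) /
         sqrt(sum(!is.na(hf))))
}
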