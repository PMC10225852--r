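#' Label registry mutations by origin epoch
#'
#' A mutation predates the population split iff it arose in the ancestral
#' population (origin generation before the first post-split generation).
#' Mutations recorded as arising in a subpopulation are "after" regardless
#' of any clock skew.
#'
#' @param registry registry data frame (from a `sim_sample_set`).
#' @param split_gen absolute generation of the first post-split generation.
#' @return the registry with an added `epoch` column (`"before"`/`"after"`).
#' @export
classify_origin <- function(registry, split_gen) {
  registry$epoch <- ifelse(
    registry$origin_pop != "ancestral", "after",
    ifelse(registry$origin_gen < split_gen, "before", "after"))
  registry
}

#' Origin-time and frequency summary of segregating mutations
#'
#' For each mutation type (and all types pooled): how many mutations are
#' still segregating at the final generation (pooled whole-population
#' frequency strictly between 0 and 1 — no minor-allele-frequency filter,
#' to capture the full spectrum), what fraction of them predate the split,
#' and the mean final frequency of the pre-/post-split groups. Separately,
#' the fraction of segregating variants with pooled frequency above
#' `maf_cut` that predate the split, and quantile tables of the selection
#' coefficients / effect sizes by origin epoch.
#'
#' @param registry registry with final `freq_pooled` column.
#' @param split_gen absolute first post-split generation.
#' @param maf_cut frequency cutoff for the "common variants" fraction
#'   (default 0.05).
#' @return an object of class `origin_summary`: list with `by_type` (data
#'   frame `type`, `n_segregating`, `fraction_before_split`,
#'   `mean_freq_before`, `mean_freq_after`), `frac_before_highfreq`, and
#'   `effects` (per type and epoch: n, quartiles, mean of coefficients).
#' @export
origin_summary <- function(registry, split_gen, maf_cut = 0.05) {
  reg <- classify_origin(registry, split_gen)
  seg <- reg[!is.na(reg$freq_pooled) & reg$freq_pooled > 0 &
               reg$freq_pooled < 1, , drop = FALSE]
  one <- function(sub, label) {
    before <- sub$epoch == "before"
    data.frame(type = label, n_segregating = nrow(sub),
               fraction_before_split =
                 if (nrow(sub)) mean(before) else NA_real_,
               mean_freq_before =
                 if (any(before)) mean(sub$freq_pooled[before]) else NA_real_,
               mean_freq_after =
                 if (any(!before)) mean(sub$freq_pooled[!before]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  types <- unique(seg$type)
  by_type <- do.call(rbind, c(
    list(one(seg, "all")),
    lapply(sort(types), function(tp) one(seg[seg$type == tp, ], tp))))
  rownames(by_type) <- NULL
  hi <- seg[seg$freq_pooled > maf_cut, , drop = FALSE]
  frac_hi <- if (nrow(hi)) mean(hi$epoch == "before") else NA_real_
  eff <- seg[seg$type %in% c("deleterious", "qtl"), , drop = FALSE]
  effects <- if (nrow(eff)) {
    do.call(rbind, lapply(split(eff, list(eff$type, eff$epoch), drop = TRUE),
      function(g) data.frame(
        type = g$type[1], epoch = g$epoch[1], n = nrow(g),
        q25 = stats::quantile(g$coeff, 0.25, names = FALSE),
        median = stats::median(g$coeff),
        q75 = stats::quantile(g$coeff, 0.75, names = FALSE),
        mean = mean(g$coeff), stringsAsFactors = FALSE)))
  } else NULL
  if (!is.null(effects)) rownames(effects) <- NULL
  structure(list(by_type = by_type, frac_before_highfreq = frac_hi,
                 maf_cut = maf_cut, effects = effects),
            class = "origin_summary")
}

#' @export
print.origin_summary <- function(x, ...) {
  cat("Origin-epoch summary of segregating mutations\n")
  print(x$by_type, row.names = FALSE)
  cat(sprintf("fraction of variants with freq > %g predating the split: %.3f\n",
              x$maf_cut, x$frac_before_highfreq))
  invisible(x)
}

#' F_ST and convergence-correlation summary of one simulated replicate
#'
#' Applies the standard locus filters (biallelic, pooled MAF >= `maf`) to the
#' five sampled cohorts, then computes spatial Weir-Cockerham F_ST between
#' the subpopulations (historic pair and contemporary pair), temporal F_ST
#' within each subpopulation, and the four canonical convergence
#' correlations.
#'
#' @param simset a `sim_sample_set` with the default five cohorts.
#' @param maf minor-allele-frequency bound applied before the statistics.
#' @param n_boot bootstrap replicates for the ConvCor intervals (0 = point
#'   estimates only).
#' @param seed optional seed for the bootstrap.
#' @return one-row data frame: `m`, `Q`, `n_loci`, `fst_spatial_hist`,
#'   `fst_spatial_mod`, `fst_temporal_p1`, `fst_temporal_p2`,
#'   `convcor_1` .. `convcor_4`.
#' @export
summarize_replicate <- function(simset, maf = 0.05, n_boot = 0,
                                seed = NULL) {
  need <- c("a_hist", "b_hist", "a_mod1", "a_mod2", "b_mod")
  if (!all(need %in% names(simset$cohorts)))
    stop("replicate is missing cohorts: ",
         paste(setdiff(need, names(simset$cohorts)), collapse = ", "))
  gms <- filter_biallelic_maf(simset$cohorts, maf = maf)
  freqs <- lapply(gms, allele_frequencies)
  cc <- canonical_convcors(freqs, n_boot = n_boot, seed = seed)
  est <- stats::setNames(cc$estimate, tolower(cc$name))
  data.frame(
    m = simset$m, Q = simset$Q, n_loci = n_loci(gms[[1]]),
    fst_spatial_hist = wc_fst(gms$a_hist, gms$b_hist)$weighted,
    fst_spatial_mod = wc_fst(gms$a_mod1, gms$b_mod)$weighted,
    fst_temporal_p1 = wc_fst(gms$a_hist, gms$a_mod1)$weighted,
    fst_temporal_p2 = wc_fst(gms$b_hist, gms$b_mod)$weighted,
    convcor_1 = est[["convcor_1"]], convcor_2 = est[["convcor_2"]],
    convcor_3 = est[["convcor_3"]], convcor_4 = est[["convcor_4"]],
    stringsAsFactors = FALSE)
}

#' Summarize replicates across a migration-rate grid
#'
#' @param replicates list of `sim_sample_set` objects (any mix of
#'   scenarios); replicates whose summary fails are skipped with a warning.
#' @param maf minor-allele-frequency bound passed to
#'   [summarize_replicate()].
#' @return list with `per_replicate` (one row per replicate, with `rep`
#'   index) and `per_scenario` (per migration rate: mean, quartiles of each
#'   statistic).
#' @export
migration_grid_summary <- function(replicates, maf = 0.05) {
  rows <- list()
  for (i in seq_along(replicates)) {
    r <- tryCatch(summarize_replicate(replicates[[i]], maf = maf),
                  error = function(e) {
                    warning("replicate ", i, " skipped: ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(r)) { r$rep <- i; rows[[length(rows) + 1]] <- r }
  }
  if (!length(rows)) stop("no replicate produced a summary")
  per_rep <- do.call(rbind, rows)
  stats_cols <- setdiff(names(per_rep), c("m", "Q", "rep", "n_loci"))
  per_scen <- do.call(rbind, lapply(split(per_rep, per_rep$m), function(g) {
    out <- data.frame(m = g$m[1], n_reps = nrow(g))
    for (cl in stats_cols) {
      out[[paste0(cl, "_mean")]] <- mean(g[[cl]], na.rm = TRUE)
      qs <- stats::quantile(g[[cl]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                            names = FALSE)
      out[[paste0(cl, "_q25")]] <- qs[1]
      out[[paste0(cl, "_median")]] <- qs[2]
      out[[paste0(cl, "_q75")]] <- qs[3]
    }
    out
  }))
  rownames(per_scen) <- NULL
  list(per_replicate = per_rep, per_scenario = per_scen)
}
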