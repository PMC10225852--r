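#!/usr/bin/env Rscript

# Calibration of the convergence-correlation detection rule on synthetic
# five-cohort data with known truth.
#
# The synthetic generator draws shared standing variation (MAF-filtered
# 1/x spectrum), evolves two populations with optional shared directional
# selection plus binomial drift, and observes each cohort through binomial
# sampling noise (20 diploids, as in the study design). Here we check:
#   (i)  the null ConvCor_1 distribution is centred at zero,
#   (ii) the positive control ConvCor_3 sits near 0.5 under the null
#        (shared historic sampling noise with equal sampling variances),
#   (iii) the "bootstrap CI excludes zero" rule holds its nominal type-I
#        error and gains power under shared polygenic selection.
#
# Writes: results/synthetic_null_convcors.tsv, results/detection_rates.tsv

suppressMessages(library(convcor))
dir.create("results", showWarnings = FALSE)
seed <- 20260922

message("Null distribution of the four statistics over 200 replicates ...")
null_rows <- do.call(rbind, lapply(1:200, function(i) {
  g <- synth_generate(synthetic_config(n_loci = 2000, Ne = 5000, gens = 15,
                                       seed = seed + i))
  cc <- canonical_convcors(g$freqs, n_boot = 0)
  data.frame(rep = i, name = cc$name, estimate = cc$estimate)
}))
write.table(null_rows, "results/synthetic_null_convcors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
m <- tapply(null_rows$estimate, null_rows$name, mean)
message(sprintf("  mean ConvCor_1 = %+.4f (cross-population null)", m["ConvCor_1"]))
message(sprintf("  mean ConvCor_3 = %+.4f (positive control, ~0.5)", m["ConvCor_3"]))
message(sprintf("  mean ConvCor_4 = %+.4f (negative control)", m["ConvCor_4"]))

message("Type-I error and power of the bootstrap-interval rule ...")
rates <- evaluate_detection(
  config_null = synthetic_config(n_loci = 2000, Ne = 5000, gens = 15),
  config_alt = synthetic_config(n_loci = 2000, Ne = 5000, gens = 15,
                                pi_sel = 0.5, s_bar = 0.5),
  n_reps = 100, alpha = 0.05, n_boot = 100, seed = seed)
out <- data.frame(quantity = c("type1", "power"),
                  rate = c(rates$type1, rates$power),
                  se = c(rates$se_type1, rates$se_power))
write.table(out, "results/detection_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("  type-I error %.3f (se %.3f), power %.3f (se %.3f)",
                rates$type1, rates$se_type1, rates$power, rates$se_power))
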