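#!/usr/bin/env Rscript

# Three-type selection scenario: neutral, recessive deleterious (gamma DFE,
# mean -0.05, shape 0.5) and N(0,1)-effect QTLs under stabilizing selection,
# equal mutation-type probabilities, migration 1e-4, same demography as the
# neutral grid (desk profile Q = 50).
#
# The question: of the mutations still segregating at the end, how many of
# each type predate the population split, and at what frequencies do
# pre-split vs post-split variants segregate? Shared (pre-split) standing
# variation at high frequency is the raw material for parallel polygenic
# adaptation, while young mutations are mostly rare and population-private.
#
# Writes: results/origin_by_type.tsv, results/origin_effects.tsv,
#         results/origin_headline.tsv

suppressMessages(library(convcor))
dir.create("results", showWarnings = FALSE)

n_reps <- 5
seeds <- child_seeds(20260922, n_reps, salt = 3L)
sc <- desk_scenario(m = 1e-4, model = mutation_model("three_type"), Q = 50)
origins <- list(); effects <- list()
for (i in seq_len(n_reps)) {
  message("replicate ", i, "/", n_reps)
  s <- run_scenario(sc$config, sc$model, seed = seeds[i])
  os <- origin_summary(s$registry, s$split_gen)
  origins[[i]] <- os
  if (!is.null(os$effects)) {
    os$effects$rep <- i
    effects[[i]] <- os$effects
  }
}
agg <- aggregate_origin_summaries(origins)

write.table(agg$by_type, "results/origin_by_type.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, effects), "results/origin_effects.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
headline <- data.frame(
  quantity = c("pct_segregating_before_split_all",
               "pct_before_split_deleterious", "pct_before_split_neutral",
               "pct_before_split_qtl", "mean_freq_before_neutral",
               "mean_freq_before_qtl", "pct_common_variants_before_split"),
  value = c(agg$by_type$pct_before_split[agg$by_type$type == "all"],
            agg$by_type$pct_before_split[agg$by_type$type == "deleterious"],
            agg$by_type$pct_before_split[agg$by_type$type == "neutral"],
            agg$by_type$pct_before_split[agg$by_type$type == "qtl"],
            agg$by_type$mean_freq_before[agg$by_type$type == "neutral"],
            agg$by_type$mean_freq_before[agg$by_type$type == "qtl"],
            agg$pct_before_highfreq))
write.table(headline, "results/origin_headline.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("replicate-averaged origin-epoch summary:")
print(agg$by_type, row.names = FALSE)
message(sprintf(
  "%.1f%% of segregating variants with pooled frequency > 0.05 predate the split",
  agg$pct_before_highfreq))
message("Reading: only a small minority of segregating mutations predate the")
message("split, but those that do segregate at far higher frequencies than")
message("post-split mutations, and deleterious variants are purged from the")
message("shared pool fastest - background selection on shared deleterious")
message("variation is an unlikely source of cross-population covariance.")
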