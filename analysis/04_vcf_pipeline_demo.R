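#!/usr/bin/env Rscript

# End-to-end demonstration of the empirical VCF pipeline on simulated data.
#
# One forward replicate is exported as five cohort VCFs (the shape of the
# deposited cod data: two populations, historic + contemporary samples, 20
# diploids each), then pushed through the same path an empirical VCF would
# take: read -> (GQ mask where present) -> reference-cohort missingness
# filter -> biallelic/MAF filter -> frequencies -> canonical convergence
# correlations with 100-replicate locus bootstrap -> stratified statistics
# -> spatial and temporal Weir-Cockerham F_ST.
#
# Writes: results/pipeline_demo/*.tsv (+ manifest.json)

suppressMessages(library(convcor))
dir.create("results", showWarnings = FALSE)

message("simulating and exporting a five-cohort VCF set ...")
sc <- desk_scenario(m = 1e-5, model = mutation_model("neutral_only"), Q = 50)
s <- run_scenario(sc$config, sc$model, seed = 20260922)
vcf_dir <- file.path("results", "pipeline_demo", "vcf")
export_vcf(s, vcf_dir)

# merge the five cohorts into one multi-sample matrix and write a single
# study VCF + design table, as the empirical inputs would arrive
loci <- s$cohorts[[1]]$loci
calls <- do.call(cbind, lapply(s$cohorts, function(g) g$calls))
ids <- unlist(lapply(s$cohorts, function(g) g$cohort$individual_ids))
all_gm <- genotype_matrix(loci, cohort_spec("all", NA, ids), calls)
study_vcf <- file.path("results", "pipeline_demo", "study.vcf")
write_vcf(all_gm, study_vcf)
design <- lapply(names(s$cohorts), function(nm)
  s$cohorts[[nm]]$cohort)
names(design) <- names(s$cohorts)

# an illustrative "inversion" stratum covering the first fifth of the
# chromosome (the cod analysis uses the annotated inversions on linkage
# groups 1, 2, 7 and 12 as a BED input here)
bed <- file.path("results", "pipeline_demo", "inversions.bed")
writeLines(sprintf("sim1\t0\t%d\tinv1", as.integer(sc$config$L / 5)), bed)

message("running the empirical pipeline ...")
res <- run_empirical(study_vcf, design, regions = bed,
                     min_gq = 0, # simulated genotypes carry no GQ field
                     reference_cohort = "b_hist", max_missing = 0.40,
                     maf = 0.05, n_boot = 100, seed = 20260922,
                     out_dir = file.path("results", "pipeline_demo"))

message("locus counts through the filters:")
print(res$locus_counts)
message("genome-wide convergence correlations (with 95% bootstrap CIs):")
print(res$convcor, row.names = FALSE)
message("F_ST summary:")
print(res$fst, row.names = FALSE)
message("Reading: on neutral simulated data the cross-population statistics")
message("(ConvCor_1/2) straddle zero, the shared-baseline positive control")
message("(ConvCor_3) is large, and the negative control (ConvCor_4) is near")
message("zero - the pattern the empirical analysis tests against.")
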