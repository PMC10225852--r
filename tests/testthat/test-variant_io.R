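test_that("a toy VCF parses into per-cohort matrices sharing one locus table", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    "LG01\t100\t.\tA\tT\t.\tPASS\t.\tGT:GQ\t0/0:40\t0/1:35\t1/1:50\t./.:.",
    "LG01\t200\t.\tC\tG\t.\tPASS\t.\tGT:GQ\t0/1:29\t0/0:30\t0/1:45\t1/1:41",
    "LG02\t50\t.\tG\tA,C\t.\tPASS\t.\tGT:GQ\t1/2:33\t0/0:44\t0/1:22\t0/0:38"),
    vcf)
  cohorts <- list(cohort_spec("A", 1907, c("s1", "s2")),
                  cohort_spec("B", 1940, c("s3", "s4")))
  gms <- read_vcf(vcf, cohorts)
  expect_length(gms, 2)
  expect_identical(gms[[1]]$loci, gms[[2]]$loci)
  expect_equal(dim(gms[[1]]$calls), c(3L, 2L))
  # dosage counts allele "1" only; "1/2" -> 1; "./." -> NA
  expect_equal(unname(gms[["A.1907"]]$calls[, "s1"]), c(0L, 1L, 1L))
  expect_equal(unname(gms[["B.1940"]]$calls[, "s4"]), c(NA_integer_, 2L, 0L))
  expect_equal(gms[[1]]$loci$multiallelic, c(FALSE, FALSE, TRUE))
  expect_equal(unname(gms[["A.1907"]]$qualities[, "s1"]), c(40, 29, 33))

  # unknown sample names the sample
  expect_error(read_vcf(vcf, list(cohort_spec("X", 1, "sX"))), "sX")

  # a GT-only VCF yields matrices with qualities absent, no error
  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    "LG01\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1"), vcf2)
  gm2 <- read_vcf(vcf2)
  expect_null(gm2[[1]]$qualities)
})

test_that("GQ masking respects the strict <30 boundary and preserves loci", {
  calls <- rbind(c(0L, 1L), c(2L, 1L), c(1L, 0L))
  qual <- rbind(c(29, 30), c(10, 10), c(31, 29.9))
  gm <- toy_gm(calls, qualities = qual)
  masked <- mask_low_quality(gm, min_gq = 30)
  expect_equal(unname(masked$calls),
               rbind(c(NA, 1L), c(NA, NA), c(1L, NA)))
  expect_equal(n_loci(masked), 3L) # locus count unchanged even if all-missing
  expect_identical(mask_low_quality(gm, min_gq = 0), gm)
  gm_noq <- toy_gm(calls)
  expect_error(mask_low_quality(gm_noq, 30), "min_gq = 0")
  expect_identical(mask_low_quality(gm_noq, 0), gm_noq)
})

test_that("reference-cohort missingness filter keeps loci strictly below the bound", {
  # 5 individuals: 2/5 missing (0.4) dropped, 1/5 (0.2) kept
  calls_ref <- rbind(c(NA, NA, 0L, 1L, 2L),   # 0.4 -> dropped
                     c(NA, 1L, 0L, 1L, 2L),   # 0.2 -> kept
                     c(0L, 1L, 1L, 1L, 0L),   # 0.0 -> kept
                     c(NA, NA, NA, 1L, 2L))   # 0.6 -> dropped
  ref <- toy_gm(calls_ref, population = "B", time_label = 1940)
  other <- toy_gm(matrix(1L, 4, 3), population = "A", time_label = 1907)
  gms <- list(B.1940 = ref, A.1907 = other)
  out <- filter_reference_missingness(gms, "B.1940", 0.40)
  expect_equal(out[["B.1940"]]$loci$locus_id, ref$loci$locus_id[c(2, 3)])
  expect_equal(out[["A.1907"]]$loci$locus_id, ref$loci$locus_id[c(2, 3)])
  # max_missing = 1.0 keeps everything (no locus has 100% missing here)
  expect_equal(n_loci(filter_reference_missingness(gms, "B.1940", 1.0)[[1]]), 4L)
  expect_error(filter_reference_missingness(gms, "nope", 0.4), "nope")
  # brute-force oracle on a random fixture
  set.seed(1)
  cl <- matrix(sample(c(0:2, NA), 50, TRUE), 10, 5)
  gm <- toy_gm(cl)
  kept <- filter_reference_missingness(list(x = gm), "x", 0.4)$x$loci$locus_id
  manual <- gm$loci$locus_id[apply(cl, 1, function(r) sum(is.na(r))) / 5 < 0.4]
  expect_identical(kept, manual)
})

test_that("biallelic/MAF filter applies the strict boundary and drops multi-allelics", {
  # 10 individuals; pooled alt freq 0.05 kept, 0.04 impossible with 20
  # chroms, so use 25 chroms via two cohorts of sizes 10 + 2.5... use one
  # cohort of 10 (20 chroms): freq 1/20 = 0.05 kept, 0/20 dropped
  calls <- rbind(c(1L, rep(0L, 9)),        # freq 0.05 -> kept (>= bound)
                 rep(0L, 10),              # freq 0    -> dropped
                 c(1L, 1L, rep(0L, 8)),    # freq 0.10 -> kept
                 c(2L, rep(1L, 9)),        # freq 0.55 -> kept
                 rep(2L, 10))              # freq 1    -> dropped (MAF 0)
  gm <- toy_gm(calls)
  gm$loci$multiallelic[4] <- TRUE          # kept by MAF but multi-allelic
  out <- filter_biallelic_maf(list(a = gm), maf = 0.05)
  expect_equal(out$a$loci$locus_id, gm$loci$locus_id[c(1, 3)])
  # pooled across cohorts equals hand-computed pooled counts
  gm1 <- toy_gm(rbind(c(1L, 0L), c(0L, 0L)))
  gm2 <- toy_gm(rbind(c(0L, 0L), c(1L, 1L)), population = "q")
  # locus 1: 1/8; locus 2: 2/8
  out2 <- filter_biallelic_maf(list(gm1, gm2), maf = 0.2)
  expect_equal(out2[[1]]$loci$locus_id, gm1$loci$locus_id[2])
})

test_that("BED regions follow the half-open convention and validate", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("LG01\t100\t200\tinv1", "LG02\t0\t50"), bed)
  rg <- read_regions(bed)
  expect_equal(rg$label, c("inv1", "region_2"))
  loci <- data.frame(chrom = "LG01", pos = c(100L, 101L, 200L, 201L),
                     locus_id = letters[1:4])
  expect_equal(loci_in_regions(loci, rg[1, ]), c(FALSE, TRUE, TRUE, FALSE))
  # empty file -> empty list
  writeLines(character(), bed)
  expect_equal(nrow(read_regions(bed)), 0L)
  # start >= end errors with the line number
  writeLines(c("LG01\t5\t10", "LG01\t20\t20"), bed)
  expect_error(read_regions(bed), "line 2")
  # overlapping intervals both retained; membership is the union
  writeLines(c("LG01\t0\t150\tx", "LG01\t100\t300\ty"), bed)
  rg2 <- read_regions(bed)
  expect_equal(nrow(rg2), 2L)
  expect_true(all(loci_in_regions(loci, rg2)))
})

test_that("masking and missingness-filtering commute on random fixtures", {
  set.seed(42)
  for (rep in 1:5) {
    calls <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(rep(0.3, 3), 0.1)),
                    12, 5)
    qual <- matrix(sample(10:60, 60, TRUE), 12, 5)
    gm <- toy_gm(calls, qualities = qual)
    a <- filter_reference_missingness(
      list(x = mask_low_quality(gm, 30)), "x", 0.7)$x
    masked <- mask_low_quality(gm, 30)
    keep <- missing_fraction(masked) < 0.7
    b <- subset_loci(masked, which(keep))
    expect_identical(a$loci, b$loci)
    expect_identical(a$calls, b$calls)
    # every filter returns a subset of input loci, retained calls unaltered
    expect_true(all(a$loci$locus_id %in% gm$loci$locus_id))
    idx <- match(a$loci$locus_id, gm$loci$locus_id)
    same <- !is.na(a$calls)
    expect_identical(a$calls[same], gm$calls[idx, ][same])
  }
})

test_that("VCF export round-trips calls exactly", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 40, TRUE), 10, 4)
  qual <- matrix(sample(20:50, 40, TRUE), 10, 4)
  gm <- toy_gm(calls, qualities = qual)
  p <- tempfile(fileext = ".vcf")
  write_vcf(gm, p)
  back <- read_vcf(p, list(gm$cohort))[[1]]
  expect_equal(unname(back$calls), unname(gm$calls))
  expect_equal(unname(back$qualities), unname(gm$qualities))
  expect_equal(back$loci$pos, gm$loci$pos)
})
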