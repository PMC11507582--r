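test_that("configuration invariants are enforced", {
  expect_error(cohort_config(group_sizes = c(BOT = -1, BOT.V600E = 0,
                                             lgOvCa = 0, hgOvCa = 0)),
               "negative group size")
  expect_error(cohort_config(group_sizes = c(XXX = 5)), "unknown group")
  expect_error(cohort_config(gene_freqs = data.frame(
    gene = "NOT_A_GENE", group = "BOT", stratum = "HIGH", prob = 0.5)),
    "not in panel")
  expect_error(cohort_config(gene_freqs = data.frame(
    gene = "TP53", group = "BOT", stratum = "HIGH", prob = 1.5)),
    "\\[0, 1\\]")
  expect_error(cohort_config(survival_effects = data.frame(
    gene = "ZZZ9", endpoint = "OS", log_hr = 1)), "absent from panel")
})

test_that("zero planted probability means zero retained-eligible calls", {
  cfg <- cohort_config(
    group_sizes = c(BOT = 0, BOT.V600E = 0, lgOvCa = 0, hgOvCa = 200),
    gene_freqs = data.frame(gene = c("TP53", "BRCA1"), group = "hgOvCa",
                            stratum = "HIGH", prob = c(0, 0.5)),
    noise_vaf_rate = 0, decoy_rate = 0, seed = 91)
  b <- generate_cohort(cfg)
  expect_equal(sum(b$calls$gene == "TP53"), 0L)
  expect_gt(sum(b$calls$gene == "BRCA1"), 0L)
})

test_that("planted frequency is recovered within exact binomial bounds", {
  n <- 1000
  cfg <- cohort_config(
    group_sizes = c(BOT = n, BOT.V600E = 0, lgOvCa = 0, hgOvCa = 0),
    gene_freqs = data.frame(gene = "BRCA2", group = "BOT",
                            stratum = "HIGH_OR_MODERATE", prob = 0.4),
    lowcov_region_rate = 0, seed = 92)
  b <- generate_cohort(cfg)
  # run the actual cascade down to the binarized matrix
  run <- run_pipeline(b, strata = "HIGH_OR_MODERATE",
                      class_subsets = "combined")
  freq <- cumulative_frequency(run$matrices[[1]], b$clinical$group)
  altered <- freq$altered[freq$gene == "BRCA2"]
  expect_gte(altered, qbinom(0.005, n, 0.4))
  expect_lte(altered, qbinom(0.995, n, 0.4))
  # every planted call is retained-eligible: survives the full cascade
  planted <- b$calls[b$calls$origin == "planted", ]
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
  kept <- run$retained[["HIGH_OR_MODERATE.combined"]]
  expect_true(all(key(planted) %in% key(kept)))
})

test_that("clinical invariants hold", {
  b <- generate_cohort(small_config(seed = 93))
  cl <- b$clinical
  bots <- cl$group %in% c("BOT", "BOT.V600E")
  expect_true(all(cl$residual_tumor[bots] == "none"))
  expect_true(all(is.na(cl$dfs_time[!is.na(cl$cr) & !cl$cr])))
  expect_true(all(!is.na(cl$dfs_time[!is.na(cl$cr) & cl$cr])))
  expect_true(all(is.na(cl$cr[bots])))
  expect_true(all(is.na(cl$tp53_accumulation[bots])))
  expect_true(all(cl$age >= 18 & cl$age <= 95))
  expect_true(all(cl$os_time >= 0 & is.finite(cl$os_time)))
  expect_true(mean(cl$age[cl$group == "BOT.V600E"]) <
                mean(cl$age[cl$group == "BOT"]))
})

test_that("planted survival effects follow the proportional-hazards model", {
  cfg <- cohort_config(
    group_sizes = c(BOT = 0, BOT.V600E = 0, lgOvCa = 0, hgOvCa = 2000),
    gene_freqs = data.frame(gene = "FANCI", group = "hgOvCa",
                            stratum = "HIGH_OR_MODERATE", prob = 0.4),
    noise_vaf_rate = 0, decoy_rate = 0, lowcov_region_rate = 0,
    survival_effects = data.frame(gene = "FANCI", endpoint = "OS",
                                  log_hr = log(2)),
    censoring_rate = 0, seed = 94)
  b <- generate_cohort(cfg)
  altered <- as.numeric(b$clinical$sample_id %in%
                          b$calls$sample_id[b$calls$gene == "FANCI"])
  fit <- survival::coxph(survival::Surv(os_time, os_event) ~ altered,
                         data = b$clinical)
  expect_lt(abs(unname(coef(fit)) - log(2)), 0.15)
})

test_that("same config and seed give byte-identical bundles", {
  cfg <- small_config(seed = 95)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(generate_cohort(cfg), d1)
  write_bundle(generate_cohort(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})

test_that("bundles round-trip through disk", {
  cfg <- small_config(
    seed = 96,
    survival_effects = data.frame(gene = "KRAS", endpoint = "OS",
                                  log_hr = log(2)),
    response_effects = data.frame(gene = "TP53", outcome = "PS",
                                  log_or = 0.5))
  b <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$clinical, b$clinical)
  expect_equal(b2$calls, b$calls)
  expect_equal(b2$annotations, b$annotations)
  expect_equal(b2$depth, b$depth)
  expect_equal(b2$config, b$config, tolerance = 1e-12)
})

test_that("an empty cohort writes valid headers-only files", {
  cfg <- cohort_config(group_sizes = c(BOT = 0, BOT.V600E = 0, lgOvCa = 0,
                                       hgOvCa = 0), seed = 97)
  b <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  b2 <- read_bundle(dir)
  expect_equal(nrow(b2$clinical), 0L)
  expect_equal(nrow(b2$calls), 0L)
})

test_that("written VCFs pass a standard validator (bcftools)", {
  cfg <- small_config(seed = 98)
  b <- generate_cohort(cfg)
  # force at least one symbolic non-SNP allele into the first sample
  sym <- make_calls(1, sample_id = b$clinical$sample_id[1],
                    chrom = b$panel$regions$chrom[1],
                    pos = b$panel$regions$start[1],
                    ref = "A", alt = "<DUP>", variant_class = "other")
  b$calls <- rbind(b$calls, sym)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  vcf <- file.path(dir, "vcf", paste0(b$clinical$sample_id[1], ".vcf"))
  out <- suppressWarnings(
    system2("bcftools", c("view", vcf), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
})

test_that("multi-allelic records are split on read with per-allele AD", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "T,G", "60", ".", "MQ=50",
            "GT:DP:AD", "1/2:30:10,12,8"), collapse = "\t")
  ), file.path(dir, "multi.vcf"))
  calls <- read_vcf_calls(file.path(dir, "multi.vcf"))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt, c("T", "G"))
  expect_equal(calls$ref_depth, c(10L, 10L))
  expect_equal(calls$alt_depth, c(12L, 8L))
  expect_equal(calls$variant_class, c("snp", "snp"))
})
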