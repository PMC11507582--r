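test_that("variant_allele_fraction computes AD-based fractions", {
  calls <- make_calls(3, ref_depth = c(18L, 0L, 0L), alt_depth = c(2L, 7L, 0L))
  vaf <- variant_allele_fraction(calls)
  expect_equal(vaf[1], 0.10)
  expect_equal(vaf[2], 1.0)
  expect_true(is.na(vaf[3]))
})

test_that("vaf decisions agree with exact rational arithmetic", {
  # oracle: retain iff 10 * alt >= 1 * (ref + alt) in integer arithmetic,
  # immune to floating-point boundary artifacts
  set.seed(11)
  calls <- make_calls(500, ref_depth = sample(0:60, 500, TRUE),
                      alt_depth = sample(0:60, 500, TRUE))
  calls <- calls[calls$ref_depth + calls$alt_depth > 0, ]
  res <- vaf_filter(calls, min_fraction = 0.10)
  oracle <- 10L * calls$alt_depth >= calls$ref_depth + calls$alt_depth
  got <- paste(calls$ref_depth, calls$alt_depth) %in%
    paste(res$retained$ref_depth, res$retained$alt_depth)
  expect_identical(got, oracle)
})

test_that("vaf_filter boundary behavior is strict below threshold", {
  calls <- make_calls(4, ref_depth = c(91L, 18L, 89L, 0L),
                      alt_depth = c(9L, 2L, 11L, 0L))  # 0.09, 0.10, 0.11, NA
  res <- vaf_filter(calls)
  expect_equal(nrow(res$retained), 2L)  # 0.10 and 0.11 retained
  expect_setequal(res$removed$gate, c("VAF", "no_allele_evidence"))
  expect_equal(res$removed$value[res$removed$gate == "VAF"], 0.09)
  expect_error(vaf_filter(calls, min_fraction = -1), "negative")
})

test_that("quality_filter gates are inclusive minima with attribution", {
  base <- list(qual = 20, mapq = 20, depth = 5L, ref_depth = 3L,
               alt_depth = 2L)
  at_boundary <- do.call(make_calls, c(list(n = 1), base))
  expect_equal(nrow(quality_filter(at_boundary)$retained), 1L)
  fail_one <- function(field, value) {
    args <- base; args[[field]] <- value
    do.call(make_calls, c(list(n = 1), args))
  }
  cases <- list(alt_bases = fail_one("alt_depth", 1L),
                qual = fail_one("qual", 19),
                mapq = fail_one("mapq", 19),
                depth = fail_one("depth", 4L))
  for (gate in names(cases)) {
    res <- quality_filter(cases[[gate]])
    expect_equal(nrow(res$retained), 0L)
    expect_identical(res$removed$gate, gate)
  }
  expect_error(quality_filter(at_boundary, min_qual = -5), "negative")
})

test_that("vaf and quality filters commute and are threshold-monotone", {
  set.seed(22)
  calls <- make_calls(400,
                      pos = sample.int(5000L, 400),
                      qual = round(runif(400, 0, 60), 1),
                      mapq = sample(0:60, 400, TRUE),
                      depth = sample(0:200, 400, TRUE),
                      ref_depth = sample(0:80, 400, TRUE),
                      alt_depth = sample(0:80, 400, TRUE))
  calls <- calls[calls$ref_depth + calls$alt_depth > 0, ]
  a <- quality_filter(vaf_filter(calls)$retained)$retained
  b <- vaf_filter(quality_filter(calls)$retained)$retained
  expect_equal(a[order(a$pos), ], b[order(b$pos), ], ignore_attr = TRUE)
  # raising any threshold never grows the retained set
  key <- function(d) paste(d$pos, d$ref_depth, d$alt_depth)
  loose <- quality_filter(calls)$retained
  for (strict in list(quality_filter(calls, min_alt_bases = 5),
                      quality_filter(calls, min_qual = 40),
                      quality_filter(calls, min_mapq = 40),
                      quality_filter(calls, min_depth = 50))) {
    expect_true(all(key(strict$retained) %in% key(loose)))
  }
  expect_true(all(key(vaf_filter(calls, 0.3)$retained) %in%
                    key(vaf_filter(calls, 0.1)$retained)))
})

test_that("low_coverage_mask applies the strictly-below-5 rule", {
  s <- data.frame(SAMPLE = "S1", CHROM = "chr1", START = 1L, END = 100L,
                  GENE = "TP53", MEAN_DEPTH = c(4.99, 5.0, 0, 150))
  m <- low_coverage_mask(s)
  expect_equal(m$MEAN_DEPTH, c(4.99, 0))
  expect_equal(nrow(low_coverage_mask(s[0, , drop = FALSE])), 0L)
  expect_error(low_coverage_mask(s, min_mean_depth = -1), "negative")
})

test_that("partition_by_class partitions every input", {
  calls <- rbind(
    make_calls(1, ref = "A", alt = "T", variant_class = "snp"),
    make_calls(1, ref = "AACTGT", alt = "A", variant_class = "indel"),
    make_calls(1, ref = "AC", alt = "TG", variant_class = "mnp"),
    make_calls(1, ref = "A", alt = "<DUP>", variant_class = "other")
  )
  p <- partition_by_class(calls)
  expect_equal(nrow(p$snp), 1L)
  expect_equal(nrow(p$non_snp), 3L)
  expect_equal(nrow(p$snp) + nrow(p$non_snp), nrow(calls))
  set.seed(3)
  rand <- make_calls(50, variant_class = sample(
    c("snp", "indel", "mnp", "bnd", "other"), 50, TRUE))
  p <- partition_by_class(rand)
  expect_equal(nrow(p$snp) + nrow(p$non_snp), 50L)
  bad <- make_calls(1, variant_class = "weird")
  expect_error(partition_by_class(bad), "unknown variant class")
})

test_that("coverage mask removal and MISSING-gene mapping work", {
  panel <- default_panel("hotspot")
  reg <- panel$regions[panel$regions$gene %in% c("KRAS", "TP53"), ]
  depth <- data.frame(SAMPLE = "S0001", CHROM = reg$chrom, START = reg$start,
                      END = reg$end, GENE = reg$gene,
                      MEAN_DEPTH = c(2, 100))
  mask <- low_coverage_mask(depth)
  calls <- make_calls(2, chrom = reg$chrom, pos = reg$start,
                      gene = reg$gene)
  res <- apply_coverage_mask(calls, mask)
  expect_equal(nrow(res$retained), 1L)
  expect_identical(res$removed$gate, "coverage")
  # hotspot genes have one region each: masking it makes the gene MISSING
  mg <- missing_gene_map(mask, panel, "S0001")
  expect_identical(mg$gene, depth$GENE[depth$MEAN_DEPTH < 5])
})

test_that("synthetic decoys are each removed by exactly their own gate", {
  b <- generate_cohort(small_config(seed = 5, noise_vaf_rate = 3,
                                    decoy_rate = 1))
  calls <- b$calls
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
  vaf_removed <- key(vaf_filter(calls)$removed)
  q <- quality_filter(calls)
  expect_true(all(key(calls[!is.na(calls$decoy_gate) &
                              calls$decoy_gate == "VAF", ]) %in% vaf_removed))
  for (gate in c("depth", "qual", "mapq", "alt_bases")) {
    mine <- calls[!is.na(calls$decoy_gate) & calls$decoy_gate == gate, ]
    rem <- q$removed[q$removed$gate == gate, ]
    expect_true(all(key(mine) %in% key(rem)))
    # and not removed by the VAF gate
    expect_false(any(key(mine) %in% vaf_removed))
  }
  # impact/retention decoys survive QC but fall at the annotation stage
  surv <- quality_filter(vaf_filter(calls)$retained)$retained
  ann <- annotation_stage(surv, b$annotations, "HIGH_OR_MODERATE",
                          panel = b$panel)
  late <- calls[!is.na(calls$decoy_gate) &
                  calls$decoy_gate %in% c("impact", "retention"), ]
  expect_true(all(key(late) %in% key(surv)))
  expect_false(any(key(late) %in% key(ann$retained)))
  gate_of <- ann$removed$gate[match(key(late), key(ann$removed))]
  expect_identical(unname(gate_of),
                   ifelse(late$decoy_gate == "impact", "impact", "retention"))
})
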