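# Pre-annotation filters: per-region coverage exclusion, allele-fraction
# gate, quality gates and SNP/non-SNP partition.
#
# Boundary reading: every "minimum X of N" gate is inclusive (>= N), and
# the allele-fraction clause removes calls strictly below the threshold
# ("less frequent than 10%"), so a call at exactly 0.10 is retained and
# a region with mean depth exactly 5.0 is kept.

.VARIANT_CLASSES <- c("snp", "indel", "mnp", "bnd", "other")

#' Per-sample low-coverage region mask
#'
#' Flags each (sample, region) pair whose mean coverage depth is
#' strictly below `min_mean_depth` reads.  Masking is per sample-region,
#' not cohort-wide: a poorly enriched region in one sample does not
#' remove it from the others.
#'
#' @param summaries Data frame with columns `SAMPLE`, `CHROM`, `START`,
#'   `END`, `GENE`, `MEAN_DEPTH` (1-based inclusive coordinates).
#' @param min_mean_depth Exclusion threshold in reads (default 5).
#' @return The excluded subset of `summaries` (same columns).
#' @export
low_coverage_mask <- function(summaries, min_mean_depth = 5) {
  if (min_mean_depth < 0) stop("argument error: negative threshold")
  stopifnot(all(c("SAMPLE", "CHROM", "START", "END", "GENE",
                  "MEAN_DEPTH") %in% names(summaries)))
  stopifnot(all(summaries$START <= summaries$END),
            all(summaries$MEAN_DEPTH >= 0))
  out <- summaries[summaries$MEAN_DEPTH < min_mean_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variant allele fraction from allele depths
#'
#' `alt_depth / (ref_depth + alt_depth)`.  Calls with zero total allele
#' depth have no usable evidence; the fraction is `NA` and such calls
#' are dropped by [vaf_filter()] with a distinct logged reason.
#'
#' @param calls Data frame with `ref_depth` and `alt_depth` columns.
#' @return Numeric vector of fractions in \[0, 1\] (`NA` where
#'   `ref_depth + alt_depth == 0`).
#' @export
variant_allele_fraction <- function(calls) {
  stopifnot(all(c("ref_depth", "alt_depth") %in% names(calls)))
  stopifnot(all(calls$ref_depth >= 0), all(calls$alt_depth >= 0))
  tot <- calls$ref_depth + calls$alt_depth
  ifelse(tot > 0, calls$alt_depth / tot, NA_real_)
}

.removal_ledger <- function(calls, reason, value = NA_real_) {
  if (!nrow(calls)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gate = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(sample_id = calls$sample_id, chrom = calls$chrom,
             pos = calls$pos, ref = calls$ref, alt = calls$alt,
             gate = reason, value = value, stringsAsFactors = FALSE)
}

#' Allele-fraction filter
#'
#' Retains calls whose variant allele fraction is at least
#' `min_fraction`; sub-threshold calls and calls with no allele-depth
#' evidence are removed with per-call reasons.
#'
#' @param calls `VariantCall` data frame.
#' @param min_fraction Retention threshold (default 0.10).
#' @return List with `retained` (calls) and `removed` (ledger with
#'   columns `sample_id, chrom, pos, ref, alt, gate, value`).
#' @export
vaf_filter <- function(calls, min_fraction = 0.10) {
  if (min_fraction < 0) stop("argument error: negative threshold")
  vaf <- variant_allele_fraction(calls)
  no_evidence <- is.na(vaf)
  low <- !no_evidence & vaf < min_fraction
  keep <- !no_evidence & !low
  removed <- rbind(
    .removal_ledger(calls[no_evidence, , drop = FALSE], "no_allele_evidence"),
    .removal_ledger(calls[low, , drop = FALSE], "VAF", vaf[low])
  )
  list(retained = calls[keep, , drop = FALSE], removed = removed)
}

#' Quality gates
#'
#' Retains calls passing all four gates: alternate-base count, call
#' quality, mapping quality and coverage depth, each inclusive at its
#' threshold.  Removed calls are tagged with every gate they failed
#' (comma-separated).
#'
#' @param calls `VariantCall` data frame.
#' @param min_alt_bases Minimum alternate-allele read count (default 2).
#' @param min_qual Minimum phred-scaled call quality (default 20).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param min_depth Minimum coverage depth (default 5).
#' @return List with `retained` and `removed` (as in [vaf_filter()]).
#' @export
quality_filter <- function(calls, min_alt_bases = 2, min_qual = 20,
                           min_mapq = 20, min_depth = 5) {
  if (any(c(min_alt_bases, min_qual, min_mapq, min_depth) < 0)) {
    stop("argument error: negative threshold")
  }
  fails <- cbind(
    alt_bases = calls$alt_depth < min_alt_bases,
    qual = calls$qual < min_qual,
    mapq = calls$mapq < min_mapq,
    depth = calls$depth < min_depth
  )
  n_fail <- if (nrow(calls)) rowSums(fails) else integer(0)
  keep <- n_fail == 0
  removed_idx <- which(!keep)
  gates <- vapply(removed_idx, function(i) {
    paste(colnames(fails)[fails[i, ]], collapse = ",")
  }, character(1))
  removed <- .removal_ledger(calls[removed_idx, , drop = FALSE],
                             reason = if (length(gates)) gates
                                      else character(0))
  list(retained = calls[keep, , drop = FALSE], removed = removed)
}

#' Partition calls into SNP and non-SNP subsets
#'
#' SNPs are single-base substitutions; everything else (indels,
#' multi-nucleotide polymorphisms, breakpoints, other symbolic alleles)
#' goes to the non-SNP subset.  The two subsets partition the input.
#'
#' @param calls `VariantCall` data frame with a `variant_class` column.
#' @return List with elements `snp` and `non_snp`.
#' @export
partition_by_class <- function(calls) {
  cls <- calls$variant_class
  bad <- !cls %in% .VARIANT_CLASSES
  if (any(bad)) {
    stop("data error: unknown variant class label(s): ",
         paste(unique(cls[bad]), collapse = ", "))
  }
  list(snp = calls[cls == "snp", , drop = FALSE],
       non_snp = calls[cls != "snp", , drop = FALSE])
}

#' Remove calls falling in coverage-masked regions
#'
#' Drops calls located inside a (sample, region) pair excluded by
#' [low_coverage_mask()].
#'
#' @param calls `VariantCall` data frame.
#' @param mask Excluded regions as returned by [low_coverage_mask()].
#' @return List with `retained` and `removed` (gate `"coverage"`).
#' @export
apply_coverage_mask <- function(calls, mask) {
  if (!nrow(mask) || !nrow(calls)) {
    return(list(retained = calls, removed = .removal_ledger(
      calls[0, , drop = FALSE], character(0))))
  }
  hit <- logical(nrow(calls))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (calls$sample_id == mask$SAMPLE[i] &
                    calls$chrom == mask$CHROM[i] &
                    calls$pos >= mask$START[i] &
                    calls$pos <= mask$END[i])
  }
  list(retained = calls[!hit, , drop = FALSE],
       removed = .removal_ledger(calls[hit, , drop = FALSE], "coverage"))
}

#' Genes with no coverage left for a sample
#'
#' A gene is MISSING (rather than unaltered) for a sample when all its
#' panel regions are coverage-excluded; MISSING entries are dropped
#' pairwise from downstream tests instead of being counted as 0.
#'
#' @param mask Excluded regions from [low_coverage_mask()].
#' @param panel An `ov_panel`.
#' @param samples Character vector of sample ids.
#' @return Data frame with columns `sample_id`, `gene`.
#' @export
missing_gene_map <- function(mask, panel, samples) {
  empty <- data.frame(sample_id = character(), gene = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(mask)) return(empty)
  n_regions <- table(panel$regions$gene)
  masked <- mask[mask$SAMPLE %in% samples, , drop = FALSE]
  if (!nrow(masked)) return(empty)
  cnt <- stats::aggregate(list(n = masked$START),
                          by = list(sample_id = masked$SAMPLE,
                                    gene = masked$GENE),
                          FUN = length)
  full <- cnt$n >= as.integer(n_regions[cnt$gene])
  out <- cnt[full, c("sample_id", "gene"), drop = FALSE]
  rownames(out) <- NULL
  out
}
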