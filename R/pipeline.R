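# End-to-end orchestration of the cascade, in the canonical stage
# order: coverage exclusion -> VAF gate -> quality gates -> SNP/non-SNP
# partition -> annotation retention -> binarization -> group contrasts
# -> regression screen.  Every intermediate can be persisted and the
# stage log records counts entering and leaving each filter.

#' Run the full prioritization cascade on a cohort bundle
#'
#' @param bundle An `ov_cohort` (from [generate_cohort()] or
#'   [read_bundle()]).
#' @param strata Impact strata to profile (default all three).
#' @param class_subsets Variant-class subsets to profile (default
#'   combined plus SNP and non-SNP separately).
#' @param min_mean_depth,min_fraction,min_alt_bases,min_qual,min_mapq,min_depth
#'   Filter thresholds (defaults: 5 reads mean region depth, VAF 0.10,
#'   2 alternate bases, quality 20, mapping quality 20, depth 5).
#' @param alpha Significance threshold for the comparison report.
#' @param rule Chi-squared/Fisher selection rule (see
#'   [contrast_table()]).
#' @param drop_genes Genes excluded from reports (default `"CRNDE"`).
#' @param screen_specs Optional list of `ov_spec` for the regression
#'   screen (run on the `HIGH_OR_MODERATE`/`combined` matrix).
#' @param B,seed Bootstrap replicates and seed for the screen.
#' @param out_dir Optional directory: when given, every intermediate
#'   (removal ledgers, matrices, frequency and comparison tables,
#'   screen results, stage log, effective config) is written as
#'   TSV/CSV.
#' @param ... Passed to [retain_annotated()].
#' @return An `ov_run`: list with `retained` (per stratum/class),
#'   `matrices`, `frequencies`, `comparison`, `counts_tests`, `screen`,
#'   `stage_log`, `removed` ledgers and the `mask`.
#' @export
run_pipeline <- function(bundle,
                         strata = c("HIGH_OR_MODERATE", "HIGH", "MODERATE"),
                         class_subsets = c("combined", "snp", "non_snp"),
                         min_mean_depth = 5, min_fraction = 0.10,
                         min_alt_bases = 2, min_qual = 20, min_mapq = 20,
                         min_depth = 5, alpha = 0.05, rule = "auto",
                         drop_genes = "CRNDE", screen_specs = NULL,
                         B = 1000, seed = 1L, out_dir = NULL, ...) {
  stopifnot(inherits(bundle, "ov_cohort"))
  panel <- bundle$panel
  samples <- bundle$clinical$sample_id
  groups <- bundle$clinical$group

  log_rows <- list()
  note <- function(stage, n_in, n_out) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, removed = n_in - n_out,
      stringsAsFactors = FALSE)
  }

  mask <- low_coverage_mask(bundle$depth, min_mean_depth)
  missing <- missing_gene_map(mask, panel, samples)

  st0 <- apply_coverage_mask(bundle$calls, mask)
  note("coverage", nrow(bundle$calls), nrow(st0$retained))
  st1 <- vaf_filter(st0$retained, min_fraction)
  note("vaf", nrow(st0$retained), nrow(st1$retained))
  st2 <- quality_filter(st1$retained, min_alt_bases, min_qual, min_mapq,
                        min_depth)
  note("quality", nrow(st1$retained), nrow(st2$retained))
  parts <- partition_by_class(st2$retained)

  # annotation retention independently for SNP and non-SNP subsets
  retained <- list(); matrices <- list(); ann_removed <- list()
  for (stratum in strata) {
    ann_snp <- annotation_stage(parts$snp, bundle$annotations, stratum,
                                panel = panel, drop_genes = drop_genes, ...)
    ann_non <- annotation_stage(parts$non_snp, bundle$annotations, stratum,
                                panel = panel, drop_genes = drop_genes, ...)
    sets <- list(snp = ann_snp$retained, non_snp = ann_non$retained,
                 combined = rbind(ann_snp$retained, ann_non$retained))
    ann_removed[[stratum]] <- rbind(ann_snp$removed, ann_non$removed)
    for (cs in class_subsets) {
      key <- paste(stratum, cs, sep = ".")
      retained[[key]] <- sets[[cs]]
      matrices[[key]] <- binarize(sets[[cs]], samples, panel$genes,
                                  missing = missing, stratum = stratum,
                                  class_subset = cs)
    }
  }
  note("annotation (HIGH_OR_MODERATE)",
       nrow(parts$snp) + nrow(parts$non_snp),
       if ("HIGH_OR_MODERATE.combined" %in% names(retained)) {
         nrow(retained[["HIGH_OR_MODERATE.combined"]])
       } else NA_integer_)

  frequencies <- lapply(matrices, cumulative_frequency, groups = groups)
  comparison <- comparison_report(matrices, groups, alpha = alpha,
                                  rule = rule)

  counts_tests <- NULL
  key0 <- paste(strata[1], class_subsets[1], sep = ".")
  counts <- tabulate(match(retained[[key0]]$sample_id, samples),
                     nbins = length(samples))
  if (length(unique(groups)) >= 2L && all(table(groups) >= 2L)) {
    counts_tests <- count_distribution_tests(counts, groups)
  }

  screen <- NULL
  if (!is.null(screen_specs) && length(screen_specs)) {
    mat_key <- if ("HIGH_OR_MODERATE.combined" %in% names(matrices)) {
      "HIGH_OR_MODERATE.combined"
    } else names(matrices)[1]
    screen <- screen_genes(bundle$clinical, matrices[[mat_key]],
                           screen_specs, B = B, seed = seed, alpha = alpha)
  }

  run <- structure(
    list(retained = retained, matrices = matrices,
         frequencies = frequencies, comparison = comparison,
         counts = counts, counts_tests = counts_tests, screen = screen,
         stage_log = do.call(rbind, log_rows),
         removed = list(coverage = st0$removed, vaf = st1$removed,
                        quality = st2$removed, annotation = ann_removed),
         mask = mask, missing = missing),
    class = "ov_run")
  if (!is.null(out_dir)) .persist_run(run, bundle, out_dir)
  run
}

.persist_run <- function(run, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(run$stage_log, file.path(out_dir, "stage_log.tsv"))
  .write_tsv(run$removed$coverage, file.path(out_dir, "removed_coverage.tsv"))
  .write_tsv(run$removed$vaf, file.path(out_dir, "removed_vaf.tsv"))
  .write_tsv(run$removed$quality, file.path(out_dir, "removed_quality.tsv"))
  for (stratum in names(run$removed$annotation)) {
    .write_tsv(run$removed$annotation[[stratum]],
               file.path(out_dir, paste0("removed_annotation_", stratum,
                                         ".tsv")))
  }
  for (key in names(run$matrices)) {
    m <- run$matrices[[key]]
    df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(df, file.path(out_dir, paste0("matrix_", key, ".tsv")))
    .write_tsv(run$frequencies[[key]],
               file.path(out_dir, paste0("frequency_", key, ".tsv")))
  }
  .write_tsv(run$comparison, file.path(out_dir, "comparison_report.tsv"))
  if (!is.null(run$screen)) {
    .write_tsv(run$screen$results, file.path(out_dir, "screen_models.tsv"))
    .write_tsv(screen_report(run$screen),
               file.path(out_dir, "screen_matched.tsv"))
  }
  .write_config(bundle$config, out_dir)
  invisible(out_dir)
}

#' @export
print.ov_run <- function(x, ...) {
  cat("<ov_run>\n")
  print(x$stage_log)
  cat(sprintf("  %d significant contrasts; %d matrices\n",
              nrow(x$comparison), length(x$matrices)))
  invisible(x)
}
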