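# Annotation-table retention logic: transcript consolidation, impact
# stratification, and the CLIN_SIG / SIFT / PolyPhen / novelty / MAX_AF
# inclusion rules.
#
# Empty annotation fields may appear as "", "-" or NA (the annotation
# engine's table dialect uses "-"); all three are treated as empty.
# Category labels may carry score suffixes like "deleterious(0.01)",
# which are stripped before comparison.

.IMPACT_LEVELS <- c(MODIFIER = 1L, LOW = 2L, MODERATE = 3L, HIGH = 4L)
.SIFT_SEVERITY <- c(tolerated = 1L, tolerated_low_confidence = 2L,
                    deleterious_low_confidence = 3L, deleterious = 4L)
.POLYPHEN_SEVERITY <- c(benign = 1L, unknown = 2L, possibly_damaging = 3L,
                        probably_damaging = 4L)

.is_empty_field <- function(x) is.na(x) | x == "" | x == "-"

.strip_score <- function(x) sub("\\(.*\\)$", "", x)

.split_labels <- function(x) {
  x[.is_empty_field(x)] <- ""
  strsplit(x, "[,&]")
}

#' Consolidate per-transcript annotation rows into one row per variant
#'
#' The annotation engine emits one row per overlapping transcript; the
#' cascade needs one consolidated record per variant.  Consolidation is
#' worst-case across transcripts: the most severe impact wins (HIGH >
#' MODERATE > LOW > MODIFIER) and contributes the gene symbol,
#' consequence and protein change; `CLIN_SIG` and `Existing_variation`
#' are unions; `SIFT`/`PolyPhen` take the most deleterious category and
#' `MAX_AF` the smallest value present.
#'
#' @param ann Annotation data frame (columns as written by
#'   [write_bundle()]: `SAMPLE, CHROM, POS, REF, ALT, SYMBOL,
#'   Consequence, IMPACT, Existing_variation, CLIN_SIG, SIFT, PolyPhen,
#'   MAX_AF, HGVSp`).
#' @return Data frame with one row per distinct
#'   `(SAMPLE, CHROM, POS, REF, ALT)` key.
#' @export
consolidate_annotations <- function(ann) {
  if (!all(ann$IMPACT %in% names(.IMPACT_LEVELS))) {
    stop("data error: IMPACT must be one of HIGH, MODERATE, LOW, MODIFIER")
  }
  if (!nrow(ann)) return(ann)
  key <- paste(ann$SAMPLE, ann$CHROM, ann$POS, ann$REF, ann$ALT, sep = "\r")
  idx <- split(seq_len(nrow(ann)), key)
  rows <- lapply(idx, function(i) .consolidate_one(ann[i, , drop = FALSE]))
  out <- do.call(rbind, rows)
  out <- out[order(out$SAMPLE, out$CHROM, out$POS, out$REF, out$ALT), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consolidate the transcript rows of a single variant
#'
#' Single-variant form of [consolidate_annotations()]; errors if the
#' rows do not share one variant key.
#'
#' @param rows Annotation rows for one variant (at least one).
#' @return One consolidated row.
#' @export
consolidate_transcript_rows <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  key <- unique(paste(rows$SAMPLE, rows$CHROM, rows$POS, rows$REF, rows$ALT))
  if (length(key) != 1L) {
    stop("data error: rows carry conflicting variant keys")
  }
  .consolidate_one(rows)
}

.consolidate_one <- function(rows) {
  sev <- .IMPACT_LEVELS[rows$IMPACT]
  top <- which.max(sev)
  out <- rows[top, , drop = FALSE]
  union_field <- function(x) {
    labs <- unique(unlist(.split_labels(x), use.names = FALSE))
    paste(labs[nzchar(labs)], collapse = ",")
  }
  out$Existing_variation <- union_field(rows$Existing_variation)
  out$CLIN_SIG <- union_field(rows$CLIN_SIG)
  pick_worst <- function(x, severity) {
    lab <- .strip_score(x)
    s <- severity[lab]
    s[.is_empty_field(x)] <- NA
    if (all(is.na(s))) "" else x[which.max(s)]
  }
  out$SIFT <- pick_worst(rows$SIFT, .SIFT_SEVERITY)
  out$PolyPhen <- pick_worst(rows$PolyPhen, .POLYPHEN_SEVERITY)
  af <- rows$MAX_AF[!is.na(rows$MAX_AF)]
  out$MAX_AF <- if (length(af)) min(af) else NA_real_
  rownames(out) <- NULL
  out
}

#' Does a variant's impact fall inside a stratum?
#'
#' Profiles are built in three impact strata: `HIGH_OR_MODERATE`,
#' `HIGH`, `MODERATE`.  LOW and MODIFIER impacts never pass any
#' stratum (they are filtered out before the retention rules apply).
#'
#' @param impact Character vector of impact categories.
#' @param stratum One of `"HIGH_OR_MODERATE"`, `"HIGH"`, `"MODERATE"`.
#' @return Logical vector.
#' @export
impact_in_stratum <- function(impact,
                              stratum = c("HIGH_OR_MODERATE", "HIGH",
                                          "MODERATE")) {
  stratum <- match.arg(stratum)
  switch(stratum,
         HIGH_OR_MODERATE = impact %in% c("HIGH", "MODERATE"),
         HIGH = impact == "HIGH",
         MODERATE = impact == "MODERATE")
}

#' Annotation-based retention rules
#'
#' A variant that passed an impact stratum is retained iff any of:
#' \describe{
#'   \item{R1}{known adverse clinical significance (`CLIN_SIG`
#'     intersects `adverse_clinsig`);}
#'   \item{R2}{predicted protein damage (`SIFT` in `deleterious_sift`
#'     or `PolyPhen` in `damaging_polyphen`);}
#'   \item{R3}{novel variant (empty `Existing_variation`);}
#'   \item{R4}{`CLIN_SIG`, `SIFT` and `PolyPhen` all empty;}
#'   \item{R5}{`MAX_AF` present and below `rare_af`.}
#' }
#' The reason code records the first rule that fired (the R1..R5 order
#' is attribution only; membership is a logical OR).  The default label
#' sets are package choices and are all configurable.
#'
#' @param ann Consolidated annotation data frame.
#' @param adverse_clinsig Clinical-significance labels counted adverse.
#' @param deleterious_sift SIFT categories counted deleterious.
#' @param damaging_polyphen PolyPhen categories counted damaging.
#' @param rare_af Population-frequency threshold (default 0.01).
#' @return `ann` with logical `retained` and character `reason`
#'   (`"R1"`..`"R5"` or `NA`) columns appended.
#' @export
retain_annotated <- function(ann,
                             adverse_clinsig = c("pathogenic",
                                                 "likely_pathogenic"),
                             deleterious_sift = c("deleterious",
                                                  "deleterious_low_confidence"),
                             damaging_polyphen = c("probably_damaging",
                                                   "possibly_damaging"),
                             rare_af = 0.01) {
  clin <- .split_labels(ann$CLIN_SIG)
  sift <- .strip_score(ann$SIFT)
  poly <- .strip_score(ann$PolyPhen)
  r1 <- vapply(clin, function(l) any(l %in% adverse_clinsig), logical(1))
  r2 <- (!.is_empty_field(ann$SIFT) & sift %in% deleterious_sift) |
    (!.is_empty_field(ann$PolyPhen) & poly %in% damaging_polyphen)
  r3 <- .is_empty_field(ann$Existing_variation)
  r4 <- .is_empty_field(ann$CLIN_SIG) & .is_empty_field(ann$SIFT) &
    .is_empty_field(ann$PolyPhen)
  r5 <- !is.na(ann$MAX_AF) & ann$MAX_AF < rare_af
  rules <- cbind(R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5)
  first <- apply(rules, 1L, function(x) {
    i <- which(x)
    if (length(i)) colnames(rules)[i[1]] else NA_character_
  })
  ann$retained <- !is.na(first)
  ann$reason <- as.character(first)
  ann
}

#' Full annotation stage: consolidate, stratify, retain
#'
#' Joins QC-passed calls with their consolidated annotations, keeps the
#' calls whose impact falls in `stratum` and that satisfy a retention
#' rule, drops configured genes (by default *CRNDE*, reported
#' elsewhere) and flags incidentally enriched genes.
#'
#' @param calls QC-passed `VariantCall` data frame.
#' @param ann Raw (per-transcript) annotation data frame.
#' @param stratum Impact stratum label.
#' @param panel `ov_panel` (used for the incidental-gene flag).
#' @param drop_genes Genes excluded from reports (default `"CRNDE"`).
#' @param ... Passed to [retain_annotated()].
#' @return List: `retained` (calls with `gene`, `impact`, `reason`,
#'   `incidental` columns), `removed` (ledger with gates
#'   `unannotated` / `impact` / `retention` / `dropped_gene`).
#' @export
annotation_stage <- function(calls, ann, stratum = "HIGH_OR_MODERATE",
                             panel = NULL, drop_genes = "CRNDE", ...) {
  cons <- consolidate_annotations(ann)
  if (nrow(cons)) cons <- retain_annotated(cons, ...)
  key_calls <- paste(calls$sample_id, calls$chrom, calls$pos,
                     calls$ref, calls$alt, sep = "\r")
  key_ann <- if (nrow(cons)) {
    paste(cons$SAMPLE, cons$CHROM, cons$POS, cons$REF, cons$ALT, sep = "\r")
  } else character(0)
  m <- match(key_calls, key_ann)
  unann <- is.na(m)
  impact <- cons$IMPACT[m]
  in_stratum <- !unann & impact_in_stratum(impact, stratum)
  kept_rule <- !unann & cons$retained[m]
  dropped <- !unann & cons$SYMBOL[m] %in% drop_genes
  keep <- in_stratum & kept_rule & !dropped
  retained <- calls[keep, , drop = FALSE]
  if (nrow(retained)) {
    retained$gene <- cons$SYMBOL[m[keep]]
    retained$impact <- impact[keep]
    retained$reason <- cons$reason[m[keep]]
    incidental <- if (!is.null(panel)) panel$incidental else character(0)
    retained$incidental <- retained$gene %in% incidental
  } else {
    retained$gene <- character(0)
    retained$impact <- character(0)
    retained$reason <- character(0)
    retained$incidental <- logical(0)
  }
  removed <- rbind(
    .removal_ledger(calls[unann, , drop = FALSE],
                    if (any(unann)) "unannotated" else character(0)),
    .removal_ledger(calls[!unann & !in_stratum, , drop = FALSE],
                    if (any(!unann & !in_stratum)) "impact"
                    else character(0)),
    .removal_ledger(calls[in_stratum & !kept_rule, , drop = FALSE],
                    if (any(in_stratum & !kept_rule)) "retention"
                    else character(0)),
    .removal_ledger(calls[in_stratum & kept_rule & dropped, , drop = FALSE],
                    if (any(in_stratum & kept_rule & dropped)) "dropped_gene"
                    else character(0))
  )
  list(retained = retained, removed = removed)
}
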