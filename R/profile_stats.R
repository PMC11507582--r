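# Gene-level binary alteration matrix and group contrasts.
#
# Entries are 1 (at least one retained variant), 0 (none) or NA
# (MISSING: all of the gene's regions were coverage-excluded for that
# sample).  MISSING entries are excluded pairwise from every 2x2 table
# rather than imputed as 0.

#' Binarize retained variants into a samples x genes 0/1 matrix
#'
#' @param variants Retained variants (data frame with `sample_id` and
#'   `gene` columns), already stratum/class filtered.
#' @param samples Ordered character vector of sample ids (matrix rows).
#' @param genes Ordered character vector of panel gene symbols (matrix
#'   columns).
#' @param missing Optional data frame `sample_id, gene` of MISSING
#'   entries (see [missing_gene_map()]); set to `NA` in the matrix.
#' @param stratum,class_subset Labels recorded as attributes
#'   (`class_subset` one of `snp`, `non_snp`, `combined`).
#' @return Integer matrix with `dimnames = list(samples, genes)` and
#'   attributes `stratum` and `class_subset`; variants in genes outside
#'   `genes` are dropped with a warning and recorded in the
#'   `incidental` attribute.
#' @export
binarize <- function(variants, samples, genes, missing = NULL,
                     stratum = "HIGH_OR_MODERATE",
                     class_subset = c("combined", "snp", "non_snp")) {
  class_subset <- match.arg(class_subset)
  m <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  outside <- NULL
  if (nrow(variants)) {
    known <- variants$gene %in% genes
    if (any(!known)) {
      outside <- variants[!known, , drop = FALSE]
      warning("variant(s) in gene(s) outside the panel assigned to the ",
              "incidental bucket: ",
              paste(unique(outside$gene), collapse = ", "))
    }
    v <- variants[known & variants$sample_id %in% samples, , drop = FALSE]
    m[cbind(match(v$sample_id, samples), match(v$gene, genes))] <- 1L
  }
  if (!is.null(missing) && nrow(missing)) {
    mm <- missing[missing$sample_id %in% samples &
                    missing$gene %in% genes, , drop = FALSE]
    m[cbind(match(mm$sample_id, samples), match(mm$gene, genes))] <- NA
  }
  structure(m, stratum = stratum, class_subset = class_subset,
            incidental = outside, class = c("ov_binmat", class(m)))
}

#' Per-group altered fractions
#'
#' Cumulative alteration frequency of each gene in each tumor group:
#' altered samples over non-MISSING samples.  Groups with zero
#' non-MISSING samples for a gene are reported as absent (no row).
#'
#' @param mat Matrix from [binarize()].
#' @param groups Group label per matrix row (character or factor).
#' @return Data frame `gene, group, n, altered, frequency`.
#' @export
cumulative_frequency <- function(mat, groups) {
  stopifnot(length(groups) == nrow(mat))
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(colnames(mat), function(g) {
    x <- mat[, g]
    do.call(rbind, lapply(unique(groups), function(gr) {
      xx <- x[groups == gr]
      n <- sum(!is.na(xx))
      if (n == 0L) return(NULL)
      data.frame(gene = g, group = gr, n = n,
                 altered = sum(xx, na.rm = TRUE),
                 frequency = sum(xx, na.rm = TRUE) / n,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Omnibus and pairwise rank tests on per-sample variant counts
#'
#' Kruskal-Wallis rank-sum test across all groups, followed by
#' two-sample Wilcoxon rank-sum tests for every group pair.  The
#' Wilcoxon test uses the standard exact/normal-approximation switch
#' (exact for small tie-free samples, continuity-corrected normal
#' otherwise).  Degenerate inputs (all counts identical) yield `NA`
#' p-values by convention.
#'
#' @param counts Numeric vector of per-sample retained-variant counts.
#' @param groups Group label per sample; at least two groups with at
#'   least two samples each.
#' @return List with `omnibus_p` and `pairwise` (data frame
#'   `group_a, group_b, p`).
#' @export
count_distribution_tests <- function(counts, groups) {
  groups <- as.character(groups)
  stopifnot(length(counts) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("argument error: need at least two groups")
  if (any(tab < 2L)) stop("argument error: every group needs >= 2 samples")
  omni <- tryCatch(stats::kruskal.test(counts, factor(groups))$p.value,
                   error = function(e) NA_real_)
  if (!is.na(omni) && !is.finite(omni)) omni <- NA_real_
  pairs <- utils::combn(sort(names(tab)), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- counts[groups == pairs[1, j]]
    b <- counts[groups == pairs[2, j]]
    p <- if (length(unique(c(a, b))) == 1L) NA_real_ else {
      suppressWarnings(stats::wilcox.test(a, b, correct = TRUE)$p.value)
    }
    data.frame(group_a = pairs[1, j], group_b = pairs[2, j], p = p,
               stringsAsFactors = FALSE)
  }))
  list(omnibus_p = omni, pairwise = pw)
}

#' 2x2 contrast of a prebuilt altered/unaltered table
#'
#' Chooses Fisher's exact test when any expected cell count is below 5
#' (`rule = "auto"`), otherwise the chi-squared test without continuity
#' correction; both choices are overridable.  This is the p-value path
#' used by [pairwise_gene_contrast()].
#'
#' @param tab 2x2 matrix: rows = groups, columns = c(altered,
#'   unaltered).
#' @param rule `"auto"`, `"fisher"` or `"chisq"`.
#' @return List with `p_value` and `test_used`.
#' @export
contrast_table <- function(tab, rule = c("auto", "fisher", "chisq")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  n <- sum(tab)
  use_fisher <- switch(rule,
    fisher = TRUE,
    chisq = FALSE,
    auto = {
      expected <- outer(rowSums(tab), colSums(tab)) / n
      any(expected < 5)
    })
  if (use_fisher) {
    list(p_value = stats::fisher.test(tab)$p.value, test_used = "fisher_exact")
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    list(p_value = p, test_used = "chi_squared")
  }
}

#' Pairwise group contrast for one gene
#'
#' Builds the altered/unaltered 2x2 table for two groups (MISSING
#' entries excluded) and tests it with [contrast_table()].  The
#' direction names the group with the higher altered fraction and is
#' undefined when the fractions tie.
#'
#' @param mat Matrix from [binarize()].
#' @param gene Gene symbol (matrix column).
#' @param groups Group label per matrix row.
#' @param group_a,group_b The two groups to contrast.
#' @param rule Test-selection rule, see [contrast_table()].
#' @return Data frame row `gene, group_a, group_b, p_value, direction,
#'   test_used`; `p_value` is `NA` when a table margin is empty.
#' @export
pairwise_gene_contrast <- function(mat, gene, groups, group_a, group_b,
                                   rule = "auto") {
  groups <- as.character(groups)
  x <- mat[, gene]
  a <- x[groups == group_a & !is.na(x)]
  b <- x[groups == group_b & !is.na(x)]
  absent <- data.frame(gene = gene, group_a = group_a, group_b = group_b,
                       p_value = NA_real_, direction = NA_character_,
                       test_used = NA_character_, stringsAsFactors = FALSE)
  if (!length(a) || !length(b)) return(absent)
  tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
  if (any(colSums(tab) == 0L)) {
    # no altered (or no unaltered) sample in either group: degenerate
    res <- list(p_value = 1, test_used = "degenerate")
  } else {
    res <- contrast_table(tab, rule)
  }
  fa <- mean(a); fb <- mean(b)
  direction <- if (fa > fb) group_a else if (fb > fa) group_b
               else NA_character_
  data.frame(gene = gene, group_a = group_a, group_b = group_b,
             p_value = res$p_value, direction = direction,
             test_used = res$test_used, stringsAsFactors = FALSE)
}

#' Long-form comparison report across strata and panels
#'
#' Runs [pairwise_gene_contrast()] for every gene and group pair in
#' each supplied matrix and keeps the contrasts significant at `alpha`.
#' Mirrors the presentation of per-panel/per-stratum comparison tables:
#' uncorrected p-values by default (`p_adjust = "BH"` switches on a
#' Benjamini-Hochberg correction across each matrix).
#'
#' @param mats Named list of [binarize()] matrices (names used as the
#'   `panel_stratum` identifier).
#' @param groups Group label per matrix row (same samples in every
#'   matrix).
#' @param alpha Significance threshold (default 0.05).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust].
#' @param rule Test-selection rule, see [contrast_table()].
#' @return Data frame `panel_stratum, gene, group_a, group_b, p_value,
#'   direction, test_used`, sorted by `panel_stratum`, `gene`, pair.
#' @export
comparison_report <- function(mats, groups, alpha = 0.05,
                              p_adjust = "none", rule = "auto") {
  if (inherits(mats, "ov_binmat")) mats <- list(matrix = mats)
  out <- do.call(rbind, lapply(names(mats), function(nm) {
    mat <- mats[[nm]]
    grp <- sort(unique(as.character(groups)))
    if (length(grp) < 2L) return(NULL)
    pairs <- utils::combn(grp, 2L)
    res <- do.call(rbind, lapply(sort(colnames(mat)), function(g) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        pairwise_gene_contrast(mat, g, groups, pairs[1, j], pairs[2, j],
                               rule = rule)
      }))
    }))
    if (is.null(res) || !nrow(res)) return(NULL)
    if (p_adjust != "none") {
      res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
    }
    res <- res[!is.na(res$p_value) & res$p_value < alpha &
                 res$test_used != "degenerate", , drop = FALSE]
    if (!nrow(res)) return(NULL)
    cbind(panel_stratum = nm, res, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(panel_stratum = character(), gene = character(),
                      group_a = character(), group_b = character(),
                      p_value = numeric(), direction = character(),
                      test_used = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
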