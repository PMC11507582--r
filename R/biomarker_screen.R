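# Matched uni/multivariable Cox and logistic biomarker screening with
# bootstrap cross-validated AUC, time-dependent ROC, Youden cutoff and
# Kaplan-Meier stratification.
#
# The gene predictor is the 0/1 indicator from the binarized matrix.
# Covariate sets are fixed per tumor class: borderline tumors (BOTS)
# adjust for chemotherapy administration, primary-tumor status,
# histotype and age; high-grade carcinomas adjust for histotype, FIGO
# stage and residual tumor category.  Regression is refused for lgOvCa
# (cohort too small for multivariable inference).

.BOTS_ENDPOINTS <- c("RFS", "microinvasion_or_implants")
.HG_ENDPOINTS <- c("OS", "DFS", "CR", "PS")
.SURV_ENDPOINTS <- c("OS", "DFS", "RFS")

.ENDPOINT_COLS <- list(
  OS = c(time = "os_time", event = "os_event"),
  DFS = c(time = "dfs_time", event = "dfs_event"),
  RFS = c(time = "rfs_time", event = "rfs_event"),
  CR = c(outcome = "cr"),
  PS = c(outcome = "ps"),
  microinvasion_or_implants = c(outcome = "mi_implants")
)

#' Analysis specification for one gene/endpoint/subgroup combination
#'
#' @param tumor_class `"BOTS"` or `"hgOvCa"` (regression is not
#'   performed for lgOvCa).
#' @param endpoint BOTS: `RFS` or `microinvasion_or_implants`; hgOvCa:
#'   `OS`, `DFS`, `CR` or `PS`.  DFS is restricted to patients who
#'   achieved complete remission.
#' @param gene Gene symbol whose 0/1 alteration indicator is the
#'   predictor of interest.
#' @param chemo Subgroup filter: `"PC"`, `"TP"` or `"any"`.
#' @param tp53 TP53-accumulation filter (`"yes"`, `"no"`, `"any"`;
#'   carcinomas only).
#' @param bots_subset `"all"`, `"BOT"` or `"BOT.V600E"`.
#' @return An `ov_spec`.
#' @export
screen_spec <- function(tumor_class = c("BOTS", "hgOvCa"), endpoint, gene,
                        chemo = c("any", "PC", "TP"),
                        tp53 = c("any", "yes", "no"),
                        bots_subset = c("all", "BOT", "BOT.V600E")) {
  tumor_class <- match.arg(tumor_class)
  chemo <- match.arg(chemo)
  tp53 <- match.arg(tp53)
  bots_subset <- match.arg(bots_subset)
  valid <- if (tumor_class == "BOTS") .BOTS_ENDPOINTS else .HG_ENDPOINTS
  if (!endpoint %in% valid) {
    stop("argument error: endpoint ", endpoint, " is not defined for ",
         tumor_class, " (valid: ", paste(valid, collapse = ", "), ")")
  }
  covariates <- if (tumor_class == "BOTS") {
    c("chemo_given", "primary_tumor", "histotype", "age")
  } else {
    c("histotype", "figo_stage", "residual_tumor")
  }
  structure(list(tumor_class = tumor_class, endpoint = endpoint,
                 gene = gene, chemo = chemo, tp53 = tp53,
                 bots_subset = bots_subset, covariates = covariates,
                 survival = endpoint %in% .SURV_ENDPOINTS),
            class = "ov_spec")
}

#' Select the patient subgroup of an analysis spec
#'
#' Applies the tumor-class, chemotherapy-regimen and TP53-accumulation
#' filters; DFS specs are additionally restricted to complete-remission
#' patients.  Requesting lgOvCa is refused.
#'
#' @param clinical Clinical data frame (as in a cohort bundle).
#' @param spec An `ov_spec`; alternatively pass the filter fields via
#'   `...` of [screen_spec()].
#' @return The clinical subset, with derived columns `chemo_given`
#'   (logical) and `mi_implants` (logical) appended.
#' @export
build_subgroup <- function(clinical, spec) {
  stopifnot(inherits(spec, "ov_spec"))
  clinical$chemo_given <- clinical$chemo != "none"
  clinical$mi_implants <- clinical$microinvasion | clinical$implants
  keep <- if (spec$tumor_class == "BOTS") {
    if (spec$bots_subset == "all") {
      clinical$group %in% c("BOT", "BOT.V600E")
    } else clinical$group == spec$bots_subset
  } else {
    clinical$group == "hgOvCa"
  }
  if (spec$chemo != "any") keep <- keep & clinical$chemo == spec$chemo
  if (spec$tp53 != "any") {
    keep <- keep & !is.na(clinical$tp53_accumulation) &
      clinical$tp53_accumulation == (spec$tp53 == "yes")
  }
  if (spec$endpoint == "DFS") {
    keep <- keep & !is.na(clinical$cr) & clinical$cr
  }
  out <- clinical[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach a gene's alteration indicator to a clinical subset
#'
#' @param clinical Clinical subset (e.g. from [build_subgroup()]).
#' @param mat Binarized matrix from [binarize()].
#' @param gene Gene symbol.
#' @return `clinical` with a `gene_altered` 0/1 column; samples with a
#'   MISSING entry for the gene are dropped.
#' @export
screen_data <- function(clinical, mat, gene) {
  ind <- mat[match(clinical$sample_id, rownames(mat)), gene]
  out <- clinical[!is.na(ind), , drop = FALSE]
  out$gene_altered <- as.numeric(ind[!is.na(ind)])
  rownames(out) <- NULL
  out
}

.model_formula <- function(spec, mode) {
  rhs <- "gene_altered"
  if (mode == "multivariable") {
    rhs <- paste(c(rhs, spec$covariates), collapse = " + ")
  }
  cols <- .ENDPOINT_COLS[[spec$endpoint]]
  if (spec$survival) {
    stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                              cols[["time"]], cols[["event"]], rhs))
  } else {
    stats::as.formula(sprintf("%s ~ %s", cols[["outcome"]], rhs))
  }
}

.prepare_factors <- function(data, spec) {
  if ("figo_stage" %in% spec$covariates && "figo_stage" %in% names(data)) {
    data$figo_stage <- factor(data$figo_stage)
  }
  if ("residual_tumor" %in% spec$covariates &&
      "residual_tumor" %in% names(data)) {
    data$residual_tumor <- factor(data$residual_tumor,
                                  levels = c("none", "lt2cm", "ge2cm"))
  }
  data
}

.skipped_model <- function(spec, mode, status) {
  structure(list(spec = spec, mode = mode, status = status,
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, ph_ok = NA, auc_original = NA_real_,
                 auc_boot = NA_real_, fit = NULL, covariate_rows = NULL),
            class = "ov_model")
}

#' Fit a Cox proportional-hazards model for one spec
#'
#' Partial-likelihood fit of the endpoint's time-to-event on the binary
#' gene indicator (univariable) or gene + fixed covariates
#' (multivariable), with Wald CI and p-value for the gene term and a
#' proportional-hazards diagnostic (scaled Schoenfeld residual test at
#' alpha 0.05) recorded per model.  The apparent AUC is the
#' time-dependent AUC of the linear predictor at `eval_time`
#' (cumulative cases / dynamic controls), defaulting to the median
#' observed event time.  Non-identifiable situations (zero events,
#' constant gene indicator) return a skipped model with a status
#' notice instead of failing.
#'
#' @param spec An `ov_spec` with a survival endpoint.
#' @param data Output of [screen_data()] on the spec's subgroup.
#' @param mode `"univariable"` or `"multivariable"`.
#' @param eval_time AUC evaluation time; `NULL` for the median event
#'   time.
#' @param diagnostics Compute the proportional-hazards diagnostic
#'   (default `TRUE`; switched off inside the bootstrap loop where it
#'   would only be discarded).
#' @return An `ov_model`: estimate (hazard ratio), `ci_low`, `ci_high`,
#'   `p_value`, `ph_ok`, `auc_original`, `status`, the `fit`, and (for
#'   multivariable models) `covariate_rows` with the covariate effect
#'   estimates.
#' @export
fit_cox <- function(spec, data, mode = c("univariable", "multivariable"),
                    eval_time = NULL, diagnostics = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "ov_spec"), spec$survival)
  cols <- .ENDPOINT_COLS[[spec$endpoint]]
  data <- data[!is.na(data[[cols[["time"]]]]) &
                 !is.na(data[[cols[["event"]]]]), , drop = FALSE]
  if (!nrow(data) || sum(data[[cols[["event"]]]]) == 0) {
    return(.skipped_model(spec, mode, "skipped: zero events"))
  }
  if (length(unique(data$gene_altered)) < 2L) {
    return(.skipped_model(spec, mode, "skipped: constant gene indicator"))
  }
  data <- .prepare_factors(data, spec)
  # separation/convergence issues are detected below and flagged via
  # status, so coxph's own warnings are redundant here
  fit <- suppressWarnings(
    survival::coxph(.model_formula(spec, mode), data = data)
  )
  s <- summary(fit)
  co <- s$coefficients
  i <- match("gene_altered", rownames(co))
  est <- co[i, "exp(coef)"]
  se <- co[i, "se(coef)"]
  ci <- exp(co[i, "coef"] + c(-1, 1) * stats::qnorm(0.975) * se)
  unstable <- is.na(est) || is.na(se) ||
    any(abs(co[, "coef"]) > 15, na.rm = TRUE) ||
    any(co[, "se(coef)"] > 50, na.rm = TRUE)
  ph_ok <- if (!diagnostics) NA else tryCatch({
    z <- survival::cox.zph(fit)
    all(z$table[, "p"] > 0.05, na.rm = TRUE)
  }, error = function(e) NA)
  times <- data[[cols[["time"]]]]
  events <- data[[cols[["event"]]]]
  if (is.null(eval_time)) eval_time <- stats::median(times[events == 1])
  lp <- unname(stats::predict(fit, type = "lp"))
  auc <- .td_auc(lp, times, events, eval_time)
  cov_rows <- NULL
  if (mode == "multivariable") {
    j <- setdiff(seq_len(nrow(co)), i)
    if (length(j)) {
      cov_rows <- data.frame(
        term = rownames(co)[j], estimate = co[j, "exp(coef)"],
        ci_low = exp(co[j, "coef"] - stats::qnorm(0.975) * co[j, "se(coef)"]),
        ci_high = exp(co[j, "coef"] + stats::qnorm(0.975) * co[j, "se(coef)"]),
        p_value = co[j, "Pr(>|z|)"], stringsAsFactors = FALSE)
      rownames(cov_rows) <- NULL
    }
  }
  structure(list(spec = spec, mode = mode,
                 status = if (unstable) "unstable: possible separation"
                          else "ok",
                 estimate = unname(est), ci_low = ci[1], ci_high = ci[2],
                 p_value = unname(co[i, "Pr(>|z|)"]), ph_ok = ph_ok,
                 auc_original = auc,
                 auc_boot = NA_real_, eval_time = eval_time, fit = fit,
                 covariate_rows = cov_rows),
            class = "ov_model")
}

#' Fit a logistic regression model for one spec
#'
#' Maximum-likelihood fit of a binary outcome (CR, PS or
#' microinvasion/implants) on the gene indicator, optionally plus the
#' fixed covariate set.  Complete separation is detected (divergent
#' coefficients or standard errors) and flagged: the model is reported
#' as unstable and excluded from matching rather than refit with a
#' penalty.
#'
#' @inheritParams fit_cox
#' @return An `ov_model` with an odds-ratio estimate; classification
#'   AUC of the fitted probabilities as `auc_original`.
#' @export
fit_logistic <- function(spec, data,
                         mode = c("univariable", "multivariable")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "ov_spec"), !spec$survival)
  col <- .ENDPOINT_COLS[[spec$endpoint]][["outcome"]]
  data <- data[!is.na(data[[col]]), , drop = FALSE]
  if (!nrow(data) || length(unique(data[[col]])) < 2L) {
    return(.skipped_model(spec, mode, "skipped: degenerate outcome"))
  }
  if (length(unique(data$gene_altered)) < 2L) {
    return(.skipped_model(spec, mode, "skipped: constant gene indicator"))
  }
  data <- .prepare_factors(data, spec)
  fit <- suppressWarnings(
    stats::glm(.model_formula(spec, mode), data = data, family = "binomial")
  )
  co <- summary(fit)$coefficients
  i <- match("gene_altered", rownames(co))
  unstable <- !fit$converged || any(abs(co[, "Estimate"]) > 15, na.rm = TRUE) ||
    any(co[, "Std. Error"] > 50, na.rm = TRUE)
  est <- exp(co[i, "Estimate"])
  ci <- exp(co[i, "Estimate"] +
              c(-1, 1) * stats::qnorm(0.975) * co[i, "Std. Error"])
  auc <- binary_auc(stats::fitted(fit), data[[col]])
  cov_rows <- NULL
  if (mode == "multivariable") {
    j <- setdiff(seq_len(nrow(co)), c(1L, i))  # drop intercept
    if (length(j)) {
      cov_rows <- data.frame(
        term = rownames(co)[j], estimate = exp(co[j, "Estimate"]),
        ci_low = exp(co[j, "Estimate"] -
                       stats::qnorm(0.975) * co[j, "Std. Error"]),
        ci_high = exp(co[j, "Estimate"] +
                        stats::qnorm(0.975) * co[j, "Std. Error"]),
        p_value = co[j, "Pr(>|z|)"], stringsAsFactors = FALSE)
      rownames(cov_rows) <- NULL
    }
  }
  structure(list(spec = spec, mode = mode,
                 status = if (unstable) "unstable: possible separation"
                          else "ok",
                 estimate = unname(est), ci_low = ci[1], ci_high = ci[2],
                 p_value = unname(co[i, "Pr(>|z|)"]), ph_ok = NA,
                 auc_original = auc, auc_boot = NA_real_, fit = fit,
                 covariate_rows = cov_rows),
            class = "ov_model")
}

#' Classification AUC (Mann-Whitney, ties at 0.5)
#'
#' @param scores Numeric risk scores.
#' @param outcome Logical/0-1 outcome.
#' @return AUC in \[0, 1\].
#' @export
binary_auc <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC-only fast path of the time-dependent ROC (same cumulative-case /
# dynamic-control convention, no curve construction).
.td_auc <- function(scores, time, status, eval_time) {
  status <- as.logical(status)
  case <- time <= eval_time & status
  control <- time > eval_time
  if (!any(case) || !any(control)) return(NA_real_)
  keep <- case | control
  binary_auc(scores[keep], case[keep])
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative-case / dynamic-control convention: cases are patients
#' with an observed event by `eval_time`, controls are patients still
#' at risk beyond `eval_time`; patients censored before `eval_time`
#' are excluded.  The AUC is the Mann-Whitney statistic of the scores
#' (equivalently the trapezoidal area under the empirical curve).
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param time Observed times.
#' @param status Event indicators (1/TRUE = event).
#' @param eval_time Evaluation horizon (within observed follow-up).
#' @return An `ov_roc`: list with `curve` (data frame `cutoff,
#'   sensitivity, specificity`, one row per observed cutoff), `auc`,
#'   `eval_time`, `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(scores, time, status, eval_time) {
  status <- as.logical(status)
  case <- time <= eval_time & status
  control <- time > eval_time
  if (!any(case) || !any(control)) {
    stop("undefined ROC: no ", if (!any(case)) "cases" else "controls",
         " at eval_time = ", eval_time)
  }
  keep <- case | control
  s <- scores[keep]; y <- case[keep]
  cuts <- sort(unique(s))
  curve <- do.call(rbind, lapply(cuts, function(ct) {
    pred <- s >= ct
    data.frame(cutoff = ct,
               sensitivity = sum(pred & y) / sum(y),
               specificity = sum(!pred & !y) / sum(!y))
  }))
  structure(list(curve = curve, auc = binary_auc(s, y),
                 eval_time = eval_time, n_cases = sum(y),
                 n_controls = sum(!y)),
            class = "ov_roc")
}

#' ROC curve for a binary outcome
#'
#' @inheritParams binary_auc
#' @return An `ov_roc` (see [time_dependent_roc()]).
#' @export
binary_roc <- function(scores, outcome) {
  y <- as.logical(outcome)
  if (!any(y) || all(y)) stop("degenerate outcome: one class absent")
  cuts <- sort(unique(scores))
  curve <- do.call(rbind, lapply(cuts, function(ct) {
    pred <- scores >= ct
    data.frame(cutoff = ct,
               sensitivity = sum(pred & y) / sum(y),
               specificity = sum(!pred & !y) / sum(!y))
  }))
  structure(list(curve = curve, auc = binary_auc(scores, y),
                 eval_time = NA_real_, n_cases = sum(y),
                 n_controls = sum(!y)),
            class = "ov_roc")
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed
#' cutoffs; ties break toward the lowest cutoff.  A flat curve (max J
#' approximately 0) is flagged.
#'
#' @param roc An `ov_roc`.
#' @return List `cutoff, sensitivity, specificity, youden, flat`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ov_roc"))
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- which(j == max(j))[1]  # curve sorted by increasing cutoff
  list(cutoff = roc$curve$cutoff[best],
       sensitivity = roc$curve$sensitivity[best],
       specificity = roc$curve$specificity[best],
       youden = j[best],
       flat = max(j) <= 1e-12)
}

#' Kaplan-Meier stratification at a risk cutoff
#'
#' Splits patients into high (score above cutoff) and low risk strata,
#' fits product-limit curves per stratum and reports the two-sample
#' log-rank statistic and p-value.
#'
#' @param time,status Survival data.
#' @param scores Risk scores.
#' @param cutoff Risk cutoff (high = `score > cutoff`).
#' @return List `fit` ([survival::survfit]), `chisq`, `p_value`,
#'   `strata` (table of group sizes).
#' @export
km_stratify <- function(time, status, scores, cutoff) {
  risk <- factor(ifelse(scores > cutoff, "high", "low"),
                 levels = c("low", "high"))
  if (any(table(risk) == 0)) {
    stop("empty risk stratum at cutoff ", cutoff)
  }
  d <- data.frame(time = time, status = as.numeric(status), risk = risk)
  fit <- survival::survfit(survival::Surv(time, status) ~ risk, data = d)
  lr <- survival::survdiff(survival::Surv(time, status) ~ risk, data = d)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(lr$chisq), p_value = p,
       strata = table(risk))
}

#' Bootstrap cross-validated AUC
#'
#' Resamples the dataset with replacement `B` times, refits the model
#' on each replicate and evaluates its AUC on that replicate
#' (time-dependent AUC at the original evaluation horizon for survival
#' endpoints, classification AUC otherwise).  Returns the mean across
#' successful replicates.  Deterministic given `seed`.
#'
#' @param spec An `ov_spec`.
#' @param data Output of [screen_data()].
#' @param mode `"univariable"` or `"multivariable"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param eval_time Evaluation horizon for survival endpoints; `NULL`
#'   for the original data's median event time.
#' @return List `auc_boot` (mean replicate AUC) and `B_effective`.
#' @export
bootstrap_auc <- function(spec, data, mode = "univariable", B = 1000,
                          seed = 1L, eval_time = NULL) {
  if (B < 1) stop("argument error: B must be >= 1")
  set.seed(seed)
  cols <- .ENDPOINT_COLS[[spec$endpoint]]
  if (spec$survival && is.null(eval_time)) {
    t0 <- data[[cols[["time"]]]]
    e0 <- data[[cols[["event"]]]]
    eval_time <- stats::median(t0[!is.na(e0) & e0 == 1], na.rm = TRUE)
  }
  aucs <- rep(NA_real_, B)
  n <- nrow(data)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- data[idx, , drop = FALSE]
    aucs[b] <- tryCatch({
      if (spec$survival) {
        m <- fit_cox(spec, d, mode, eval_time = eval_time,
                     diagnostics = FALSE)
      } else {
        m <- fit_logistic(spec, d, mode)
      }
      m$auc_original
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(aucs)
  list(auc_boot = if (any(ok)) mean(aucs[ok]) else NA_real_,
       B_effective = sum(ok))
}

#' Match a univariable model with its multivariable counterpart
#'
#' A gene/endpoint/subgroup combination is matched when (C1) both
#' p-values are below `alpha`, (C2) both effect estimates lie on the
#' same side of 1, and (C3) every AUC of both models (apparent and
#' bootstrap) strictly exceeds `auc_floor`.  Models that were skipped
#' or flagged unstable never match.
#'
#' @param uni,multi `ov_model` objects sharing gene and spec.
#' @param alpha Significance threshold (default 0.05).
#' @param auc_floor AUC floor (default 0.65; strict `>`).
#' @return An `ov_match`: list `gene, spec, matched, reasons`.
#' @export
match_models <- function(uni, multi, alpha = 0.05, auc_floor = 0.65) {
  stopifnot(inherits(uni, "ov_model"), inherits(multi, "ov_model"))
  if (!identical(uni$spec$gene, multi$spec$gene) ||
      !identical(uni$spec$endpoint, multi$spec$endpoint) ||
      !identical(uni$spec$tumor_class, multi$spec$tumor_class)) {
    stop("argument error: models do not share gene and spec")
  }
  reasons <- character(0)
  if (uni$status != "ok" || multi$status != "ok" ||
      anyNA(c(uni$p_value, multi$p_value, uni$estimate, multi$estimate))) {
    reasons <- c(reasons, "estimation")
  } else {
    if (!(uni$p_value < alpha && multi$p_value < alpha)) {
      reasons <- c(reasons, "significance")
    }
    same_side <- (uni$estimate > 1 && multi$estimate > 1) ||
      (uni$estimate < 1 && multi$estimate < 1)
    if (!same_side) reasons <- c(reasons, "direction")
    aucs <- c(uni$auc_original, uni$auc_boot,
              multi$auc_original, multi$auc_boot)
    if (any(is.na(aucs)) || !all(aucs > auc_floor)) {
      reasons <- c(reasons, "auc")
    }
  }
  structure(list(gene = uni$spec$gene, spec = uni$spec,
                 matched = length(reasons) == 0L, reasons = reasons,
                 uni = uni, multi = multi),
            class = "ov_match")
}

#' Screen genes over analysis specs
#'
#' For each spec: builds the subgroup, attaches the gene indicator,
#' fits the univariable and multivariable models, bootstrap
#' cross-validates both AUCs and applies the matching decision.  Empty
#' or degenerate combinations are skipped with a notice, not an error.
#'
#' @param clinical Clinical data frame.
#' @param mat Binarized matrix from [binarize()].
#' @param specs List of `ov_spec` objects.
#' @param B Bootstrap replicates per model.
#' @param seed Integer seed (each spec uses a derived sub-seed).
#' @param alpha,auc_floor Matching thresholds, see [match_models()].
#' @return An `ov_screen`: list with `decisions` (list of `ov_match`)
#'   and `results` (one data frame row per fitted model).
#' @export
screen_genes <- function(clinical, mat, specs, B = 1000, seed = 1L,
                         alpha = 0.05, auc_floor = 0.65) {
  decisions <- vector("list", length(specs))
  rows <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    sub <- build_subgroup(clinical, spec)
    d <- screen_data(sub, mat, spec$gene)
    fit1 <- if (spec$survival) fit_cox(spec, d, "univariable")
            else fit_logistic(spec, d, "univariable")
    fit2 <- if (spec$survival) fit_cox(spec, d, "multivariable")
            else fit_logistic(spec, d, "multivariable")
    if (fit1$status == "ok") {
      fit1$auc_boot <- bootstrap_auc(spec, d, "univariable", B = B,
                                     seed = seed + 2L * k)$auc_boot
    }
    if (fit2$status == "ok") {
      fit2$auc_boot <- bootstrap_auc(spec, d, "multivariable", B = B,
                                     seed = seed + 2L * k + 1L)$auc_boot
    }
    decisions[[k]] <- match_models(fit1, fit2, alpha = alpha,
                                   auc_floor = auc_floor)
    rows[[k]] <- do.call(rbind, lapply(list(fit1, fit2), function(m) {
      data.frame(tumor_class = spec$tumor_class, endpoint = spec$endpoint,
                 chemo = spec$chemo, tp53 = spec$tp53,
                 bots_subset = spec$bots_subset, gene = spec$gene,
                 mode = m$mode, status = m$status, n = nrow(d),
                 estimate = m$estimate, ci_low = m$ci_low,
                 ci_high = m$ci_high, p_value = m$p_value,
                 ph_ok = if (is.null(m$ph_ok)) NA else m$ph_ok,
                 auc_original = m$auc_original, auc_boot = m$auc_boot,
                 matched = decisions[[k]]$matched,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(decisions = decisions,
                 results = do.call(rbind, rows)),
            class = "ov_screen")
}

#' Report of matched models only
#'
#' Long table with one row per matched gene model (multivariable
#' estimates shown with their covariate contrast rows, mirroring the
#' usual matched-model presentation).
#'
#' @param screen An `ov_screen` from [screen_genes()], or a list of
#'   `ov_match` decisions.
#' @return Data frame `tumor_class, endpoint, chemo, tp53, bots_subset,
#'   term, mode, estimate, ci_low, ci_high, p_value`.
#' @export
screen_report <- function(screen) {
  decisions <- if (inherits(screen, "ov_screen")) screen$decisions
               else screen
  empty <- data.frame(tumor_class = character(), endpoint = character(),
                      chemo = character(), tp53 = character(),
                      bots_subset = character(), term = character(),
                      mode = character(), estimate = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rows <- lapply(decisions, function(dec) {
    if (!dec$matched) return(NULL)
    spec <- dec$spec
    hdr <- function(m, term) {
      data.frame(tumor_class = spec$tumor_class, endpoint = spec$endpoint,
                 chemo = spec$chemo, tp53 = spec$tp53,
                 bots_subset = spec$bots_subset, term = term,
                 mode = m$mode, estimate = m$estimate, ci_low = m$ci_low,
                 ci_high = m$ci_high, p_value = m$p_value,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(hdr(dec$uni, spec$gene), hdr(dec$multi, spec$gene))
    cr <- dec$multi$covariate_rows
    if (!is.null(cr) && nrow(cr)) {
      out <- rbind(out, data.frame(
        tumor_class = spec$tumor_class, endpoint = spec$endpoint,
        chemo = spec$chemo, tp53 = spec$tp53,
        bots_subset = spec$bots_subset, term = cr$term,
        mode = "multivariable", estimate = cr$estimate,
        ci_low = cr$ci_low, ci_high = cr$ci_high, p_value = cr$p_value,
        stringsAsFactors = FALSE))
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ov_model <- function(x, ...) {
  cat(sprintf("<ov_model> %s %s %s | %s | %s\n",
              x$spec$tumor_class, x$spec$endpoint, x$spec$gene, x$mode,
              x$status))
  if (x$status == "ok") {
    cat(sprintf("  estimate %.3f [%.3f, %.3f], p = %.4g, AUC %.3f (boot %.3f)\n",
                x$estimate, x$ci_low, x$ci_high, x$p_value,
                x$auc_original, x$auc_boot))
  }
  invisible(x)
}
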