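test_that("build_subgroup applies every filter like a brute-force scan", {
  b <- generate_cohort(small_config(seed = 71,
                                    group_sizes = c(BOT = 30, BOT.V600E = 15,
                                                    lgOvCa = 5,
                                                    hgOvCa = 80)))
  cl <- b$clinical
  spec <- screen_spec("hgOvCa", "OS", "TP53", chemo = "TP", tp53 = "no")
  sub <- build_subgroup(cl, spec)
  oracle <- cl[cl$group == "hgOvCa" & cl$chemo == "TP" &
                 !is.na(cl$tp53_accumulation) & !cl$tp53_accumulation, ]
  expect_setequal(sub$sample_id, oracle$sample_id)
  # {any, any} is the identity on the tumor class
  sub2 <- build_subgroup(cl, screen_spec("hgOvCa", "OS", "TP53"))
  expect_setequal(sub2$sample_id, cl$sample_id[cl$group == "hgOvCa"])
  # DFS restricted to complete-remission patients
  sub3 <- build_subgroup(cl, screen_spec("hgOvCa", "DFS", "TP53"))
  expect_true(all(sub3$cr))
  # lgOvCa refused; endpoint/tumor-class mismatches refused
  expect_error(screen_spec("lgOvCa", "OS", "TP53"))
  expect_error(screen_spec("BOTS", "OS", "TP53"), "not defined")
  expect_error(screen_spec("hgOvCa", "RFS", "TP53"), "not defined")
})

test_that("fit_cox recovers a planted PARP1-like hazard ratio", {
  cfg <- cohort_config(
    group_sizes = c(BOT = 1400, BOT.V600E = 600, lgOvCa = 0, hgOvCa = 0),
    panel = default_panel("genes44"),
    gene_freqs = data.frame(gene = "PARP1", group = c("BOT", "BOT.V600E"),
                            stratum = "HIGH_OR_MODERATE", prob = 0.4),
    noise_vaf_rate = 0, decoy_rate = 0, lowcov_region_rate = 0,
    survival_effects = data.frame(gene = "PARP1", endpoint = "RFS",
                                  log_hr = log(6.82)),
    censoring_rate = 0.2, seed = 72)
  b <- generate_cohort(cfg)
  mat <- binarize(b$calls[b$calls$origin == "planted", ],
                  b$clinical$sample_id, "PARP1")
  spec <- screen_spec("BOTS", "RFS", "PARP1")
  d <- screen_data(build_subgroup(b$clinical, spec), mat, "PARP1")
  fit <- fit_cox(spec, d, "univariable")
  expect_identical(fit$status, "ok")
  expect_gt(fit$estimate, 5.5)
  expect_lt(fit$estimate, 8.5)
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
  expect_lt(fit$p_value, 1e-10)
  # degenerate inputs are skipped with a notice, not an error
  d0 <- d; d0$rfs_event <- FALSE
  expect_match(fit_cox(spec, d0, "univariable")$status, "zero events")
  d1 <- d; d1$gene_altered <- 0
  expect_match(fit_cox(spec, d1, "univariable")$status, "constant gene")
})

test_that("fit_logistic recovers a planted BRCA2-like odds ratio", {
  cfg <- cohort_config(
    group_sizes = c(BOT = 0, BOT.V600E = 0, lgOvCa = 0, hgOvCa = 2000),
    panel = default_panel("genes44"),
    gene_freqs = data.frame(gene = c("BRCA2", "FANCC"), group = "hgOvCa",
                            stratum = "HIGH_OR_MODERATE", prob = 0.4),
    noise_vaf_rate = 0, decoy_rate = 0, lowcov_region_rate = 0,
    response_effects = data.frame(gene = "BRCA2", outcome = "CR",
                                  log_or = log(7.06)),
    seed = 73)
  b <- generate_cohort(cfg)
  mat <- binarize(b$calls[b$calls$origin == "planted", ],
                  b$clinical$sample_id, c("BRCA2", "FANCC"))
  spec <- screen_spec("hgOvCa", "CR", "BRCA2")
  d <- screen_data(build_subgroup(b$clinical, spec), mat, "BRCA2")
  fit <- fit_logistic(spec, d, "univariable")
  expect_identical(fit$status, "ok")
  expect_gt(fit$estimate, 5)
  expect_lt(fit$estimate, 10)
  # null gene: OR near 1, CI covers 1
  dn <- screen_data(build_subgroup(b$clinical, spec), mat, "FANCC")
  fitn <- fit_logistic(screen_spec("hgOvCa", "CR", "FANCC"), dn,
                       "univariable")
  expect_true(fitn$ci_low < 1 && fitn$ci_high > 1)
  # one outcome class absent
  d2 <- d; d2$cr <- TRUE
  expect_match(fit_logistic(spec, d2, "univariable")$status,
               "degenerate outcome")
})

test_that("ROC machinery matches quadrature and brute-force oracles", {
  set.seed(81)
  # perfectly separating marker
  y <- rep(c(FALSE, TRUE), each = 25)
  s <- ifelse(y, 2, 1)
  roc <- binary_roc(s, y)
  expect_equal(roc$auc, 1.0)
  yd <- youden_cutoff(roc)
  expect_equal(yd$youden, 1.0)
  expect_equal(yd$cutoff, 2)
  # uninformative scores: AUC near 0.5, J near 0
  y2 <- runif(2000) < 0.5
  s2 <- runif(2000)
  roc2 <- binary_roc(s2, y2)
  expect_lt(abs(roc2$auc - 0.5), 0.03)
  expect_lt(youden_cutoff(roc2)$youden, 0.1)
  # trapezoidal quadrature over the empirical curve equals the AUC
  s3 <- sample(1:8, 300, TRUE)  # heavy ties exercise the 0.5 convention
  y3 <- runif(300) < plogis(s3 - 4.5)
  roc3 <- binary_roc(s3, y3)
  fpr <- c(1, 1 - roc3$curve$specificity, 0)
  tpr <- c(1, roc3$curve$sensitivity, 0)
  auc_trap <- sum((fpr[-length(fpr)] - fpr[-1]) *
                    (tpr[-length(tpr)] + tpr[-1]) / 2)
  expect_equal(roc3$auc, auc_trap, tolerance = 1e-12)
  # Youden equals a brute-force scan over all observed thresholds
  j_brute <- vapply(sort(unique(s3)), function(ct) {
    mean(s3[y3] >= ct) + mean(s3[!y3] < ct) - 1
  }, numeric(1))
  expect_equal(youden_cutoff(roc3)$youden, max(j_brute))
  cuts <- sort(unique(s3))
  expect_equal(youden_cutoff(roc3)$cutoff,
               cuts[which(j_brute == max(j_brute))[1]])
})

test_that("time-dependent ROC uses cumulative cases / dynamic controls", {
  set.seed(82)
  time <- c(1, 2, 3, 10, 11, 12)
  status <- c(1, 1, 0, 0, 0, 1)
  # risk score = event-by-t indicator gives AUC 1
  roc <- time_dependent_roc(c(9, 9, 0, 1, 1, 1), time, status, eval_time = 5)
  expect_equal(roc$n_cases, 2L)     # events at 1, 2
  expect_equal(roc$n_controls, 3L)  # at risk beyond 5; censored-at-3 dropped
  expect_equal(roc$auc, 1.0)
  # random scores at large n: AUC about 0.5
  n <- 3000
  tt <- rexp(n); ss <- rep(1, n)
  roc2 <- time_dependent_roc(runif(n), tt, ss, eval_time = median(tt))
  expect_lt(abs(roc2$auc - 0.5), 0.03)
  expect_error(time_dependent_roc(runif(5), rep(10, 5), rep(1, 5), 1),
               "no cases")
})

test_that("km_stratify matches the hand-enumerated log-rank statistic", {
  # 6 patients, all events: group A at 1,2,3; group B at 4,5,6
  time <- 1:6
  status <- rep(1, 6)
  scores <- c(1, 1, 1, 0, 0, 0)
  res <- km_stratify(time, status, scores, cutoff = 0.5)
  # hand enumeration: O-E and variance summed over event times
  o_e <- 0; v <- 0
  at_risk <- data.frame(t = time, high = scores > 0.5)
  for (t in time) {
    alive <- at_risk$t >= t
    n <- sum(alive); n_high <- sum(at_risk$high[alive])
    e <- n_high / n
    o_e <- o_e + (at_risk$high[at_risk$t == t] - e)
    if (n > 1) v <- v + n_high * (n - n_high) / n^2
  }
  expect_equal(res$chisq, o_e^2 / v, tolerance = 1e-10)
  expect_error(km_stratify(time, status, scores, cutoff = 2), "empty")
})

test_that("km separation at HR 4 gives log-rank p < 0.001", {
  set.seed(83)
  for (rep in 1:5) {
    n <- 500
    high <- runif(n) < 0.5
    time <- rexp(n, 0.01 * ifelse(high, 4, 1))
    res <- km_stratify(time, rep(1, n), as.numeric(high), 0.5)
    expect_lt(res$p_value, 0.001)
  }
})

test_that("bootstrap AUC is deterministic and near 0.5 for null markers", {
  set.seed(84)
  n <- 1000
  d <- data.frame(gene_altered = as.numeric(runif(n) < 0.4),
                  cr = runif(n) < 0.6)
  spec <- screen_spec("hgOvCa", "CR", "G")
  b1 <- bootstrap_auc(spec, d, "univariable", B = 200, seed = 9)
  b2 <- bootstrap_auc(spec, d, "univariable", B = 200, seed = 9)
  expect_identical(b1, b2)
  expect_lt(abs(b1$auc_boot - 0.5), 0.03)
  expect_error(bootstrap_auc(spec, d, "univariable", B = 0), "B must be")
})

test_that("match_models applies C1-C3 with a strict AUC floor", {
  spec <- screen_spec("BOTS", "RFS", "PARP1")
  model <- function(est, p, auc, auc_boot = auc, status = "ok") {
    structure(list(spec = spec, mode = "x", status = status, estimate = est,
                   ci_low = est / 2, ci_high = est * 2, p_value = p,
                   ph_ok = TRUE, auc_original = auc, auc_boot = auc_boot),
              class = "ov_model")
  }
  good <- match_models(model(6.8, 0.01, 0.75), model(6.8, 0.01, 0.78))
  expect_true(good$matched)
  # C2: estimates on opposite sides of 1
  dir <- match_models(model(1.4, 0.01, 0.8), model(0.8, 0.01, 0.8))
  expect_false(dir$matched)
  expect_true("direction" %in% dir$reasons)
  # C3: AUC exactly at the floor never matches (strict >)
  floor <- match_models(model(6.8, 0.01, 0.65), model(6.8, 0.01, 0.8))
  expect_false(floor$matched)
  expect_true("auc" %in% floor$reasons)
  # skipped/unstable models never match
  bad <- match_models(model(6.8, 0.01, 0.8, status = "unstable"),
                      model(6.8, 0.01, 0.8))
  expect_identical(bad$reasons, "estimation")
  # monotone: lowering alpha or raising the floor never adds matches
  m1 <- model(6.8, 0.03, 0.70); m2 <- model(6.8, 0.04, 0.72)
  for (alpha in c(0.05, 0.035, 0.01)) {
    strict <- match_models(m1, m2, alpha = alpha)$matched
    loose <- match_models(m1, m2, alpha = 0.05)$matched
    expect_true(loose >= strict)
  }
  for (fl in c(0.6, 0.65, 0.71, 0.8)) {
    strict <- match_models(m1, m2, auc_floor = fl)$matched
    loose <- match_models(m1, m2, auc_floor = 0.6)$matched
    expect_true(loose >= strict)
  }
  expect_error(match_models(model(2, 0.1, 0.7),
                            structure(list(spec = screen_spec("BOTS", "RFS",
                                                              "TP53"),
                                           status = "ok"),
                                      class = "ov_model")),
               "share gene")
})

test_that("screen_report row count equals matched decisions", {
  b <- generate_cohort(small_config(seed = 85))
  run <- run_pipeline(b, strata = "HIGH_OR_MODERATE",
                      class_subsets = "combined")
  mat <- run$matrices[[1]]
  specs <- list(screen_spec("hgOvCa", "OS", "TP53"),
                screen_spec("hgOvCa", "OS", "KRAS"))
  sc <- screen_genes(b$clinical, mat, specs, B = 20, seed = 2)
  rep_tab <- screen_report(sc)
  n_matched <- sum(vapply(sc$decisions, `[[`, logical(1), "matched"))
  # two rows (uni+multi) per matched model plus covariate contrast rows
  gene_rows <- rep_tab[rep_tab$term %in% c("TP53", "KRAS"), ]
  expect_equal(nrow(gene_rows), 2L * n_matched)
  expect_equal(nrow(screen_report(list())), 0L)
})
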