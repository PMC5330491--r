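test_that("AUC matches hand-counted concordant pairs and boundary cases", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_identical(roc_auc(c(1, 1, 0), c(0.9, 0.8, 0.1))$auc, 1)
  # ties count one half
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both outcome classes")
})

test_that("ROC points are monotone and AUC is near 0.5 for uninformative scores", {
  set.seed(31)
  lab <- rbinom(4000, 1, 0.5)
  sc <- runif(4000)
  roc <- roc_auc(lab, sc)
  expect_lt(abs(roc$auc - 0.5), 0.03)
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_true(all(diff(roc$points$fpr) >= 0))
})

test_that("rank-based AUC equals brute-force pair counting", {
  set.seed(32)
  for (n in c(10, 37, 120, 500)) {
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0, 1)
    sc <- round(rnorm(n), 1)  # coarse scores force ties
    expect_equal(roc_auc(lab, sc)$auc, auc_bruteforce(lab, sc))
  }
})

test_that("DeLong test: identical models give P = 1, swapping negates z", {
  set.seed(33)
  lab <- rep(c(1, 0), each = 15)
  pa <- plogis(rnorm(30) + lab)
  pb <- plogis(rnorm(30) + 0.5 * lab)
  same <- delong_test(lab, pa, pa)
  expect_identical(same$p_value, 1)
  expect_true(same$degenerate)
  ab <- delong_test(lab, pa, pb)
  ba <- delong_test(lab, pb, pa)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("DeLong agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  lab <- rep(c(1, 0), each = 20)
  pa <- plogis(rnorm(40) + 1.2 * lab)
  pb <- plogis(rnorm(40) + 0.6 * lab)
  mine <- delong_test(lab, pa, pb)
  ref <- pROC::roc.test(pROC::roc(lab, pa, quiet = TRUE),
                        pROC::roc(lab, pb, quiet = TRUE), method = "delong")
  expect_equal(mine$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(abs(mine$statistic), abs(as.numeric(ref$statistic)),
               tolerance = 1e-8)
})

test_that("exact binomial accuracy test matches closed forms and brute force", {
  # all correct: tail collapses to nir^total
  expect_equal(binomial_accuracy_test(10, 10, 0.642), 0.642^10)
  # at the expected count the upper tail is near one half
  p_center <- binomial_accuracy_test(round(100 * 0.642), 100, 0.642)
  expect_gt(p_center, 0.3); expect_lt(p_center, 0.7)
  # brute-force summation of binomial terms
  brute <- sum(dbinom(79:109, 109, 0.642))
  expect_equal(binomial_accuracy_test(79, 109, 0.642), brute,
               tolerance = 1e-12)
})

test_that("GLMM without patient effects reduces to plain logistic regression", {
  set.seed(35)
  d <- simulate_glmm_data(n_patients = 150, n_pairs = 3,
                          beta = c(dcv = 0.8, dfv = 0, scv = 0, sfv = 0),
                          sd_patient = 0)
  fit <- suppressWarnings(fit_glmm(d, model_spec(c("dcv"))))
  ref <- glm(progression ~ dcv, binomial(), d)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 0.02)
  expect_lt(fit$ranef_sd, 0.25)
})

test_that("single-class outcomes and tiny cohorts are rejected", {
  d <- simulate_glmm_data(n_patients = 10, n_pairs = 2)
  d$progression <- 1
  expect_error(fit_glmm(d), "single class")
  d2 <- simulate_glmm_data(n_patients = 1, n_pairs = 5)
  expect_error(fit_glmm(d2), "2 patients")
})

test_that("cross-validation covers every observation once, reproducibly", {
  set.seed(36)
  d <- simulate_glmm_data(n_patients = 25, n_pairs = 4)
  spec <- model_spec(c("dcv", "dfv"), n_folds = 5, fold_seed = 7)
  cv1 <- crossvalidate(d, spec)
  cv2 <- crossvalidate(d, spec)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$prob, cv2$prob)
  expect_true(all(!is.na(cv1$prob)))
  expect_true(all(cv1$prob >= 0 & cv1$prob <= 1))
  # grouped folds: every patient confined to one fold
  expect_true(all(tapply(cv1$fold, cv1$patient_id,
                         function(f) length(unique(f))) == 1))
  # leave-one-patient-out at the fold-count boundary
  spec_lopo <- model_spec(c("dcv"), n_folds = 25, fold_seed = 1)
  cv3 <- suppressWarnings(crossvalidate(d, spec_lopo))
  expect_identical(length(unique(cv3$fold)), 25L)
  expect_error(crossvalidate(d, model_spec(c("dcv"), n_folds = 26)),
               "more folds")
})

test_that("cross-validated AUC tracks training AUC on strong-signal cohorts", {
  set.seed(37)
  d <- simulate_glmm_data(n_patients = 150, n_pairs = 4,
                          beta = c(dcv = 1.2, dfv = 0, scv = 0, sfv = 0))
  spec <- model_spec(c("dcv"), n_folds = 5, fold_seed = 2)
  fit <- suppressWarnings(fit_glmm(d, spec))
  train_prob <- predict(fit$model, type = "response", re.form = NA)
  train_auc <- roc_auc(d$progression, as.numeric(train_prob))$auc
  cv <- crossvalidate(d, spec)
  expect_lt(abs(roc_auc(cv$progression, cv$prob)$auc - train_auc), 0.05)
})

test_that("model comparison returns coherent per-model and paired statistics", {
  co <- simulate_cohort_table(phantom_spec(seed = 12))
  rec <- label_records(change_records(co$scans), co$mc_sources)
  cmp <- suppressWarnings(compare_models(rec, fold_seed = 3))
  for (m in list(cmp$delta, cmp$subtraction)) {
    expect_true(m$auc >= 0 && m$auc <= 1)
    expect_true(m$accuracy >= 0 && m$accuracy <= 1)
    expect_identical(m$correct <= m$n, TRUE)
  }
  expect_equal(cmp$delong$auc_a, cmp$delta$auc)
  expect_equal(cmp$delong$auc_b, cmp$subtraction$auc)
  expect_gt(cmp$nir, 0.5)
  expect_identical(nrow(cmp$joint$coefficients), 5L)
})
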