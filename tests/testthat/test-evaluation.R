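test_that("rms pools within subject, then over subjects and folds", {
  expect_equal(rms_error(c(1, 2, 3), c(1, 2, 3), rep("a", 3)), 0)
  # one subject, four appointments, every error 2
  expect_equal(rms_error(rep(0, 4), rep(2, 4), rep("a", 4)), 2)
  # two subjects with per-subject mean squared errors 1 and 9
  expect_equal(rms_error(c(0, 0), c(1, 3), c("a", "b")), sqrt(5))
  # a constant shift of a perfect predictor scores |c|
  y <- rnorm(10)
  expect_equal(rms_error(y, y + 0.3, rep(c("a", "b"), 5)), 0.3)
  # subjects weighted equally regardless of course length
  expect_equal(rms_error(c(0, 0, 0), c(2, 0, 1),
                         c("a", "a", "b")),
               sqrt(mean(c(mean(c(4, 0)), 1))))
  expect_error(rms_error(numeric(0), numeric(0), character(0)), "no predictions")
})

test_that("critical-value classification is inclusive and monotone", {
  # c = 0 reduces to plain point-estimate thresholding
  expect_identical(classify_remission(c(-1, -0.5), -0.97),
                   c(TRUE, FALSE))
  # boundary: point estimate exactly threshold + c counts as remission
  expect_true(classify_remission(-0.97 + 0.3, -0.97, critical_value = 0.3))
  # very large critical value labels everything remission
  expect_true(all(classify_remission(rnorm(50, 5), -0.97,
                                     critical_value = 1e6)))
})

test_that("confusion metrics reproduce their defining ratios", {
  m <- confusion_metrics(list(tp = 0, fp = 0, fn = 10, tn = 90))
  expect_equal(m$sen, 0)
  expect_equal(m$spc, 1)
  expect_equal(m$bac, 0.5)
  expect_true(is.na(m$ppv))   # undefined, flagged not propagated
  set.seed(10)
  for (i in 1:10) {
    cm <- list(tp = sample(0:50, 1) + 1, fp = sample(0:50, 1),
               fn = sample(0:50, 1), tn = sample(0:50, 1) + 1)
    m <- confusion_metrics(cm)
    expect_equal(m$bac, (m$sen + m$spc) / 2)
    expect_equal(m$youden_j, 2 * m$bac - 1)
    expect_equal(m$accuracy,
                 (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn))
    expect_gte(m$bac, min(m$sen, m$spc))
    expect_lte(m$bac, max(m$sen, m$spc))
  }
})

test_that("ROC endpoints and degenerate cases behave", {
  # perfectly separated scores
  roc <- roc_curve(c(-3, -2.5, 1, 2), c(1, 1, 0, 0), threshold = -0.97,
                   type = "additive")
  expect_equal(roc$auc, 1)
  # uninformative identical scores
  roc2 <- roc_curve(rep(0.5, 20), rep(c(1, 0), 10), threshold = -0.97,
                    type = "additive")
  expect_equal(roc2$auc, 0.5)
  expect_error(roc_curve(rnorm(5), rep(1, 5), -0.97), "both classes")
})

test_that("trapezoid AUC equals the pairwise concordance oracle", {
  set.seed(42)
  for (rep in 1:5) {
    score <- rnorm(30)
    label <- rbinom(30, 1, 0.4)
    if (all(label == label[1])) label[1] <- 1 - label[1]
    roc <- roc_curve(score, label, threshold = -0.97, type = "additive")
    expect_equal(roc$auc, concordance_auc(score, label), tolerance = 1e-9)
  }
  # independent library cross-check on one instance
  score <- rnorm(40); label <- rbinom(40, 1, 0.3)
  if (all(label == label[1])) label[1] <- 1 - label[1]
  roc <- roc_curve(score, label, threshold = -0.97, type = "additive")
  ref <- pROC::auc(pROC::roc(label, -score, direction = "<", quiet = TRUE))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("sensitivity rises and specificity falls along the sweep", {
  set.seed(17)
  score <- rnorm(80, -0.5, 0.8)
  label <- rbinom(80, 1, plogis(-2 * score - 2))
  if (all(label == label[1])) label[1] <- 1 - label[1]
  for (ty in c("additive", "quantile")) {
    roc <- roc_curve(score, label, threshold = -0.97, type = ty,
                     scale_sq = runif(80, 0.5, 2), nu = rep(6, 80))
    pts <- roc$points[order(roc$points$critical), ]
    expect_true(all(diff(pts$sen) >= -1e-12))
    expect_true(all(diff(pts$spc) <= 1e-12))
  }
})

test_that("operating-point selection maximizes training balanced accuracy", {
  # perfectly separated at c = 0: zero critical value already optimal
  op <- select_operating_point(c(-3, -2, 1, 2), c(1, 1, 0, 0),
                               threshold = -0.97, type = "additive")
  expect_equal(op$critical, 0)
  expect_equal(op$bac, 1)
  # tie-break toward the smaller critical value on a plateau
  set.seed(23)
  score <- rnorm(60, 0, 1)
  label <- rbinom(60, 1, plogis(-score))
  if (all(label == label[1])) label[1] <- 1 - label[1]
  grid <- seq(0, 3, by = 0.1)
  op2 <- select_operating_point(score, label, threshold = -0.97,
                                grid = grid, type = "additive")
  bacs <- vapply(grid, function(g) {
    cm <- confusion_matrix(label, classify_remission(score, -0.97, g))
    confusion_metrics(cm)$bac
  }, numeric(1))
  expect_equal(op2$critical, grid[min(which(bacs == max(bacs)))])
  expect_error(select_operating_point(rnorm(5), rep(1, 5), -0.97),
               "both classes")
})

test_that("null-model rates equal prevalence and its complement", {
  nm <- null_model_rates(0.5)
  expect_equal(nm$sen, 0.5); expect_equal(nm$spc, 0.5)
  # Monte-Carlo: independent guessing at q = 0.2
  set.seed(99)
  truth <- rbinom(1e6, 1, 0.3)
  guess <- rbinom(1e6, 1, 0.2)
  m <- confusion_metrics(confusion_matrix(truth, guess))
  expect_equal(m$sen, 0.2, tolerance = 0.002)
  expect_equal(m$spc, 0.8, tolerance = 0.002)
  expect_error(null_model_rates(0), "prevalence")
})

test_that("cross-validated evaluation assembles rms, confusion and ROC", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, seed = 15))
  prior <- build_prior(default_evidence(), parameter_names(14))
  res <- run_crossval(coh, prior, k = 5, seed = 2, strategy = "BU",
                      dimensions = "score_ina")
  ev <- evaluate_crossval(res, "score_ina", threshold = -0.97)
  expect_true(is.finite(ev$rms) && ev$rms > 0)
  expect_equal(ev$confusion$tp + ev$confusion$fn,
               sum(res$y_true <= -0.97))
  expect_gte(ev$roc$auc, 0); expect_lte(ev$roc$auc, 1)
  expect_length(ev$operating_points, 5)
})
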