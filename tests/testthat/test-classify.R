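test_that("the single-feature discriminant reduces to the midpoint threshold", {
  x <- c(-1, 0, 1, 3, 4, 5)
  lab <- rep(c("nondysplastic", "dysplastic"), each = 3)
  fit <- fit_lda_1d(x, lab)
  expect_equal(fit$threshold, 2.0)
  expect_equal(fit$direction, 1)
  expect_identical(predict(fit, c(1.9, 2.1)), c(FALSE, TRUE))
  # zero pooled variance still thresholds at the midpoint of distinct means
  fit0 <- fit_lda_1d(rep(c(0, 4), each = 3), rep(lab[c(1, 4)], each = 3))
  expect_equal(fit0$threshold, 2.0)
  # identical means are degenerate
  expect_error(fit_lda_1d(c(1, 2, 1, 2),
                          rep(c("dysplastic", "nondysplastic"), each = 2)),
               "identical class means")
})

test_that("swapping labels flips the orientation but not the classification rate", {
  set.seed(41)
  x <- c(rnorm(30, 0), rnorm(30, 2))
  lab <- rep(c("nondysplastic", "dysplastic"), each = 30)
  f1 <- fit_lda_1d(x, lab)
  f2 <- fit_lda_1d(x, ifelse(lab == "dysplastic", "nondysplastic",
                             "dysplastic"))
  expect_equal(f2$direction, -f1$direction)
  p1 <- predict(f1, x); p2 <- predict(f2, x)
  expect_identical(p1, !p2)
  expect_equal(mean(p1 == (lab == "dysplastic")),
               mean(p2 == (lab != "dysplastic")))
})

test_that("no-signal features classify near chance", {
  set.seed(42)
  x <- rnorm(400)
  lab <- rep(c("nondysplastic", "dysplastic"), 200)
  fit <- fit_lda_1d(x, lab)
  ccr <- mean(predict(fit, x) == (lab == "dysplastic"))
  expect_gt(ccr, 0.40)
  expect_lt(ccr, 0.60)
})

test_that("the threshold agrees with MASS::lda under equal priors", {
  skip_if_not_installed("MASS")
  set.seed(43)
  x <- c(rnorm(40, 0, 1.3), rnorm(40, 1.5, 1.3))
  lab <- factor(rep(c("nondysplastic", "dysplastic"), each = 40))
  fit <- fit_lda_1d(x, lab)
  m <- MASS::lda(x = data.frame(x = x), grouping = lab,
                 prior = c(0.5, 0.5))
  pm <- predict(m, data.frame(x = x))$class == "dysplastic"
  expect_identical(unname(predict(fit, x)), unname(pm))
})

test_that("select_feature picks the feature with highest training CCR, first on ties", {
  feats <- data.frame(patient_id = sprintf("P%02d", 1:12),
                      f_plus = c(1:6, 1:6 + 0.5) / 10,   # heavy overlap
                      f_minus = c(1:6, 1:6 + 0.5) / 10,  # heavy overlap
                      f_diff = c(rep(0, 6), rep(1, 6)))  # separates
  ct <- data.frame(patient_id = feats$patient_id,
                   label = rep(c("nondysplastic", "dysplastic"), each = 6),
                   split = "train")
  sel <- select_feature(feats, ct)
  expect_identical(sel$feature, "f_diff")
  expect_equal(unname(sel$training_ccr["f_diff"]), 1)
  # exact tie: all three identical -> first candidate wins, with a message
  feats2 <- feats
  feats2$f_plus <- feats$f_diff
  feats2$f_minus <- feats$f_diff
  expect_message(sel2 <- select_feature(feats2, ct), "tie")
  expect_identical(sel2$feature, "f_plus")
})

test_that("evaluate matches the generic Pearson chi-squared on random tables", {
  set.seed(44)
  for (rep in 1:25) {
    cm <- confusion_counts(tn = sample(1:60, 1), fp = sample(1:60, 1),
                           fn = sample(1:60, 1), tp = sample(1:60, 1))
    ev <- evaluate(cm)
    tab <- matrix(c(cm$tn, cm$fn, cm$fp, cm$tp), 2, 2)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ev$pearson_chi2, unname(ref$statistic), tolerance = 1e-9)
  }
  # proportional rows are independent
  expect_equal(evaluate(confusion_counts(10, 10, 20, 20))$pearson_chi2, 0)
})

test_that("evaluate swaps sensitivity and specificity under label/call swap", {
  cm <- confusion_counts(tn = 50, fp = 4, fn = 17, tp = 41)
  sw <- confusion_counts(tn = 41, fp = 17, fn = 4, tp = 50)
  a <- evaluate(cm); b <- evaluate(sw)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$pearson_chi2, b$pearson_chi2)
})

test_that("a zero marginal leaves chi-squared undefined with a reason", {
  ev <- evaluate(confusion_counts(tn = 10, fp = 0, fn = 5, tp = 0))
  expect_true(is.na(ev$pearson_chi2))
  expect_match(ev$chi2_reason, "marginal")
  expect_equal(ev$specificity, 100)
})

test_that("the panel rule is OR with missing ploidy treated as negative", {
  expect_identical(combine_nt_icm(c(TRUE, FALSE, TRUE, FALSE),
                                  c(FALSE, FALSE, TRUE, TRUE)),
                   c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(combine_nt_icm(c(FALSE, TRUE), c(NA, NA)),
                   c(FALSE, TRUE))
  expect_warning(out <- combine_nt_icm(c(NA, TRUE), c(TRUE, FALSE)),
                 "excluded")
  expect_identical(out, c(NA, TRUE))
})

test_that("the OR rule reproduces the combined confusion matrix of the study tables", {
  # 54 non-dysplastic: 4 texture-positive, 0 aneuploid (2 ploidy calls
  # missing); 58 HGD: 41 texture-positive, 38 aneuploid of 57 measured,
  # overlapping in 35 patients
  truth <- rep(c(FALSE, TRUE), c(54, 58))
  nt <- c(rep(TRUE, 4), rep(FALSE, 50),
          rep(TRUE, 35), rep(TRUE, 6), rep(FALSE, 3), rep(FALSE, 14))
  icm <- c(rep(FALSE, 52), NA, NA,
           rep(TRUE, 35), rep(FALSE, 6), rep(TRUE, 3), rep(FALSE, 13), NA)
  comb <- combine_nt_icm(nt, icm)
  cm <- confusion_matrix(truth, comb)
  expect_equal(cm$tn, 50); expect_equal(cm$fp, 4)
  expect_equal(cm$fn, 14); expect_equal(cm$tp, 44)
  ev <- evaluate(cm)
  expect_equal(round(ev$pearson_chi2, 1), 53.5)
})
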