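# Small helper: build a glem_set with k cases per class, m "nuclei" each,
# using random 4x4 probability matrices in a single area group.
random_prob_matrix <- function(nr = 4, nc = 4) {
  m <- matrix(runif(nr * nc), nr, nc)
  m / sum(m)
}

test_that("two-step averaging weights cases equally, matching a nested-loop oracle", {
  set.seed(21)
  cases <- list(D1 = 5, D2 = 5, D3 = 5, N1 = 5, N2 = 5, N3 = 5)
  info <- list(); glems <- list(); k <- 0L
  for (pid in names(cases)) {
    for (j in seq_len(cases[[pid]])) {
      k <- k + 1L
      info[[k]] <- data.frame(patient_id = pid, nucleus_id = paste0("n", j),
                              area = 1500L, area_group = 1L)
      glems[[k]] <- random_prob_matrix()
    }
  }
  gs <- make_glem_set(do.call(rbind, info), glems)
  ct <- data.frame(patient_id = names(cases),
                   label = rep(c("dysplastic", "nondysplastic"), each = 3),
                   split = "train")
  stats <- fit_class_statistics(gs, ct, area_groups = 1L)

  # nested-loop oracle: per-case mean and population variance, then
  # unweighted mean of the per-case matrices across cases
  oracle <- function(pids) {
    ms <- list(); vs <- list()
    for (pid in pids) {
      sel <- which(gs$info$patient_id == pid)
      arr <- simplify2array(gs$glems[sel])
      ms[[pid]] <- apply(arr, 1:2, mean)
      vs[[pid]] <- apply(arr, 1:2, function(x) mean((x - mean(x))^2))
    }
    list(mean = Reduce(`+`, ms) / length(ms),
         var = Reduce(`+`, vs) / length(vs))
  }
  od <- oracle(c("D1", "D2", "D3")); on <- oracle(c("N1", "N2", "N3"))
  expect_equal(stats$groups[["1"]]$dysplastic$mean, od$mean,
               tolerance = 1e-12)
  expect_equal(stats$groups[["1"]]$dysplastic$var, od$var, tolerance = 1e-12)
  expect_equal(stats$groups[["1"]]$nondysplastic$mean, on$mean,
               tolerance = 1e-12)
  expect_equal(stats$groups[["1"]]$nondysplastic$var, on$var,
               tolerance = 1e-12)
})

test_that("a case with many nuclei does not swamp the class mean", {
  set.seed(22)
  A <- random_prob_matrix(); B <- random_prob_matrix()
  info <- data.frame(
    patient_id = c(rep("D1", 1), rep("D2", 10), "N1", "N2"),
    nucleus_id = "n", area = 1500L, area_group = 1L)
  glems <- c(list(A), rep(list(B), 10), list(A), list(B))
  gs <- make_glem_set(info, glems)
  ct <- data.frame(patient_id = c("D1", "D2", "N1", "N2"),
                   label = c("dysplastic", "dysplastic",
                             "nondysplastic", "nondysplastic"),
                   split = "train")
  stats <- fit_class_statistics(gs, ct, area_groups = 1L)
  # step-2 mean is (A + B)/2, not the nucleus-pooled (A + 10 B)/11
  expect_equal(stats$groups[["1"]]$dysplastic$mean, (A + B) / 2,
               tolerance = 1e-12)
  # a class with no training cases errors
  expect_error(
    fit_class_statistics(gs, transform(ct, label = "dysplastic"),
                         area_groups = 1L),
    "nondysplastic")
})

test_that("discriminant matrices follow the squared Mahalanobis formula", {
  mk_stats <- function(m1, v1, m2, v2) {
    structure(list(groups = list("1" = list(
      dysplastic = list(mean = m1, var = v1, n_cases = 3),
      nondysplastic = list(mean = m2, var = v2, n_cases = 3))),
      area_groups = 1L, classes = c("dysplastic", "nondysplastic")),
      class = "class_stats")
  }
  one <- matrix(1, 2, 2)
  st <- mk_stats(0.4 * one, 0.01 * one, 0.2 * one, 0.03 * one)
  d <- derive_discriminants(st, epsilon = 1e-12)
  expect_equal(d$groups[["1"]]$delta, 0.2 * one, tolerance = 1e-12)
  expect_equal(d$groups[["1"]]$d2, 2.0 * one, tolerance = 1e-9)
  # identical means: both matrices vanish
  st0 <- mk_stats(0.4 * one, 0.01 * one, 0.4 * one, 0.03 * one)
  d0 <- derive_discriminants(st0)
  expect_equal(d0$groups[["1"]]$delta, 0 * one)
  expect_equal(d0$groups[["1"]]$d2, 0 * one)
  # swapping the classes negates delta and leaves d2 unchanged
  sw <- mk_stats(0.2 * one, 0.03 * one, 0.4 * one, 0.01 * one)
  dsw <- derive_discriminants(sw, epsilon = 1e-12)
  expect_equal(dsw$groups[["1"]]$delta, -d$groups[["1"]]$delta)
  expect_equal(dsw$groups[["1"]]$d2, d$groups[["1"]]$d2)
  # zero variance with nonzero difference is controlled by epsilon
  stz <- mk_stats(0.4 * one, 0 * one, 0.2 * one, 0 * one)
  dz <- derive_discriminants(stz, epsilon = 1e-8)
  expect_equal(dz$groups[["1"]]$d2, 0.2^2 / 1e-8 * one)
})

test_that("nucleus features sum the weighted partitions of the GLEM", {
  P <- rbind(c(0.5, 0.1), c(0.2, 0.2))
  delta <- rbind(c(1, -1), c(1, -1))
  d2 <- rbind(c(1, 2), c(3, 4))
  disc <- make_disc(list("2" = list(delta = delta, d2 = d2)))
  f <- nucleus_features(P, disc, area_group = 2)
  expect_equal(f[["f_plus"]], 0.5 * 1 + 0.2 * 3)   # = 1.1
  expect_equal(f[["f_minus"]], 0.1 * 2 + 0.2 * 4)  # = 1.0
  # all-positive partition leaves f_minus empty; constant d2 gives f_plus = c
  disc2 <- make_disc(list("2" = list(delta = matrix(1, 2, 2),
                                     d2 = matrix(7, 2, 2))))
  f2 <- nucleus_features(P, disc2, 2)
  expect_equal(f2[["f_minus"]], 0)
  expect_equal(f2[["f_plus"]], 7)  # GLEM sums to 1
  # elements with delta = 0 contribute to neither partition
  disc3 <- make_disc(list("2" = list(delta = rbind(c(0, 1), c(-1, 0)),
                                     d2 = matrix(1, 2, 2))))
  f3 <- nucleus_features(P, disc3, 2)
  expect_equal(f3[["f_plus"]], 0.1)
  expect_equal(f3[["f_minus"]], 0.2)
  # missing area group flags the nucleus unusable
  expect_null(nucleus_features(P, disc, area_group = 5))
})

test_that("patient features average eligible nuclei and flag unscorable patients", {
  # weights chosen so f_plus = 2 * (first-row mass): nuclei get 1, 2, 6
  disc_v <- make_disc(list("1" = list(delta = rbind(c(1, 1), c(-1, -1)),
                                      d2 = rbind(c(2, 2), c(0, 0)))))
  info <- data.frame(patient_id = "P1", nucleus_id = c("a", "b", "c"),
                     area = 1500L, area_group = 1L)
  gs <- make_glem_set(info, list(rbind(c(0.5, 0), c(0.5, 0)),
                                 rbind(c(1, 0), c(0, 0)),
                                 rbind(c(3, 0), c(-2, 0))))
  pf <- patient_features(gs, disc_v, area_groups = 1:5)
  expect_equal(pf$f_plus, mean(c(2 * 0.5, 2 * 1, 2 * 3)))  # = 3
  expect_equal(pf$f_diff, pf$f_plus - pf$f_minus)
  expect_equal(pf$n_nuclei_used, 3L)
  # nuclei outside A1-A5 are excluded; a patient with none is unscorable
  info0 <- data.frame(patient_id = "P2", nucleus_id = c("a", "b"),
                      area = c(500L, 12000L), area_group = c(0L, 10L))
  gs0 <- make_glem_set(info0, list(rbind(c(1, 0), c(0, 0)),
                                   rbind(c(1, 0), c(0, 0))))
  expect_warning(pf0 <- patient_features(gs0, disc_v), "unscorable")
  expect_true(is.na(pf0$f_plus))
  expect_identical(pf0$n_nuclei_used, 0L)
})

test_that("scaling every d2 by k scales the features by k and leaves CCR unchanged", {
  set.seed(23)
  delta <- matrix(rnorm(16), 4, 4)
  d2 <- matrix(rexp(16), 4, 4)
  disc1 <- make_disc(list("1" = list(delta = delta, d2 = d2)))
  disck <- make_disc(list("1" = list(delta = delta, d2 = 5 * d2)))
  info <- data.frame(patient_id = sprintf("P%02d", 1:12), nucleus_id = "n",
                     area = 1500L, area_group = 1L)
  glems <- replicate(12, random_prob_matrix(), simplify = FALSE)
  gs <- make_glem_set(info, glems)
  f1 <- patient_features(gs, disc1)
  fk <- patient_features(gs, disck)
  expect_equal(fk$f_plus, 5 * f1$f_plus, tolerance = 1e-12)
  expect_equal(fk$f_minus, 5 * f1$f_minus, tolerance = 1e-12)
  labels <- rep(c("dysplastic", "nondysplastic"), 6)
  fit1 <- fit_lda_1d(f1$f_diff, labels)
  fitk <- fit_lda_1d(fk$f_diff, labels)
  expect_identical(predict(fit1, f1$f_diff), predict(fitk, fk$f_diff))
})

test_that("fitted models survive a JSON round trip", {
  set.seed(24)
  disc <- make_disc(list("1" = list(delta = matrix(rnorm(9), 3, 3),
                                    d2 = matrix(rexp(9), 3, 3)),
                         "3" = list(delta = matrix(rnorm(9), 3, 3),
                                    d2 = matrix(rexp(9), 3, 3))))
  lda <- fit_lda_1d(c(1, 2, 3, 10, 11, 12),
                    rep(c("nondysplastic", "dysplastic"), each = 3))
  model <- list(params = glem_params(), disc = disc, selected = "f_diff",
                lda = lda)
  path <- withr::local_tempfile(fileext = ".json")
  write_nt_model(model, path)
  back <- read_nt_model(path)
  expect_equal(back$disc$groups[["3"]]$d2, disc$groups[["3"]]$d2,
               tolerance = 1e-12)
  expect_equal(back$selected, "f_diff")
  expect_equal(back$lda$threshold, lda$threshold)
  expect_identical(predict(back$lda, c(0, 5, 9, 20)),
                   predict(lda, c(0, 5, 9, 20)))
  expect_equal(back$params$window, 9L)
})
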