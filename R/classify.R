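#' Two-class linear discriminant on a single feature
#'
#' With a shared (pooled) variance, the two-class linear discriminant on one
#' feature reduces to a threshold
#' `t = (m1 + m0)/2 + s2 * log(pi0/pi1) / (m1 - m0)`
#' where `m1`, `m0` are the class means, `s2` the pooled variance and
#' `pi1`, `pi0` the priors (equal by default, so the prior term vanishes
#' and `t` is the midpoint of the means). A case is called positive when its
#' feature lies strictly on the positive-class side of the threshold. If the
#' pooled variance is zero the threshold falls back to the midpoint of the
#' (distinct) means; identical class means are a non-separable degenerate
#' input and an error.
#'
#' @param x Numeric feature values.
#' @param labels Class labels, same length as `x`.
#' @param positive Label of the positive (dysplastic) class.
#' @param priors `c(positive, negative)` prior probabilities.
#' @return Object of class `lda1d` with `threshold`, `direction` (+1 when
#'   the positive mean exceeds the negative mean), `means`, `pooled_sd`,
#'   `priors`, `positive`.
#' @export
fit_lda_1d <- function(x, labels, positive = "dysplastic",
                       priors = c(0.5, 0.5)) {
  ok <- is.finite(x) & !is.na(labels)
  x <- x[ok]; labels <- labels[ok]
  pos <- labels == positive
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("need >= 2 cases per class to fit the discriminant")
  }
  m1 <- mean(x[pos]); m0 <- mean(x[!pos])
  if (m1 == m0) stop("identical class means: non-separable degenerate input")
  n1 <- sum(pos); n0 <- sum(!pos)
  s2 <- ((n1 - 1) * var(x[pos]) + (n0 - 1) * var(x[!pos])) / (n1 + n0 - 2)
  t <- (m1 + m0) / 2
  if (s2 > 0 && priors[1] != priors[2]) {
    t <- t + s2 * log(priors[2] / priors[1]) / (m1 - m0)
  }
  structure(list(threshold = t, direction = if (m1 > m0) 1 else -1,
                 means = c(positive = m1, negative = m0),
                 pooled_sd = sqrt(s2), priors = priors, positive = positive),
            class = "lda1d")
}

#' @param object An `lda1d` fit.
#' @param newdata Numeric feature values to classify.
#' @param ... Unused.
#' @return Logical vector: `TRUE` = positive (dysplastic) call.
#' @rdname fit_lda_1d
#' @export
predict.lda1d <- function(object, newdata, ...) {
  object$direction * (newdata - object$threshold) > 0
}

#' Select the best single adaptive feature by training CCR
#'
#' Fits the discriminant separately to each candidate feature on the
#' training cases, computes each training correct classification rate and
#' returns the feature with the highest one. Exact ties are broken by the
#' fixed candidate order (first wins) and reported via a message.
#'
#' @param features Data.frame from [patient_features()].
#' @param case_table Case table; only `split == "train"` rows are used for
#'   fitting.
#' @param candidates Feature columns to compare, in tie-break order.
#' @param priors Passed to [fit_lda_1d()].
#' @return List with `feature` (chosen name), `fit` (the `lda1d`), and
#'   `training_ccr` (named vector over all candidates, fractions in
#'   `[0, 1]`).
#' @export
select_feature <- function(features, case_table,
                           candidates = c("f_plus", "f_minus", "f_diff"),
                           priors = c(0.5, 0.5)) {
  validate_case_table(case_table)
  tab <- merge(features, case_table, by = "patient_id")
  tab <- tab[tab$split == "train" & is.finite(tab$f_plus), ]
  ccr <- numeric(length(candidates)); names(ccr) <- candidates
  fits <- vector("list", length(candidates)); names(fits) <- candidates
  for (f in candidates) {
    fits[[f]] <- fit_lda_1d(tab[[f]], tab$label, priors = priors)
    pred <- predict(fits[[f]], tab[[f]])
    ccr[f] <- mean(pred == (tab$label == "dysplastic"))
  }
  best <- candidates[which.max(ccr)]
  if (sum(ccr == max(ccr)) > 1L) {
    message("training CCR tie between ",
            paste(candidates[ccr == max(ccr)], collapse = ", "),
            "; keeping ", best, " by fixed order")
  }
  list(feature = best, fit = fits[[best]], training_ccr = ccr)
}

#' Build a 2x2 confusion matrix
#'
#' Row convention: row 1 = truly non-dysplastic (tn, fp), row 2 = truly
#' dysplastic/HGD (fn, tp); a positive call means test-positive
#' (texture-positive, aneuploid, or combined-positive).
#'
#' @param truth_positive Logical: `TRUE` when the case is truly dysplastic.
#' @param call_positive Logical: `TRUE` when the test calls it positive.
#' @return Object of class `confusion_2x2` with counts `tn`, `fp`, `fn`,
#'   `tp` and total `n`.
#' @export
confusion_matrix <- function(truth_positive, call_positive) {
  ok <- !is.na(truth_positive) & !is.na(call_positive)
  t <- truth_positive[ok]; p <- call_positive[ok]
  structure(list(tn = sum(!t & !p), fp = sum(!t & p),
                 fn = sum(t & !p), tp = sum(t & p), n = sum(ok)),
            class = "confusion_2x2")
}

#' @rdname confusion_matrix
#' @param tn,fp,fn,tp Counts, for building a table directly.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp, n = tn + fp + fn + tp),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(c("no dysplasia", "HGD"), c("0", "1")))
  print(cbind(m, Total = rowSums(m)))
  invisible(x)
}

#' Evaluation statistics of a 2x2 confusion matrix
#'
#' Sensitivity `100*tp/(tp+fn)`, specificity `100*tn/(tn+fp)`, correct
#' classification rate `100*(tp+tn)/n`, and the Pearson chi-squared
#' statistic without continuity correction,
#' `n*(tn*tp - fp*fn)^2 / ((tn+fp)(fn+tp)(tn+fn)(fp+tp))`. Percentages are
#' reported unrounded with integer-rounded companions. A zero marginal
#' leaves chi-squared undefined (`NA` with a reason).
#'
#' @param confusion A [confusion_matrix()] / [confusion_counts()] object.
#' @return Object of class `eval_report`: list with `sensitivity`,
#'   `specificity`, `ccr` (unrounded percentages), `rounded` (integer
#'   versions), `pearson_chi2`, `chi2_reason` (NA unless undefined) and `n`.
#' @export
evaluate <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_2x2"))
  tn <- confusion$tn; fp <- confusion$fp
  fn <- confusion$fn; tp <- confusion$tp
  n <- confusion$n
  if (n == 0) stop("empty confusion matrix")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  ccr <- 100 * (tp + tn) / n
  marg <- c(tn + fp, fn + tp, tn + fn, fp + tp)
  if (any(marg == 0)) {
    chi2 <- NA_real_
    reason <- "zero marginal: chi-squared undefined"
  } else {
    chi2 <- n * (tn * tp - fp * fn)^2 / prod(marg)
    reason <- NA_character_
  }
  structure(list(sensitivity = sens, specificity = spec, ccr = ccr,
                 rounded = c(sensitivity = round(sens), specificity = round(spec),
                             ccr = round(ccr)),
                 pearson_chi2 = chi2, chi2_reason = reason, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  sens %.1f%%  spec %.1f%%  CCR %.1f%%  chi2 %s\n",
    x$n, x$sensitivity, x$specificity, x$ccr,
    if (is.na(x$pearson_chi2)) x$chi2_reason else
      sprintf("%.1f", x$pearson_chi2)))
  invisible(x)
}

#' Combine texture and ploidy calls into a panel score
#'
#' A patient is combined-positive when texture-positive OR aneuploid by
#' image cytometry. A missing ploidy call (e.g. too few nuclei) is treated
#' as ploidy-negative so the patient is retained; a missing texture call
#' excludes the patient with a warning.
#'
#' @param nt_positive Logical vector of texture calls (may contain `NA`).
#' @param icm_positive Logical vector of ploidy calls (`NA` allowed).
#' @return Logical vector of combined calls; `NA` where the texture call
#'   was missing.
#' @export
combine_nt_icm <- function(nt_positive, icm_positive) {
  stopifnot(length(nt_positive) == length(icm_positive))
  icm_positive[is.na(icm_positive)] <- FALSE
  if (anyNA(nt_positive)) {
    warning(sum(is.na(nt_positive)),
            " patient(s) without a texture call excluded from the panel")
  }
  ifelse(is.na(nt_positive), NA, nt_positive | icm_positive)
}
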