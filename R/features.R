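#' Per-class mean and variance GLEMs from the training set
#'
#' Two-step averaging within each area group: (1) for every training case
#' the element-wise mean and population variance of that case's nuclear
#' GLEMs; (2) the unweighted element-wise mean of those per-case matrices
#' across the cases of each class. Step 2 weights every case equally, so a
#' case contributing 1000 nuclei does not swamp one contributing 10 — this
#' is what removes the bias from uneven nucleus counts per class and area
#' interval.
#'
#' Statistics are fitted only for the area groups that feed the patient
#' features (A1-A5 by default); a group with no contributing case in a
#' class is marked absent.
#'
#' @param glem_set A [cohort_glems()] result.
#' @param case_table Case table (see [read_case_table()]); only rows with
#'   `split == "train"` contribute.
#' @param area_groups Integer vector of area groups to fit (default `1:5`).
#' @return Object of class `class_stats`: per area group, per class
#'   (`dysplastic`, `nondysplastic`), matrices `mean` and `var` plus the
#'   number of contributing cases.
#' @export
fit_class_statistics <- function(glem_set, case_table, area_groups = 1:5) {
  stopifnot(inherits(glem_set, "glem_set"))
  validate_case_table(case_table)
  train <- case_table[case_table$split == "train", ]
  classes <- c("dysplastic", "nondysplastic")
  for (cl in classes) {
    if (sum(train$label == cl) == 0L) {
      stop("no training cases with label '", cl, "'")
    }
  }
  info <- glem_set$info
  lab <- train$label[match(info$patient_id, train$patient_id)]
  out <- list()
  for (a in area_groups) {
    per_class <- list()
    for (cl in classes) {
      idx <- which(!is.na(lab) & lab == cl & info$area_group == a)
      if (length(idx) == 0L) { per_class[[cl]] <- NULL; next }
      case_means <- list(); case_vars <- list()
      for (pid in unique(info$patient_id[idx])) {
        sub <- idx[info$patient_id[idx] == pid]
        s <- Reduce(`+`, glem_set$glems[sub])
        s2 <- Reduce(`+`, lapply(glem_set$glems[sub], function(m) m * m))
        n <- length(sub)
        m <- s / n
        case_means[[pid]] <- m
        case_vars[[pid]] <- s2 / n - m * m  # population variance
      }
      per_class[[cl]] <- list(
        mean = Reduce(`+`, case_means) / length(case_means),
        var = pmax(Reduce(`+`, case_vars) / length(case_vars), 0),
        n_cases = length(case_means)
      )
    }
    out[[as.character(a)]] <- per_class
  }
  structure(list(groups = out, area_groups = area_groups, classes = classes),
            class = "class_stats")
}

#' Class difference and squared Mahalanobis distance matrices
#'
#' For each fitted area group: the difference matrix
#' `Delta = mean(dysplastic) - mean(nondysplastic)` and the squared
#' elemental Mahalanobis distance
#' `d2 = Delta^2 / ((var_dys + var_non)/2 + epsilon)`. The dysplastic class
#' is fixed as class 1, so the sign of `Delta` (and hence which partition a
#' matrix element belongs to) is deterministic. `epsilon` regularises
#' elements whose class variances are both zero: with `Delta = 0` they get
#' `d2 = 0`, with `Delta != 0` they get `Delta^2 / epsilon`.
#'
#' @param stats A [fit_class_statistics()] result.
#' @param epsilon Variance regulariser (default `1e-8`).
#' @return Object of class `nt_discriminants`: per present area group,
#'   matrices `delta` and `d2`.
#' @export
derive_discriminants <- function(stats, epsilon = 1e-8) {
  stopifnot(inherits(stats, "class_stats"), epsilon > 0)
  groups <- list()
  for (a in names(stats$groups)) {
    g <- stats$groups[[a]]
    if (is.null(g$dysplastic) || is.null(g$nondysplastic)) next
    delta <- g$dysplastic$mean - g$nondysplastic$mean
    d2 <- delta^2 / ((g$dysplastic$var + g$nondysplastic$var) / 2 + epsilon)
    groups[[a]] <- list(delta = delta, d2 = d2)
  }
  if (length(groups) == 0L) stop("no area group has both classes present")
  structure(list(groups = groups, epsilon = epsilon),
            class = "nt_discriminants")
}

#' Adaptive texture features of one nucleus
#'
#' Weighted sums of the nucleus's GLEM with the squared elemental
#' Mahalanobis distance as weight, taken separately over the positive and
#' negative partitions of the class difference matrix:
#' `f_plus = sum over Delta > 0 of d2 * P` and
#' `f_minus = sum over Delta < 0 of d2 * P`. Elements with `Delta = 0`
#' contribute to neither.
#'
#' @param P GLEM probability matrix of the nucleus (or a `glem` object).
#' @param disc A [derive_discriminants()] result.
#' @param area_group The nucleus's area group.
#' @return Named vector `c(f_plus =, f_minus =)`, or `NULL` when no
#'   discriminant matrices exist for that area group (nucleus unusable).
#' @export
nucleus_features <- function(P, disc, area_group) {
  stopifnot(inherits(disc, "nt_discriminants"))
  if (inherits(P, "glem")) P <- P$P
  g <- disc$groups[[as.character(area_group)]]
  if (is.null(g)) return(NULL)
  c(f_plus = sum(g$d2[g$delta > 0] * P[g$delta > 0]),
    f_minus = sum(g$d2[g$delta < 0] * P[g$delta < 0]))
}

#' Per-patient adaptive features
#'
#' Unweighted means of the per-nucleus features over all usable nuclei in
#' area groups A1-A5 (nuclei in A0 and A6-A10 are excluded), plus the
#' difference feature `f_diff = f_plus - f_minus`. A patient with no
#' eligible nucleus is flagged unscorable (`NA` features) with a warning
#' and excluded from downstream evaluation.
#'
#' @param glem_set A [cohort_glems()] result covering the patients to score.
#' @param disc A [derive_discriminants()] result.
#' @param area_groups Area groups aggregated into the patient mean
#'   (default `1:5`).
#' @return Data.frame with columns `patient_id`, `f_plus`, `f_minus`,
#'   `f_diff`, `n_nuclei_used`.
#' @export
patient_features <- function(glem_set, disc, area_groups = 1:5) {
  stopifnot(inherits(glem_set, "glem_set"))
  info <- glem_set$info
  pids <- unique(info$patient_id)
  res <- data.frame(patient_id = pids, f_plus = NA_real_, f_minus = NA_real_,
                    f_diff = NA_real_, n_nuclei_used = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pids)) {
    idx <- which(info$patient_id == pids[i] & info$area_group %in% area_groups)
    fp <- 0; fm <- 0; used <- 0L
    for (k in idx) {
      f <- nucleus_features(glem_set$glems[[k]], disc, info$area_group[k])
      if (is.null(f)) next
      fp <- fp + f[["f_plus"]]; fm <- fm + f[["f_minus"]]; used <- used + 1L
    }
    if (used > 0L) {
      res$f_plus[i] <- fp / used
      res$f_minus[i] <- fm / used
      res$f_diff[i] <- fp / used - fm / used
      res$n_nuclei_used[i] <- used
    } else {
      warning("patient ", pids[i],
              " has no usable nucleus in area groups A1-A5; unscorable")
    }
  }
  res
}

# ---- model serialisation ---------------------------------------------------

#' Save or load a fitted nucleotyping model
#'
#' The fitted model (GLEM parameters, per-area-group difference and weight
#' matrices, selected feature and its discriminant threshold) is serialised
#' as versioned JSON so a trained classifier can be re-applied later.
#'
#' @param model List as assembled by [run_pipeline()] (fields `params`,
#'   `disc`, `selected`, `lda`).
#' @param path File path.
#' @export
write_nt_model <- function(model, path) {
  ser <- list(
    schema = "nucleotyping-model/1",
    glem_params = unclass(model$params),
    epsilon = model$disc$epsilon,
    area_groups = names(model$disc$groups),
    delta = lapply(model$disc$groups, function(g) g$delta),
    d2 = lapply(model$disc$groups, function(g) g$d2),
    selected_feature = model$selected,
    lda = model$lda[c("threshold", "direction", "means", "pooled_sd",
                      "priors")]
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nt_model
#' @export
read_nt_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$schema, "nucleotyping-model/1")) {
    stop("unrecognised model schema: ", ser$schema)
  }
  groups <- list()
  for (a in ser$area_groups) {
    groups[[a]] <- list(delta = ser$delta[[a]], d2 = ser$d2[[a]])
  }
  lda <- ser$lda
  class(lda) <- "lda1d"
  list(params = do.call(glem_params, as.list(ser$glem_params)),
       disc = structure(list(groups = groups, epsilon = ser$epsilon),
                        class = "nt_discriminants"),
       selected = ser$selected_feature, lda = lda)
}
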