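#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: where the galleries
#' and case table live, GLEM parameters, the Mahalanobis regulariser, the
#' ploidy rules, LDA priors and the panel combination rule.
#'
#' @param gallery_dir Directory of per-patient galleries (as written by
#'   [generate_cohort()]).
#' @param case_table_path Cohort case table CSV (defaults to
#'   `case_table.csv` inside `gallery_dir`).
#' @param out_dir Output directory for reports.
#' @param glem A [glem_params()].
#' @param grey_depth Grey depth of the stored images.
#' @param background_intensity Background glass grey level used for
#'   densitometry.
#' @param epsilon Mahalanobis variance regulariser.
#' @param area_groups Area groups used for fitting and patient aggregation.
#' @param ploidy A [ploidy_rules()].
#' @param min_nuclei_ploidy Minimum nuclei for a ploidy call; patients
#'   below it get a missing ploidy call (treated as negative in the panel).
#' @param priors LDA priors `c(dysplastic, nondysplastic)`.
#' @param combine Panel rule; only `"or"` is implemented.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic given the inputs).
#' @export
pipeline_config <- function(gallery_dir, case_table_path = file.path(
                              gallery_dir, "case_table.csv"),
                            out_dir = tempfile("ntpipe"),
                            glem = glem_params(), grey_depth = 1024L,
                            background_intensity = 1000L, epsilon = 1e-8,
                            area_groups = 1:5, ploidy = ploidy_rules(),
                            min_nuclei_ploidy = 100L,
                            priors = c(0.5, 0.5), combine = "or",
                            seed = 1L) {
  stopifnot(combine == "or")
  structure(list(gallery_dir = gallery_dir,
                 case_table_path = case_table_path, out_dir = out_dir,
                 glem = glem, grey_depth = grey_depth,
                 background_intensity = background_intensity,
                 epsilon = epsilon, area_groups = area_groups,
                 ploidy = ploidy, min_nuclei_ploidy = min_nuclei_ploidy,
                 priors = priors, combine = combine, seed = seed),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Analyse an in-memory cohort
#'
#' The computational core of [run_pipeline()], usable without any file I/O:
#' computes GLEMs and IODs, fits the class statistics and discriminant
#' matrices on the training patients, extracts patient features, selects
#' the best single feature by training CCR, scores ploidy per patient, and
#' evaluates texture, ploidy and combined calls against the labels.
#'
#' @param cohort An `nt_cohort` ([generate_cohort()] / [load_cohort()]).
#' @param config A [pipeline_config()] (paths ignored).
#' @return List with `features`, `selection`, `model`, `ploidy`
#'   (data.frame), `calls` (per-patient calls), `reports` (eval_report for
#'   `nt`, `icm`, `combined` over all scorable patients), `ccr`
#'   (training/test CCR of the selected feature, percentages).
#' @export
analyse_cohort <- function(cohort, config = pipeline_config(NA)) {
  case_table <- cohort$case_table
  glems <- .stage("glem", cohort_glems(cohort$nuclei, config$glem,
                                       from_levels = config$grey_depth))
  stats <- .stage("fit", fit_class_statistics(glems, case_table,
                                              config$area_groups))
  disc <- .stage("fit", derive_discriminants(stats, config$epsilon))
  feats <- .stage("features", patient_features(glems, disc,
                                               config$area_groups))
  sel <- .stage("train", select_feature(feats, case_table,
                                        priors = config$priors))

  tab <- merge(feats, case_table, by = "patient_id")
  tab$nt_positive <- NA
  ok <- is.finite(tab[[sel$feature]])
  tab$nt_positive[ok] <- predict(sel$fit, tab[[sel$feature]][ok])

  ploidy_rows <- list()
  for (pid in case_table$patient_id) {
    iods <- vapply(cohort$nuclei[[pid]], integrated_optical_density,
                   numeric(1), background_intensity =
                     config$background_intensity)
    if (length(iods) >= config$min_nuclei_ploidy) {
      ps <- .stage("ploidy",
                   ploidy_summary(iods, pid, config$ploidy,
                                  min_nuclei = config$min_nuclei_ploidy))
      ploidy_rows[[pid]] <- data.frame(
        patient_id = pid, dna_index = ps$dna_index, fivec_er = ps$fivec_er,
        ninec_er = ps$ninec_er, call = ps$call, stringsAsFactors = FALSE)
    } else {
      ploidy_rows[[pid]] <- data.frame(
        patient_id = pid, dna_index = NA_real_, fivec_er = NA_real_,
        ninec_er = NA_real_, call = NA_character_, stringsAsFactors = FALSE)
    }
  }
  ploidy <- do.call(rbind, c(ploidy_rows, make.row.names = FALSE))

  tab <- merge(tab, ploidy, by = "patient_id")
  tab$icm_positive <- tab$call == "aneuploid"
  tab$combined_positive <- combine_nt_icm(tab$nt_positive, tab$icm_positive)
  truth <- tab$label == "dysplastic"

  reports <- list(
    nt = evaluate(confusion_matrix(truth, tab$nt_positive)),
    icm = evaluate(confusion_matrix(truth[!is.na(tab$icm_positive)],
                                    tab$icm_positive[!is.na(tab$icm_positive)])),
    combined = evaluate(confusion_matrix(truth, tab$combined_positive))
  )
  ccr_split <- function(s) {
    i <- tab$split == s & !is.na(tab$nt_positive)
    100 * mean(tab$nt_positive[i] == truth[i])
  }
  list(features = feats, selection = sel,
       model = list(params = config$glem, disc = disc,
                    selected = sel$feature, lda = sel$fit),
       ploidy = ploidy, calls = tab, reports = reports,
       ccr = c(train = ccr_split("train"), test = ccr_split("test")))
}

#' Run the full pipeline from disk to report files
#'
#' Loads the galleries and case table, runs [analyse_cohort()], and writes:
#' the fitted model (`model.json`), patient features (`features.csv`),
#' ploidy results (`ploidy.csv`) and DNA histograms (`histograms.csv`),
#' per-patient calls (`calls.csv`), evaluation reports (`evaluation.csv`),
#' a Table-2-style text summary (`summary.txt`), and a `manifest.json`
#' recording the configuration hash, package version and every declared
#' output. Reruns on identical inputs are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the [analyse_cohort()] result plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  case_table <- .stage("load", read_case_table(config$case_table_path))
  cohort <- .stage("load", {
    nuclei <- list()
    for (pid in case_table$patient_id) {
      nuclei[[pid]] <- load_gallery(file.path(config$gallery_dir, pid),
                                    patient_id = pid,
                                    grey_depth = config$grey_depth)
    }
    structure(list(case_table = case_table, nuclei = nuclei),
              class = "nt_cohort")
  })
  res <- analyse_cohort(cohort, config)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out, name)
    writer(path)
    outputs <<- c(outputs, name)
  }
  emit("model.json", function(p) write_nt_model(res$model, p))
  emit("features.csv", function(p) write.csv(res$features, p,
                                             row.names = FALSE))
  emit("ploidy.csv", function(p) write.csv(res$ploidy, p, row.names = FALSE))
  emit("histograms.csv", function(p) {
    rows <- list()
    for (pid in case_table$patient_id) {
      iods <- vapply(cohort$nuclei[[pid]], integrated_optical_density,
                     numeric(1), background_intensity =
                       config$background_intensity)
      if (length(iods) < config$min_nuclei_ploidy) next
      h <- ploidy_histogram(
        ploidy_summary(iods, pid, config$ploidy,
                       min_nuclei = config$min_nuclei_ploidy))
      rows[[pid]] <- cbind(patient_id = pid, h)
    }
    write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), p,
              row.names = FALSE)
  })
  emit("calls.csv", function(p) {
    cols <- c("patient_id", "label", "split", "f_plus", "f_minus", "f_diff",
              "nt_positive", "icm_positive", "combined_positive")
    write.csv(res$calls[, cols], p, row.names = FALSE)
  })
  emit("evaluation.csv", function(p) {
    rows <- do.call(rbind, lapply(names(res$reports), function(m) {
      r <- res$reports[[m]]
      data.frame(method = m, n = r$n, sensitivity = r$sensitivity,
                 specificity = r$specificity, ccr = r$ccr,
                 pearson_chi2 = r$pearson_chi2)
    }))
    write.csv(rows, p, row.names = FALSE)
  })
  emit("summary.txt", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    fmt_cm <- function(v) {
      cm <- confusion_matrix(v$truth, v$call)
      sprintf("  no dysplasia %4d %4d %5d\n  HGD          %4d %4d %5d\n",
              cm$tn, cm$fp, cm$tn + cm$fp, cm$fn, cm$tp, cm$fn + cm$tp)
    }
    truth <- res$calls$label == "dysplastic"
    for (m in names(res$reports)) {
      r <- res$reports[[m]]
      call <- switch(m, nt = res$calls$nt_positive,
                     icm = res$calls$icm_positive,
                     combined = res$calls$combined_positive)
      keep <- !is.na(call)
      writeLines(sprintf(
        "%s: chi2=%.1f sens=%.0f%% spec=%.0f%% CCR=%.0f%% (n=%d)", m,
        r$pearson_chi2, r$sensitivity, r$specificity, r$ccr, r$n), con)
      writeLines(sprintf("               0    1 Total"), con)
      writeLines(fmt_cm(list(truth = truth[keep], call = call[keep])), con)
    }
    writeLines(sprintf("selected feature: %s (training CCR %.0f%%, test CCR %.0f%%)",
                       res$selection$feature, res$ccr["train"],
                       res$ccr["test"]), con)
  })
  emit("config.json", function(p) {
    jsonlite::write_json(rapply(unclass(config), identity, how = "replace"),
                         p, auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  manifest <- list(
    package = "nucleotyping",
    version = as.character(utils::packageVersion("nucleotyping")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(file.path(out, "config.json"))),
    outputs = c(outputs, "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(out_dir = out)))
}
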