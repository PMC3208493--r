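#' Texture parameters of the simulated chromatin field
#'
#' The chromatin of a synthetic nucleus is a Gaussian random field: white
#' noise convolved with a Gaussian kernel of standard deviation
#' `correlation_length` (pixels), affinely mapped to the target mean
#' intensity and a grey-level standard deviation of `contrast`. Short
#' correlation lengths give fine-grained, locally heterogeneous chromatin
#' (high local entropy); long ones give coarse, locally homogeneous
#' chromatin (low local entropy).
#'
#' @param correlation_length Gaussian kernel sd in pixels.
#' @param contrast Grey-level standard deviation of the field.
#' @export
texture_params <- function(correlation_length, contrast) {
  stopifnot(correlation_length >= 0, contrast >= 0)
  list(correlation_length = correlation_length, contrast = contrast)
}

#' A DNA-content population profile
#'
#' Describes the DNA histogram one patient is drawn from: Gaussian G0/G1
#' components at given modal DNA contents (c units) with mixing fractions
#' and coefficients of variation, an S-phase fraction filled uniformly
#' between 2c and 4c, and a tail fraction spread uniformly over 5c-10c.
#'
#' @param components Data.frame with columns `c` (modal DNA content, c
#'   units, > 0), `fraction` (mixing fractions summing to 1 with the
#'   s-phase and tail fractions excluded), `cv` (coefficient of variation).
#' @param s_phase_fraction Fraction of nuclei in the uniform 2c-4c fill.
#' @param tail_fraction Fraction of nuclei uniform on 5c-10c.
#' @export
ploidy_profile <- function(components, s_phase_fraction = 0.05,
                           tail_fraction = 0) {
  stopifnot(is.data.frame(components),
            all(c("c", "fraction", "cv") %in% names(components)),
            all(components$c > 0),
            abs(sum(components$fraction) - 1) < 1e-9,
            s_phase_fraction >= 0, tail_fraction >= 0,
            s_phase_fraction + tail_fraction < 1)
  list(components = components, s_phase_fraction = s_phase_fraction,
       tail_fraction = tail_fraction)
}

#' Configuration of a synthetic cohort
#'
#' Defines the study conditions a simulated cohort emulates: two patient
#' groups with class-dependent chromatin texture and DNA-content structure.
#' Defaults follow the design of the clinical setting the pipeline targets:
#' 1500 nuclei captured per case, 1024 grey levels, nuclear areas log-normal
#' with median ~3000 px spanning the area groups, a diploid-only
#' non-dysplastic class and a dysplastic class in which 65% of patients
#' carry an aneuploid population with a >5c tail.
#'
#' @param n_patients_per_class Patients per class.
#' @param nuclei_per_patient Nuclei per gallery (default 1500).
#' @param grey_depth Grey levels of the capture system (default 1024).
#' @param background_intensity Grey level of clear glass (default 1000).
#' @param iod_per_c IOD units per c of DNA (arbitrary fixed constant,
#'   default 75).
#' @param area_meanlog,area_sdlog Log-normal parameters of nuclear pixel
#'   area (defaults: median 3000 px, sdlog 0.35).
#' @param texture Named list (`nondysplastic`, `dysplastic`) of
#'   [texture_params()].
#' @param ploidy Named list per class: each a list of profiles, each profile
#'   a list with `weight` (probability that a patient of this class draws
#'   this profile) and `profile` (a [ploidy_profile()]).
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(
    n_patients_per_class = 10L,
    nuclei_per_patient = 1500L,
    grey_depth = 1024L,
    background_intensity = 1000L,
    iod_per_c = 75,
    area_meanlog = log(3000),
    area_sdlog = 0.35,
    texture = list(
      nondysplastic = texture_params(correlation_length = 6, contrast = 110),
      dysplastic = texture_params(correlation_length = 2, contrast = 110)
    ),
    ploidy = list(
      nondysplastic = list(
        list(weight = 1,
             profile = ploidy_profile(
               data.frame(c = 2, fraction = 1, cv = 0.03),
               s_phase_fraction = 0.05, tail_fraction = 0))
      ),
      dysplastic = list(
        list(weight = 0.35,
             profile = ploidy_profile(
               data.frame(c = 2, fraction = 1, cv = 0.03),
               s_phase_fraction = 0.05, tail_fraction = 0)),
        list(weight = 0.65,
             profile = ploidy_profile(
               data.frame(c = c(2, 3.4), fraction = c(0.55, 0.45),
                          cv = c(0.03, 0.03)),
               s_phase_fraction = 0.05, tail_fraction = 0.02))
      )
    ),
    seed = 1L) {
  stopifnot(n_patients_per_class >= 1, nuclei_per_patient >= 1,
            background_intensity < grey_depth, iod_per_c > 0)
  for (cl in c("nondysplastic", "dysplastic")) {
    w <- vapply(ploidy[[cl]], function(p) p$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-9) {
      stop("profile weights for class '", cl, "' must sum to 1")
    }
  }
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 nuclei_per_patient = as.integer(nuclei_per_patient),
                 grey_depth = as.integer(grey_depth),
                 background_intensity = as.integer(background_intensity),
                 iod_per_c = iod_per_c, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, texture = texture, ploidy = ploidy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Separable Gaussian smoothing of a white-noise field via banded kernel
# matrices; cheap at nucleus-canvas sizes.
.gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

.smooth_noise <- function(nr, nc, sigma) {
  W <- matrix(rnorm(nr * nc), nr, nc)
  .gauss_kernel_matrix(nr, sigma) %*% W %*%
    t(.gauss_kernel_matrix(nc, sigma))
}

#' Generate one synthetic Feulgen-like nucleus
#'
#' Draws an axis-aligned elliptical mask of approximately `target_area`
#' pixels (eccentricity uniform on \[0, 0.6\]), superimposes a Gaussian
#' random chromatin field with the requested correlation length and
#' contrast, and rescales the mean transmitted intensity by bisection until
#' the integrated optical density ([integrated_optical_density()]) is
#' within 2% of `target_iod` (0.5% in typical cases). In-mask intensities
#' are integers clipped to `[1, background_intensity - 1]`, i.e. always
#' darker than the background glass.
#'
#' @param target_area Target mask area in pixels (>= 50).
#' @param target_iod Target IOD in optical-density pixel units (> 0).
#' @param texture A [texture_params()].
#' @param grey_depth,background_intensity Capture parameters.
#' @param patient_id,nucleus_id Identifiers.
#' @return A [nucleus_image()].
#' @export
generate_nucleus <- function(target_area, target_iod, texture,
                             grey_depth = 1024L,
                             background_intensity = 1000L,
                             patient_id = NA_character_,
                             nucleus_id = NA_character_) {
  if (target_area < 50) stop("`target_area` must be >= 50 pixels")
  if (target_iod <= 0) stop("`target_iod` must be positive")
  bg <- background_intensity

  ecc <- runif(1, 0, 0.6)
  q <- sqrt(1 - ecc^2)
  a <- sqrt(target_area / (pi * q)); b <- a * q
  make_mask <- function(a, b) {
    nc <- 2L * ceiling(a) + 3L; nr <- 2L * ceiling(b) + 3L
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    y <- (seq_len(nr) - cy) / b; x <- (seq_len(nc) - cx) / a
    outer(y^2, x^2, `+`) <= 1
  }
  mask <- make_mask(a, b)
  if (abs(sum(mask) - target_area) > 0.1 * target_area) {
    s <- sqrt(target_area / sum(mask))  # one discretisation correction
    a <- a * s; b <- b * s
    mask <- make_mask(a, b)
  }
  nr <- nrow(mask); nc <- ncol(mask)

  Z <- if (texture$contrast > 0) {
    z <- .smooth_noise(nr, nc, texture$correlation_length)
    zi <- z[mask]
    if (sd(zi) > 0) (z - mean(zi)) / sd(zi) else z * 0
  } else matrix(0, nr, nc)

  field <- function(mu) {
    pmin(pmax(round(mu + texture$contrast * Z[mask]), 1), bg - 1)
  }
  iod_of <- function(px) sum(log10(bg / px))

  lo <- 1 - 6 * texture$contrast  # dark enough that all pixels clip to 1
  hi <- bg - 1 + 6 * texture$contrast  # bright enough to clip to bg - 1
  iod_lo <- iod_of(field(lo)); iod_hi <- iod_of(field(hi))
  if (target_iod > iod_lo) {
    stop("infeasible `target_iod`: would require intensity <= 0 ",
         sprintf("(max attainable %.2f)", iod_lo))
  }
  if (target_iod < iod_hi) {
    stop("infeasible `target_iod`: below the minimum absorbance ",
         sprintf("%.2f of a nucleus this size", iod_hi))
  }
  best_px <- NULL; best_err <- Inf
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    px <- field(mid)
    iod <- iod_of(px)
    err <- abs(iod - target_iod) / target_iod
    if (err < best_err) { best_err <- err; best_px <- px }
    if (err < 0.005) break
    if (iod > target_iod) lo <- mid else hi <- mid
  }
  pixels <- matrix(bg, nr, nc)
  pixels[mask] <- best_px
  storage.mode(pixels) <- "integer"
  nucleus_image(pixels, mask, patient_id = patient_id,
                nucleus_id = nucleus_id, grey_depth = grey_depth)
}

#' Draw per-nucleus DNA contents (c units) from a population profile
#'
#' @param profile A [ploidy_profile()].
#' @param n Number of nuclei.
#' @return Numeric vector of c-values.
#' @export
sample_c_values <- function(profile, n) {
  k <- nrow(profile$components)
  probs <- c(profile$components$fraction *
               (1 - profile$s_phase_fraction - profile$tail_fraction),
             profile$s_phase_fraction, profile$tail_fraction)
  pick <- sample.int(k + 2L, n, replace = TRUE, prob = probs)
  out <- numeric(n)
  for (i in seq_len(k)) {
    sel <- pick == i
    out[sel] <- rnorm(sum(sel), profile$components$c[i],
                      profile$components$cv[i] * profile$components$c[i])
  }
  out[pick == k + 1L] <- runif(sum(pick == k + 1L), 2, 4)
  out[pick == k + 2L] <- runif(sum(pick == k + 2L), 5, 10)
  pmax(out, 0.2)
}

#' Generate a synthetic two-class cohort
#'
#' Generates per-patient galleries for both classes under a single seed:
#' per patient a ploidy profile is drawn by its class weights, per-nucleus
#' DNA contents and areas are sampled, each nucleus is rendered with
#' [generate_nucleus()], and patients are randomly assigned to training and
#' test sets in a 1:1 ratio within each class. With `out_dir` the galleries
#' (TIFF + manifest CSV) and the cohort case table are written to disk and
#' the same seed yields byte-identical output; without it the cohort is
#' returned in memory.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `nt_cohort`: `case_table`, `nuclei` (named list
#'   by patient of [nucleus_image()] lists; `NULL` entries when written to
#'   disk with `keep_images = FALSE`), `manifest` (per-nucleus truth:
#'   `patient_id`, `nucleus_id`, `area_px`, `c_value`, `target_iod`),
#'   `config`, and `path` when written.
#' @param keep_images Keep images in memory even when writing to disk.
#' @export
generate_cohort <- function(config, out_dir = NULL, keep_images = is.null(out_dir)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- c("nondysplastic", "dysplastic")
  prefix <- c(nondysplastic = "ND", dysplastic = "DY")
  npc <- config$n_patients_per_class

  case_rows <- list(); nuclei <- list(); manifest <- list()
  for (cl in classes) {
    ids <- sprintf("%s%03d", prefix[[cl]], seq_len(npc))
    ord <- sample.int(npc)
    split <- character(npc)
    split[ord[seq_len(ceiling(npc / 2))]] <- "train"
    split[split == ""] <- "test"
    case_rows[[cl]] <- data.frame(patient_id = ids, label = cl,
                                  split = split, stringsAsFactors = FALSE)
    profs <- config$ploidy[[cl]]
    w <- vapply(profs, function(p) p$weight, numeric(1))
    for (i in seq_len(npc)) {
      prof <- profs[[sample.int(length(profs), 1L, prob = w)]]$profile
      cvals <- sample_c_values(prof, config$nuclei_per_patient)
      areas <- pmax(round(rlnorm(config$nuclei_per_patient,
                                 config$area_meanlog, config$area_sdlog)),
                    60)
      iods <- cvals * config$iod_per_c
      pid <- ids[i]
      nuc <- vector("list", config$nuclei_per_patient)
      for (j in seq_len(config$nuclei_per_patient)) {
        nuc[[j]] <- generate_nucleus(
          areas[j], iods[j], config$texture[[cl]],
          grey_depth = config$grey_depth,
          background_intensity = config$background_intensity,
          patient_id = pid, nucleus_id = sprintf("n%04d", j))
      }
      man <- data.frame(
        patient_id = pid,
        nucleus_id = sprintf("n%04d", seq_len(config$nuclei_per_patient)),
        area_px = vapply(nuc, function(n) n$area, integer(1)),
        c_value = cvals, target_iod = iods, stringsAsFactors = FALSE)
      manifest[[pid]] <- man
      if (!is.null(out_dir)) {
        write_gallery(nuc, file.path(out_dir, pid),
                      extra = man[, c("c_value", "target_iod")])
      }
      nuclei[[pid]] <- if (keep_images) nuc else NULL
    }
  }
  case_table <- do.call(rbind, case_rows)
  rownames(case_table) <- NULL
  if (!is.null(out_dir)) {
    write_case_table(case_table, file.path(out_dir, "case_table.csv"))
  }
  structure(list(case_table = case_table, nuclei = nuclei,
                 manifest = do.call(rbind, c(manifest,
                                             make.row.names = FALSE)),
                 config = config,
                 path = if (is.null(out_dir)) NA_character_ else out_dir),
            class = "nt_cohort")
}

#' Load a cohort written by [generate_cohort()] from disk
#'
#' @param path Directory containing per-patient galleries and
#'   `case_table.csv`.
#' @param grey_depth Grey depth of the stored images.
#' @return An `nt_cohort` (without the simulation truth manifest).
#' @export
load_cohort <- function(path, grey_depth = 1024L) {
  case_table <- read_case_table(file.path(path, "case_table.csv"))
  nuclei <- list()
  for (pid in case_table$patient_id) {
    nuclei[[pid]] <- load_gallery(file.path(path, pid), patient_id = pid,
                                  grey_depth = grey_depth)
  }
  structure(list(case_table = case_table, nuclei = nuclei, manifest = NULL,
                 config = NULL, path = path),
            class = "nt_cohort")
}
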