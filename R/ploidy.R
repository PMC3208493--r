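#' Integrated optical density of one nucleus
#'
#' Per-pixel optical density is `log10(background / pixel)`; IOD is its sum
#' over mask-true pixels. Because the Feulgen reaction is stoichiometric for
#' DNA, IOD is proportional to the DNA content of the nucleus. IOD is always
#' computed on the original grey depth, never on re-quantised images, and is
#' invariant to a common exposure scaling of background and pixels (the
#' factor cancels inside the log).
#'
#' @param nucleus A [nucleus_image()] at original grey depth.
#' @param background_intensity Grey level of clear glass.
#' @return IOD in optical-density times pixel units.
#' @export
integrated_optical_density <- function(nucleus, background_intensity) {
  stopifnot(inherits(nucleus, "nucleus_image"), background_intensity > 0)
  px <- as.numeric(nucleus$pixels[nucleus$mask])
  if (any(px <= 0)) {
    warning(sum(px <= 0), " non-positive pixel value(s) clipped to 1")
    px[px <= 0] <- 1
  }
  sum(log10(background_intensity / px))
}

#' Configurable ploidy scoring rules
#'
#' Simplified, configurable interpretation rules for a DNA histogram:
#' the main peak of the kernel-smoothed IOD density is taken as the G0/G1
#' (2c) reference, secondary peaks are expressed as DNA indices relative to
#' it, and the exceeding rates count nuclei above fixed multiples of the 2c
#' scale.
#'
#' @param diploid_window,tetraploid_window DNA-index windows regarded as 2c
#'   and 4c peaks.
#' @param fivec_factor,ninec_factor Multiples of the 2c scale above which a
#'   nucleus counts towards the 5c / 9c exceeding rate.
#' @param fivec_er_limit 5cER (%) above which a case is called aneuploid.
#' @param tetraploid_fraction_limit 4c-peak fraction above which a case is
#'   called tetraploid when no aneuploid criterion fires.
#' @param peak_min_fraction Minimum relative density height for a local
#'   maximum to count as a peak.
#' @export
ploidy_rules <- function(diploid_window = c(0.9, 1.1),
                         tetraploid_window = c(1.9, 2.1),
                         fivec_factor = 2.5, ninec_factor = 4.5,
                         fivec_er_limit = 1,
                         tetraploid_fraction_limit = 10,
                         peak_min_fraction = 0.05) {
  structure(list(diploid_window = diploid_window,
                 tetraploid_window = tetraploid_window,
                 fivec_factor = fivec_factor, ninec_factor = ninec_factor,
                 fivec_er_limit = fivec_er_limit,
                 tetraploid_fraction_limit = tetraploid_fraction_limit,
                 peak_min_fraction = peak_min_fraction),
            class = "ploidy_rules")
}

#' DNA ploidy summary of one patient
#'
#' Builds a kernel-smoothed density of the per-nucleus IODs, takes the
#' global mode as the 2c reference scale (`calibration = "mode"`; an
#' external reference IOD can be supplied instead), locates secondary
#' peaks, and derives the DNA index, the 5c and 9c exceeding rates and a
#' ploidy call:
#' \itemize{
#'   \item aneuploid — a peak with DNA index outside both the diploid and
#'     tetraploid windows, or 5cER above `fivec_er_limit`;
#'   \item tetraploid — the 4c-peak fraction exceeds
#'     `tetraploid_fraction_limit` without any aneuploid criterion;
#'   \item diploid — otherwise.
#' }
#'
#' @param iod_values Numeric vector of per-nucleus IODs (>= `min_nuclei`
#'   values).
#' @param patient_id Identifier carried into the result.
#' @param rules A [ploidy_rules()].
#' @param min_nuclei Minimum number of nuclei for a meaningful histogram
#'   (default 100).
#' @param calibration `"mode"` (default) or `"reference"`.
#' @param reference_2c IOD of the 2c reference when
#'   `calibration = "reference"`.
#' @return Object of class `ploidy_result` with fields `patient_id`,
#'   `iod_values`, `c_scale` (IOD at 2c), `dna_index`, `fivec_er`,
#'   `ninec_er`, `call`, `peaks` (data.frame of peak DNA index and relative
#'   height).
#' @export
ploidy_summary <- function(iod_values, patient_id = NA_character_,
                           rules = ploidy_rules(),
                           calibration = c("mode", "reference"),
                           reference_2c = NULL, min_nuclei = 100L) {
  calibration <- match.arg(calibration)
  iod_values <- iod_values[is.finite(iod_values)]
  if (length(iod_values) < min_nuclei) {
    stop("ploidy histogram needs >= ", min_nuclei, " nuclei, got ",
         length(iod_values))
  }
  dens <- density(iod_values, n = 1024)
  loc_max <- which(diff(sign(diff(dens$y))) == -2) + 1L
  if (length(loc_max) == 0L) stop("no detectable peak in the IOD histogram")
  loc_max <- loc_max[dens$y[loc_max] >=
                       rules$peak_min_fraction * max(dens$y)]
  if (length(loc_max) == 0L) stop("no detectable peak in the IOD histogram")
  if (calibration == "mode") {
    c_scale <- dens$x[loc_max[which.max(dens$y[loc_max])]]
  } else {
    if (is.null(reference_2c) || reference_2c <= 0) {
      stop("`reference_2c` must be a positive IOD")
    }
    c_scale <- reference_2c
  }
  peaks <- data.frame(dna_index = dens$x[loc_max] / c_scale,
                      rel_height = dens$y[loc_max] / max(dens$y))
  peaks <- peaks[peaks$dna_index > 0.3, , drop = FALSE]  # ignore debris

  in_win <- function(x, w) x >= w[1] & x <= w[2]
  off_peaks <- peaks[!in_win(peaks$dna_index, rules$diploid_window) &
                       !in_win(peaks$dna_index, rules$tetraploid_window), ,
                     drop = FALSE]
  dna_index <- if (nrow(off_peaks) > 0) {
    off_peaks$dna_index[which.max(off_peaks$rel_height)]
  } else 1.0

  fivec_er <- 100 * mean(iod_values > rules$fivec_factor * c_scale)
  ninec_er <- 100 * mean(iod_values > rules$ninec_factor * c_scale)
  di <- iod_values / c_scale
  tetra_fraction <- 100 * mean(in_win(di, rules$tetraploid_window))

  call <- if (nrow(off_peaks) > 0 || fivec_er > rules$fivec_er_limit) {
    "aneuploid"
  } else if (tetra_fraction > rules$tetraploid_fraction_limit) {
    "tetraploid"
  } else "diploid"

  structure(list(patient_id = patient_id, iod_values = iod_values,
                 c_scale = c_scale, dna_index = dna_index,
                 fivec_er = fivec_er, ninec_er = ninec_er, call = call,
                 peaks = peaks),
            class = "ploidy_result")
}

#' @export
print.ploidy_result <- function(x, ...) {
  cat(sprintf(
    "<ploidy_result> %s: DI %.2f, 5cER %.2f%%, 9cER %.2f%%, call %s (n=%d)\n",
    x$patient_id, x$dna_index, x$fivec_er, x$ninec_er, x$call,
    length(x$iod_values)))
  invisible(x)
}

#' DNA histogram of a ploidy result in c units
#'
#' @param result A [ploidy_summary()] result.
#' @param binwidth Bin width in c units (default 0.1).
#' @return Data.frame with columns `bin_center_c` and `count`.
#' @export
ploidy_histogram <- function(result, binwidth = 0.1) {
  stopifnot(inherits(result, "ploidy_result"))
  cvals <- 2 * result$iod_values / result$c_scale
  breaks <- seq(0, ceiling(max(cvals) / binwidth) * binwidth + binwidth,
                by = binwidth)
  h <- hist(cvals, breaks = breaks, plot = FALSE)
  data.frame(bin_center_c = h$mids, count = h$counts)
}
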