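#' Parameters of the grey level entropy matrix
#'
#' The GLEM element `P(i, j | w)` estimates the probability that a pixel of
#' grey level `i` has first-order entropy `j` inside the `w x w` window
#' centred on it. Entropies (in bits) are discretised onto `entropy_bins`
#' equal-width bins covering `[0, entropy_max]`; the maximum attainable
#' first-order entropy over `G` grey levels is `log2(G)`, which is the
#' default bin range.
#'
#' @param window Odd window side length in pixels (default 9).
#' @param grey_levels Number of grey levels `G` after re-quantisation
#'   (default 64).
#' @param entropy_bins Number of entropy bins `B` (default 64, keeping the
#'   matrix square).
#' @param entropy_max Upper edge of the entropy axis in bits (default
#'   `log2(grey_levels)`).
#' @return A list of class `glem_params`.
#' @export
glem_params <- function(window = 9L, grey_levels = 64L, entropy_bins = 64L,
                        entropy_max = log2(grey_levels)) {
  window <- as.integer(window)
  grey_levels <- as.integer(grey_levels)
  entropy_bins <- as.integer(entropy_bins)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd and >= 3")
  if (grey_levels < 2L) stop("`grey_levels` must be >= 2")
  if (entropy_bins < 2L) stop("`entropy_bins` must be >= 2")
  if (entropy_max <= 0) stop("`entropy_max` must be positive")
  structure(list(window = window, grey_levels = grey_levels,
                 entropy_bins = entropy_bins, entropy_max = entropy_max),
            class = "glem_params")
}

#' First-order entropy of the window around one pixel
#'
#' Computes `-sum_i P(i) log2 P(i)` where `P(i)` is the frequency of grey
#' level `i` among the mask-true pixels of the `w x w` window centred on
#' `center`, clipped at the image borders. Terms with `P(i) = 0` contribute
#' nothing. The centre pixel itself is always counted, so the result is
#' always defined.
#'
#' @param pixels Integer matrix of re-quantised grey levels in
#'   `[0, grey_levels - 1]`.
#' @param mask Logical matrix of the same shape.
#' @param center `c(row, col)` of a mask-true pixel.
#' @param params A [glem_params()].
#' @return Entropy in bits, in `[0, log2(grey_levels)]`.
#' @export
local_entropy <- function(pixels, mask, center, params = glem_params()) {
  r <- center[1L]; cc <- center[2L]
  if (!mask[r, cc]) stop("`center` must be a mask-true pixel")
  half <- params$window %/% 2L
  rows <- max(1L, r - half):min(nrow(pixels), r + half)
  cols <- max(1L, cc - half):min(ncol(pixels), cc + half)
  v <- pixels[rows, cols][mask[rows, cols]]
  p <- tabulate(v + 1L, nbins = params$grey_levels) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Map of local first-order entropies over a nucleus
#'
#' @inheritParams compute_glem
#' @return Matrix the shape of the nucleus image with the entropy (bits) at
#'   every mask-true pixel and `NA` elsewhere.
#' @export
local_entropy_map <- function(nucleus, params = glem_params()) {
  .glem_checked(nucleus, params)$entropy_map
}

#' Compute the grey level entropy matrix of one nucleus
#'
#' Accumulates, over every mask-true pixel, the pair (grey level `i`,
#' entropy bin `j`) where `j = floor(E * B / entropy_max)` clamped to
#' `B - 1`, and normalises the count matrix to total mass 1. Only mask-true
#' pixels are counted inside windows (background glass would otherwise
#' dominate windows at the nuclear rim), and windows are clipped at image
#' borders with normalisation by the pixels actually counted.
#'
#' @param nucleus A re-quantised [nucleus_image()] with pixels in
#'   `[0, grey_levels - 1]`.
#' @param params A [glem_params()].
#' @return An object of class `glem`: list with `P` (G x B probability
#'   matrix), `params` and `n_pixels_counted` (the nuclear area).
#' @export
compute_glem <- function(nucleus, params = glem_params()) {
  res <- .glem_checked(nucleus, params)
  structure(list(P = res$P, params = params,
                 n_pixels_counted = res$n_pixels_counted),
            class = "glem")
}

.glem_checked <- function(nucleus, params) {
  stopifnot(inherits(nucleus, "nucleus_image"),
            inherits(params, "glem_params"))
  mx <- max(nucleus$pixels[nucleus$mask])
  if (mx >= params$grey_levels) {
    stop("pixel value ", mx, " >= grey_levels (", params$grey_levels,
         "); re-quantise first")
  }
  glem_core(nucleus$pixels, nucleus$mask, params$window, params$grey_levels,
            params$entropy_bins, params$entropy_max)
}

#' @export
print.glem <- function(x, ...) {
  cat(sprintf("<glem> %d x %d, window %d, %d pixels counted\n",
              nrow(x$P), ncol(x$P), x$params$window, x$n_pixels_counted))
  invisible(x)
}

#' GLEMs and area groups for a whole cohort
#'
#' Convenience wrapper used by the pipeline: re-quantises every nucleus,
#' computes its GLEM and assigns its area group.
#'
#' @param nuclei_by_patient Named list (by patient id) of lists of
#'   [nucleus_image()] objects at original grey depth.
#' @param params A [glem_params()].
#' @param from_levels Grey depth of the input images (default 1024).
#' @return A list of class `glem_set`: `info`, a data.frame with columns
#'   `patient_id`, `nucleus_id`, `area`, `area_group`; and `glems`, a list
#'   of GLEM probability matrices row-aligned with `info`.
#' @export
cohort_glems <- function(nuclei_by_patient, params = glem_params(),
                         from_levels = 1024L) {
  rows <- list(); mats <- list(); k <- 0L
  for (pid in names(nuclei_by_patient)) {
    for (n in nuclei_by_patient[[pid]]) {
      k <- k + 1L
      rq <- requantise(n, from_levels = from_levels,
                       to_levels = params$grey_levels)
      mats[[k]] <- compute_glem(rq, params)$P
      rows[[k]] <- data.frame(patient_id = pid, nucleus_id = n$nucleus_id,
                              area = n$area, area_group = area_group(n$area),
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(info = do.call(rbind, rows), glems = mats),
            class = "glem_set")
}
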