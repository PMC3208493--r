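#' Construct a segmented nucleus image
#'
#' A nucleus image couples a transmitted-light grey-level matrix with a binary
#' segmentation mask of identical shape. Grey levels follow the convention
#' that larger values mean brighter pixels, i.e. more transmitted light and
#' therefore less DNA; clear glass sits near `grey_depth - 1`.
#'
#' @param pixels Integer matrix of grey levels in `[0, grey_depth - 1]`.
#' @param mask Logical matrix, same shape as `pixels`; `TRUE` marks nuclear
#'   pixels.
#' @param patient_id,nucleus_id Identifiers carried through the pipeline.
#' @param grey_depth Number of grey levels of the capture system
#'   (default 1024).
#' @return An object of class `nucleus_image` with fields `pixels`, `mask`,
#'   `area` (count of mask-true pixels), `patient_id`, `nucleus_id` and
#'   `grey_depth`.
#' @export
nucleus_image <- function(pixels, mask, patient_id = NA_character_,
                          nucleus_id = NA_character_, grey_depth = 1024L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.matrix(mask) || !is.logical(mask)) {
    mask <- matrix(as.logical(mask), nrow(pixels), ncol(pixels))
  }
  if (!identical(dim(pixels), dim(mask))) {
    stop("`pixels` and `mask` must have identical dimensions")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels)) stop("`pixels` must not contain NA")
  if (any(pixels < 0L) || any(pixels >= grey_depth)) {
    stop("pixel values must lie in [0, grey_depth - 1]")
  }
  area <- sum(mask)
  if (area == 0L) stop("mask is empty: nucleus has zero area")
  structure(
    list(pixels = pixels, mask = mask, area = area,
         patient_id = patient_id, nucleus_id = nucleus_id,
         grey_depth = as.integer(grey_depth)),
    class = "nucleus_image"
  )
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("<nucleus_image> %s/%s: %d x %d px, area %d, grey depth %d\n",
              x$patient_id, x$nucleus_id, nrow(x$pixels), ncol(x$pixels),
              x$area, x$grey_depth))
  invisible(x)
}

#' Re-quantise a nucleus image to fewer grey levels
#'
#' Linear floor binning: `pixel -> floor(pixel * to_levels / from_levels)`.
#' This preserves the ordering of optical densities. Mask and area are
#' unchanged. Texture matrices are computed on re-quantised images (by
#' default 1024 grey levels down to 64); densitometry
#' ([integrated_optical_density()]) always uses the original depth.
#'
#' @param nucleus A [nucleus_image()].
#' @param from_levels Grey depth of the input (defaults to the nucleus's own
#'   `grey_depth`).
#' @param to_levels Target number of grey levels (default 64).
#' @return A `nucleus_image` whose pixels lie in `[0, to_levels - 1]` and
#'   whose `grey_depth` equals `to_levels`.
#' @export
requantise <- function(nucleus, from_levels = nucleus$grey_depth,
                       to_levels = 64L) {
  stopifnot(inherits(nucleus, "nucleus_image"))
  from_levels <- as.integer(from_levels)
  to_levels <- as.integer(to_levels)
  if (from_levels < to_levels) stop("`from_levels` must be >= `to_levels`")
  if (any(nucleus$pixels >= from_levels)) {
    stop("pixel value >= `from_levels`; image is not at the stated depth")
  }
  px <- matrix(as.integer(floor(as.numeric(nucleus$pixels) * to_levels /
                                  from_levels)),
               nrow(nucleus$pixels), ncol(nucleus$pixels))
  out <- nucleus
  out$pixels <- px
  out$grey_depth <- to_levels
  out
}

#' Assign a nuclear area to its area group
#'
#' Nuclei are grouped by pixel area into the intervals A0 (< 1000 px),
#' A1 (1000-1999 px), A2 (2000-2999 px), ..., A9 (9000-9999 px) and
#' A10 (>= 10000 px). The adaptive texture statistics are learned per group
#' so that chromatin texture is compared between nuclei of similar size.
#'
#' @param area Positive integer vector of pixel areas.
#' @return Integer vector of group indices in `0:10`.
#' @export
area_group <- function(area) {
  if (!is.numeric(area) || any(is.na(area)) || any(area <= 0)) {
    stop("`area` must be positive")
  }
  pmin(as.integer(area %/% 1000), 10L)
}

# ---- gallery read/write ----------------------------------------------------

# 16-bit grey TIFFs hold raw integer grey levels (<= 65535); masks are
# written as 0/1 single-bit-equivalent 8-bit images.
.write_tiff_int <- function(m, path, bits = 16L) {
  scale <- 2^bits - 1
  tiff::writeTIFF(m / scale, path, bits.per.sample = bits,
                  compression = "none")
}

.read_tiff_int <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # tolerate multi-channel files
  storage.mode(m) <- "integer"
  m
}

#' Write a gallery of nucleus images for one patient
#'
#' One directory per patient: for each nucleus a 16-bit greyscale TIFF
#' `<nucleus_id>.tif` plus a mask image `<nucleus_id>_mask.tif`, and a
#' `manifest.csv` with one row per nucleus.
#'
#' @param nuclei List of [nucleus_image()] objects (one patient).
#' @param path Directory to create/fill.
#' @param extra Optional data.frame of per-nucleus columns (e.g. the true
#'   c-value of a synthetic nucleus), row-aligned with `nuclei`, merged into
#'   the manifest.
#' @return Invisibly, the manifest data.frame.
#' @export
write_gallery <- function(nuclei, path, extra = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(nuclei, function(n) n$nucleus_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate nucleus ids in gallery")
  for (n in nuclei) {
    .write_tiff_int(n$pixels, file.path(path, paste0(n$nucleus_id, ".tif")))
    .write_tiff_int(matrix(as.integer(n$mask) * 255L, nrow(n$mask),
                           ncol(n$mask)),
                    file.path(path, paste0(n$nucleus_id, "_mask.tif")),
                    bits = 8L)
  }
  manifest <- data.frame(
    nucleus_id = ids,
    area_px = vapply(nuclei, function(n) n$area, integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) manifest <- cbind(manifest, extra)
  write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a gallery of nucleus images
#'
#' Reads every `<id>.tif` / `<id>_mask.tif` pair in a patient directory.
#' A missing mask is an error naming the offending image; a mask with no
#' `TRUE` pixel drops that nucleus with a warning. Nuclei are returned in
#' lexicographic `nucleus_id` order so downstream results are deterministic.
#'
#' @param path Gallery directory.
#' @param patient_id Identifier stored on each nucleus (defaults to the
#'   directory name).
#' @param grey_depth Grey depth the images were captured at (default 1024).
#' @return List of [nucleus_image()] objects.
#' @export
load_gallery <- function(path, patient_id = basename(path),
                         grey_depth = 1024L) {
  if (!dir.exists(path)) stop("gallery directory does not exist: ", path)
  files <- list.files(path, pattern = "\\.tif$")
  imgs <- sort(files[!grepl("_mask\\.tif$", files)])
  out <- vector("list", length(imgs))
  keep <- logical(length(imgs))
  for (k in seq_along(imgs)) {
    id <- sub("\\.tif$", "", imgs[k])
    mask_file <- file.path(path, paste0(id, "_mask.tif"))
    if (!file.exists(mask_file)) {
      stop("missing mask for nucleus image: ", file.path(path, imgs[k]))
    }
    px <- .read_tiff_int(file.path(path, imgs[k]))
    mk <- .read_tiff_int(mask_file) > 0L
    if (!identical(dim(px), dim(mk))) {
      stop("image/mask shape mismatch for nucleus: ", id)
    }
    if (!any(mk)) {
      warning("empty mask, nucleus skipped: ", id)
      next
    }
    out[[k]] <- nucleus_image(px, mk, patient_id = patient_id,
                              nucleus_id = id, grey_depth = grey_depth)
    keep[k] <- TRUE
  }
  out[keep]
}

#' Read or write a cohort case table
#'
#' The case table has exactly the columns `patient_id`, `label`
#' (`nondysplastic`/`dysplastic`) and `split` (`train`/`test`).
#'
#' @param path CSV file path.
#' @return `read_case_table()` returns the validated data.frame.
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stop("case table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_case_table(tab)
  tab
}

#' @rdname read_case_table
#' @param case_table Data.frame with the three columns above.
#' @export
write_case_table <- function(case_table, path) {
  validate_case_table(case_table)
  write.csv(case_table, path, row.names = FALSE)
  invisible(path)
}

validate_case_table <- function(tab) {
  need <- c("patient_id", "label", "split")
  if (!all(need %in% names(tab))) {
    stop("case table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$patient_id)) stop("duplicate patient_id in case table")
  if (!all(tab$label %in% c("nondysplastic", "dysplastic"))) {
    stop("label must be 'nondysplastic' or 'dysplastic'")
  }
  if (!all(tab$split %in% c("train", "test"))) {
    stop("split must be 'train' or 'test'")
  }
  invisible(tab)
}
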