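#' One CT slice in Hounsfield units
#'
#' The unit every stage of the package consumes: a numeric matrix of
#' Hounsfield units (HU, water = 0, air = -1000) plus the acquisition
#' metadata needed downstream (pixel spacing for physical-radius ROIs,
#' patient id for patient-level splitting, slice index for ordering).
#'
#' @param pixels numeric matrix of HU values; all entries must be finite.
#' @param pixel_spacing length-2 numeric, (row, col) spacing in mm, both > 0.
#' @param patient_id opaque string identifying the subject.
#' @param slice_index integer >= 0, position of the slice within its series.
#' @param dose_tag one of `"HQ"` (high-dose reference), `"LQ"` (low-dose
#'   input) or `"OUTPUT"` (network output).
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(pixels, pixel_spacing = c(1, 1), patient_id = "anon",
                     slice_index = 0L, dose_tag = c("HQ", "LQ", "OUTPUT")) {
  dose_tag <- match.arg(dose_tag)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("`pixels` must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("`pixels` must be finite everywhere", call. = FALSE)
  }
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0)) {
    stop("`pixel_spacing` must be two strictly positive numbers (mm)",
         call. = FALSE)
  }
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0L) {
    stop("`slice_index` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         patient_id = as.character(patient_id),
         slice_index = slice_index, dose_tag = dose_tag),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d px, spacing %.3f x %.3f mm, patient %s, slice %d, %s\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$patient_id, x$slice_index, x$dose_tag))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

#' An 8-bit image with its HU window
#'
#' The network consumes 8-bit arrays; the window used for the HU mapping is
#' kept on the object so the mapping stays invertible (up to clipping and
#' quantization) and so ROI analysis can always be run in HU.
#'
#' @param pixels numeric/integer matrix with values in `[0, 255]`.
#' @param window length-2 numeric `(center_hu, width_hu)`; width must be > 0.
#' @return An object of class `image8`.
#' @export
image8 <- function(pixels, window = c(40, 400)) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (any(pixels < 0 | pixels > 255) || any(!is.finite(pixels))) {
    stop("`pixels` must lie in [0, 255]", call. = FALSE)
  }
  window <- as.numeric(window)
  if (length(window) != 2L || window[2] <= 0) {
    stop("`window` must be (center, width) with width > 0", call. = FALSE)
  }
  structure(list(pixels = pixels, window = window), class = "image8")
}

#' @export
print.image8 <- function(x, ...) {
  cat(sprintf("<image8> %d x %d px, window C%.0f/W%.0f HU, range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$window[1], x$window[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image8 <- function(x) dim(x$pixels)

#' An aligned high-dose / low-dose slice pair
#'
#' @param hq,lq `ct_image` objects from the same subject and slice position;
#'   they must share dimensions, pixel spacing, patient id and slice index.
#' @param dose_fraction low-to-high dose ratio, in `(0, 1]`.
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(hq, lq, dose_fraction) {
  stopifnot(inherits(hq, "ct_image"), inherits(lq, "ct_image"))
  if (!identical(dim(hq$pixels), dim(lq$pixels))) {
    stop("hq and lq must share dimensions", call. = FALSE)
  }
  if (!isTRUE(all.equal(hq$pixel_spacing, lq$pixel_spacing))) {
    stop("hq and lq must share pixel spacing", call. = FALSE)
  }
  if (!identical(hq$patient_id, lq$patient_id) ||
      !identical(hq$slice_index, lq$slice_index)) {
    stop("hq and lq must come from the same patient and slice", call. = FALSE)
  }
  dose_fraction <- as.numeric(dose_fraction)
  if (length(dose_fraction) != 1L || is.na(dose_fraction) ||
      dose_fraction <= 0 || dose_fraction > 1) {
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(hq = hq, lq = lq, dose_fraction = dose_fraction),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> patient %s slice %d, %d x %d px, dose fraction %.3f\n",
              x$hq$patient_id, x$hq$slice_index,
              nrow(x$hq$pixels), ncol(x$hq$pixels), x$dose_fraction))
  invisible(x)
}

# round-half-up, bit-exact across platforms (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Convert stored DICOM values to Hounsfield units
#'
#' Applies the standard DICOM rescale `HU = stored * slope + intercept`.
#'
#' @param stored numeric vector/matrix of stored pixel values.
#' @param slope rescale slope; must be non-zero.
#' @param intercept rescale intercept.
#' @return Values in HU, same shape as `stored`.
#' @seealso [hu_to_stored()]
#' @export
stored_to_hu <- function(stored, slope, intercept) {
  if (!is.numeric(stored)) stop("`stored` must be numeric", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0) {
    stop("`slope` must be a single non-zero number", call. = FALSE)
  }
  stored * slope + intercept
}

#' Convert Hounsfield units to stored DICOM values
#'
#' Inverse of [stored_to_hu()]; rounds to the nearest stored integer
#' (half-up), so a round trip is exact for integer-valued HU with slope 1.
#'
#' @inheritParams stored_to_hu
#' @param hu numeric vector/matrix of HU values.
#' @export
hu_to_stored <- function(hu, slope, intercept) {
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0) {
    stop("`slope` must be a single non-zero number", call. = FALSE)
  }
  round_half_up((hu - intercept) / slope)
}

#' Window a CT slice into an 8-bit image
#'
#' Linearly maps the HU interval `[center - width/2, center + width/2]` onto
#' `[0, 255]`, rounding half-up to the nearest integer and clipping values
#' outside the window. The window is recorded on the result so the mapping is
#' invertible (up to clipping and quantization) via [uint8_to_hu()].
#'
#' The default is a soft-tissue window (center 40 HU, width 400 HU).
#'
#' @param img a `ct_image` or a numeric HU matrix.
#' @param window length-2 numeric `(center_hu, width_hu)`, width > 0.
#' @return An [image8()] object.
#' @export
hu_to_uint8 <- function(img, window = c(40, 400)) {
  px <- if (inherits(img, "ct_image")) img$pixels else img
  if (!is.matrix(px)) stop("`img` must be a ct_image or a matrix", call. = FALSE)
  window <- as.numeric(window)
  if (length(window) != 2L || !all(is.finite(window)) || window[2] <= 0) {
    stop("`window` width must be > 0", call. = FALSE)
  }
  lo <- window[1] - window[2] / 2
  y <- round_half_up((px - lo) / window[2] * 255)
  y[y < 0] <- 0
  y[y > 255] <- 255
  image8(y, window)
}

#' Map an 8-bit image back to Hounsfield units
#'
#' Inverts the linear windowing of [hu_to_uint8()] using the window stored on
#' the object. Exact up to the clipping and quantization incurred on the way
#' in.
#'
#' @param img8 an [image8()] object.
#' @param template optional `ct_image` supplying spacing and metadata for the
#'   result; if omitted a bare HU matrix is returned.
#' @param dose_tag dose tag for the reconstructed `ct_image` when `template`
#'   is given.
#' @export
uint8_to_hu <- function(img8, template = NULL, dose_tag = "OUTPUT") {
  stopifnot(inherits(img8, "image8"))
  lo <- img8$window[1] - img8$window[2] / 2
  hu <- lo + img8$pixels / 255 * img8$window[2]
  if (is.null(template)) return(hu)
  ct_image(hu, pixel_spacing = template$pixel_spacing,
           patient_id = template$patient_id,
           slice_index = template$slice_index, dose_tag = dose_tag)
}
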