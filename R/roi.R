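# Circular-ROI noise analysis in Hounsfield units: physical-radius masks,
# mean/SD inside each ROI, and the percent SD reduction between arms.

#' Describe a circular region of interest
#'
#' @param name ROI label (e.g. an organ name).
#' @param center length-2 numeric, (row, col) center in 1-based pixel
#'   coordinates (pixel centers sit at integer coordinates).
#' @param radius_mm physical radius, mm (> 0); the conventional value for
#'   organ-level noise measurements is 8 mm.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, center, radius_mm = 8) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2L)
  if (!is.numeric(radius_mm) || radius_mm <= 0) {
    stop("`radius_mm` must be > 0", call. = FALSE)
  }
  structure(list(name = as.character(name), center = center,
                 radius_mm = radius_mm),
            class = "roi_spec")
}

#' Boolean mask of a circular ROI
#'
#' A pixel is included iff the physical distance from its center to the ROI
#' center is at most `radius_mm`; anisotropic spacing therefore yields an
#' ellipse in pixel space. The circle must lie fully inside the image.
#'
#' @param center (row, col) in 1-based pixel coordinates.
#' @param radius_mm radius in mm.
#' @param pixel_spacing (row, col) spacing in mm.
#' @param shape (rows, cols) of the image.
#' @return Logical matrix of dimension `shape`.
#' @export
circular_mask <- function(center, radius_mm, pixel_spacing, shape) {
  center <- as.numeric(center)
  pixel_spacing <- as.numeric(pixel_spacing)
  shape <- as.integer(shape)
  # image extent runs from pixel 0.5 to m + 0.5 in pixel units
  if (center[1] - radius_mm / pixel_spacing[1] < 0.5 ||
      center[1] + radius_mm / pixel_spacing[1] > shape[1] + 0.5 ||
      center[2] - radius_mm / pixel_spacing[2] < 0.5 ||
      center[2] + radius_mm / pixel_spacing[2] > shape[2] + 0.5) {
    stop("ROI circle exceeds the image bounds", call. = FALSE)
  }
  dr <- (seq_len(shape[1]) - center[1]) * pixel_spacing[1]
  dc <- (seq_len(shape[2]) - center[2]) * pixel_spacing[2]
  outer(dr^2, dc^2, `+`) <= radius_mm^2
}

#' Mean and SD of HU inside a circular ROI
#'
#' @param img a [ct_image()].
#' @param roi a [roi_spec()].
#' @return An object of class `roi_stats`: list with `name`, `n_pixels`,
#'   `mean_hu`, `sd_hu` (sample SD, n-1 denominator; 0 for a single pixel).
#' @export
roi_stats <- function(img, roi) {
  stopifnot(inherits(img, "ct_image"), inherits(roi, "roi_spec"))
  mask <- circular_mask(roi$center, roi$radius_mm, img$pixel_spacing,
                        dim(img$pixels))
  n <- sum(mask)
  if (n == 0L) stop("ROI mask is empty", call. = FALSE)
  vals <- img$pixels[mask]
  structure(list(name = roi$name, n_pixels = n, mean_hu = mean(vals),
                 sd_hu = if (n > 1L) stats::sd(vals) else 0),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s: %d px, mean %.2f HU, SD %.2f HU\n",
              x$name, x$n_pixels, x$mean_hu, x$sd_hu))
  invisible(x)
}

#' Percent reduction in noise SD between arms
#'
#' `100 * (sd_lq - sd_out) / sd_lq`: positive when processing reduced the
#' noise.
#'
#' @param sd_lq SD in the low-dose arm, must be > 0.
#' @param sd_out SD in the processed arm.
#' @export
sd_reduction_pct <- function(sd_lq, sd_out) {
  if (!is.numeric(sd_lq) || any(sd_lq <= 0)) {
    stop("`sd_lq` must be > 0", call. = FALSE)
  }
  100 * (sd_lq - sd_out) / sd_lq
}

#' Organ-level ROI comparison table
#'
#' Computes mean/SD of HU inside each ROI on the low-dose and processed
#' slices and the percent SD reduction, in the shape of an organ-level
#' attenuation-and-noise table (one LQ row and one processed row per organ,
#' with the difference on the LQ row).
#'
#' @param lq,out `ct_image` slices (low-dose input and processed output).
#' @param rois list of [roi_spec()].
#' @return data.frame with columns organ, arm, n_pixels, mean_hu, sd_hu,
#'   sd_reduction_pct.
#' @export
roi_compare <- function(lq, out, rois) {
  stopifnot(length(rois) > 0)
  rows <- lapply(rois, function(roi) {
    s_lq <- roi_stats(lq, roi)
    s_out <- roi_stats(out, roi)
    rbind(
      data.frame(organ = roi$name, arm = "LQ", n_pixels = s_lq$n_pixels,
                 mean_hu = s_lq$mean_hu, sd_hu = s_lq$sd_hu,
                 sd_reduction_pct = sd_reduction_pct(s_lq$sd_hu, s_out$sd_hu)),
      data.frame(organ = roi$name, arm = "output", n_pixels = s_out$n_pixels,
                 mean_hu = s_out$mean_hu, sd_hu = s_out$sd_hu,
                 sd_reduction_pct = NA_real_)
    )
  })
  do.call(rbind, rows)
}

#' Read/write ROI definitions
#'
#' ROI lists round-trip through a plain CSV with columns
#' `name, row, col, radius_mm`.
#'
#' @param rois list of [roi_spec()].
#' @param path CSV path.
#' @export
write_rois <- function(rois, path) {
  df <- data.frame(name = vapply(rois, `[[`, "", "name"),
                   row = vapply(rois, function(r) r$center[1], 0),
                   col = vapply(rois, function(r) r$center[2], 0),
                   radius_mm = vapply(rois, `[[`, 0, "radius_mm"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    roi_spec(df$name[i], c(df$row[i], df$col[i]), df$radius_mm[i])
  })
}
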