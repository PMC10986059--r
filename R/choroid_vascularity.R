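#' Scan geometry of a structural B-scan
#'
#' @param lateral_um_per_px,axial_um_per_px nominal device pixel spacing, um.
#' @param nominal_scan_length_mm nominal scan line length, mm.
#' @param fovea_col image column of the fovea (1-based).
#' @param al_mm subject axial length, mm (must lie in (15, 40)).
#' @param reference_al_mm axial length the device scale assumes, mm.
#' @return validated list of class `scan_geometry`.
#' @export
scan_geometry <- function(lateral_um_per_px,
                          axial_um_per_px,
                          nominal_scan_length_mm = 12,
                          fovea_col,
                          al_mm = 24.385,
                          reference_al_mm = 24.385) {
  g <- list(lateral_um_per_px = lateral_um_per_px,
            axial_um_per_px = axial_um_per_px,
            nominal_scan_length_mm = nominal_scan_length_mm,
            fovea_col = as.integer(fovea_col),
            al_mm = al_mm,
            reference_al_mm = reference_al_mm)
  if (g$lateral_um_per_px <= 0 || g$axial_um_per_px <= 0)
    stopf("pixel spacings must be positive")
  if (!is_count(g$fovea_col)) stopf("fovea_col must be a positive integer")
  if (g$al_mm <= 15 || g$al_mm >= 40 ||
      g$reference_al_mm <= 15 || g$reference_al_mm >= 40)
    stopf("axial lengths must lie in (15, 40) mm")
  class(g) <- "scan_geometry"
  g
}

#' Ocular magnification scale factor from axial length
#'
#' Lateral image scale correction by Bennett's abbreviated axial-length
#' method: the retinal scaling factor q is proportional to (AL - 1.82) mm,
#' so an image acquired in an eye of length `al_mm` but displayed at the
#' device's `reference_al_mm` scale has its true lateral pixel spacing equal
#' to the nominal spacing times `(al_mm - 1.82) / (reference_al_mm - 1.82)`.
#' Only the lateral dimension is rescaled; axial spacing is AL-independent.
#'
#' @param al_mm subject axial length, mm, in (15, 40).
#' @param reference_al_mm device-assumed axial length, mm, in (15, 40).
#' @return dimensionless scale factor, strictly increasing in `al_mm`.
#' @examples
#' magnification_scale(26.205, 24.385) # about 1.0807
#' @export
magnification_scale <- function(al_mm, reference_al_mm = 24.385) {
  if (any(al_mm <= 15) || any(al_mm >= 40) ||
      any(reference_al_mm <= 15) || any(reference_al_mm >= 40))
    stopf("axial lengths must lie in (15, 40) mm")
  (al_mm - 1.82) / (reference_al_mm - 1.82)
}

#' Choroid boundary curves
#'
#' Per-column row indices of the choroid inner boundary (Bruch's membrane)
#' and the choroid-sclera interface, as produced by upstream segmentation.
#' The choroid band of a column `j` is the half-open pixel run
#' `(upper[j], lower[j]]`.
#'
#' @param upper_px,lower_px integer vectors of equal length (one entry per
#'   image column); `upper_px < lower_px` everywhere.
#' @return validated list of class `choroid_boundaries`.
#' @export
choroid_boundaries <- function(upper_px, lower_px) {
  if (length(upper_px) != length(lower_px))
    stopf("boundary vectors must have the same length")
  if (any(upper_px >= lower_px))
    stopf("upper boundary must lie strictly above the lower boundary everywhere")
  structure(list(upper_px = as.integer(upper_px),
                 lower_px = as.integer(lower_px)),
            class = "choroid_boundaries")
}

# choroid band mask implied by boundary curves
boundaries_to_mask <- function(boundaries, n_row) {
  up <- boundaries$upper_px
  lo <- boundaries$lower_px
  n_col <- length(up)
  if (any(lo > n_row) || any(up < 0))
    stopf("boundaries leave the image (height %d)", n_row)
  mask <- matrix(FALSE, n_row, n_col)
  for (j in seq_len(n_col)) mask[(up[j] + 1L):lo[j], j] <- TRUE
  mask
}

#' Niblack local-threshold parameters
#'
#' @param window_px odd window side length in pixels (>= 3). The default,
#'   51 px, spans about 0.3 mm laterally at 5.86 um/px.
#' @param k threshold offset multiplier; the classic Niblack setting is -0.2.
#' @return validated list of class `niblack_params`.
#' @export
niblack_params <- function(window_px = 51L, k = -0.2) {
  p <- list(window_px = as.integer(window_px), k = k)
  if (!is_count(p$window_px) || p$window_px < 3L || p$window_px %% 2L == 0L)
    stopf("window_px must be an odd integer >= 3")
  class(p) <- "niblack_params"
  p
}

#' Median despeckle filter
#'
#' 3x3 (radius 1) median filtering is the standard despeckle step applied to
#' OCT choroid images before binarization; it suppresses residual speckle
#' without blurring vessel walls.
#'
#' @param image 8-bit gray matrix.
#' @param radius median window radius in pixels (window side `2*radius+1`).
#' @return filtered 8-bit gray matrix of the same size.
#' @export
despeckle <- function(image, radius = 1L) {
  if (radius <= 0) return(image)
  out <- EBImage::medianFilter(image / 255, as.integer(radius)) * 255
  quantize_gray(matrix(as.numeric(out), nrow(image), ncol(image)))
}

#' Binarize the choroid with a masked Niblack local threshold
#'
#' Per-pixel threshold `T = mean + k * SD`, where mean and SD are computed
#' over a `window_px` square window restricted to pixels inside
#' `region_mask` (so statistics at the choroid's edge are never contaminated
#' by retina or sclera). A pixel is lumen iff its intensity is strictly
#' below `T`; ties are stroma. The output is confined to `region_mask`.
#'
#' @param image gray image matrix.
#' @param region_mask logical matrix of the same size; must be non-empty.
#' @param params a [niblack_params()] object.
#' @return logical lumen mask of the same size.
#' @export
niblack_binarize <- function(image, region_mask, params = niblack_params()) {
  stopifnot(inherits(params, "niblack_params"))
  if (!all(dim(image) == dim(region_mask)))
    stopf("image and region_mask dimensions differ")
  if (!any(region_mask)) stopf("region_mask is empty")
  if (params$window_px > min(dim(image)))
    stopf("window (%d px) does not fit in a %d x %d image",
          params$window_px, nrow(image), ncol(image))
  M <- region_mask * 1
  n <- box_sum(M, params$window_px)
  s1 <- box_sum(image * M, params$window_px)
  s2 <- box_sum(image * image * M, params$window_px)
  n_safe <- pmax(n, 1)
  mu <- s1 / n_safe
  va <- pmax(s2 / n_safe - mu^2, 0)
  thr <- mu + params$k * sqrt(va)
  region_mask & (image < thr)
}

#' Choroidal metrics container
#'
#' Builds a consistent set of choroidal metrics from a luminal and stromal
#' area: the total area is their sum by construction and the vascularity
#' index is the luminal share of the total, in percent.
#'
#' @param SFCT subfoveal choroidal thickness, um.
#' @param LA,SA luminal and stromal area, um^2.
#' @param meridian one of "vertical", "horizontal", "averaged".
#' @return list of class `choroid_metrics` with fields `SFCT`, `LA`, `SA`,
#'   `TCA`, `CVI`, `meridian`.
#' @export
choroid_metrics <- function(SFCT, LA, SA,
                            meridian = c("horizontal", "vertical", "averaged")) {
  meridian <- match.arg(meridian)
  if (LA < 0 || SA < 0 || SFCT < 0) stopf("areas and SFCT must be >= 0")
  TCA <- LA + SA
  structure(list(SFCT = SFCT, LA = LA, SA = SA, TCA = TCA,
                 CVI = if (TCA > 0) 100 * LA / TCA else 0,
                 meridian = meridian),
            class = "choroid_metrics")
}

#' @export
print.choroid_metrics <- function(x, ...) {
  cat(sprintf("<choroid_metrics %s> SFCT %.1f um | LA %.1f | SA %.1f | TCA %.1f (x10^3 um^2) | CVI %.2f%%\n",
              x$meridian, x$SFCT, x$LA / 1e3, x$SA / 1e3, x$TCA / 1e3, x$CVI))
  invisible(x)
}

#' Compute choroidal metrics over the submacular ROI
#'
#' The choroid region is the set of pixels in the half-open band
#' `(upper, lower]` within the ROI columns `[fovea_col - w, fovea_col + w)`,
#' where `w = round(roi_width_mm/2 * 1000 / corrected lateral spacing)` and
#' the corrected spacing is the nominal spacing times the axial-length
#' magnification scale. LA is the lumen pixel count times the corrected
#' pixel area, SA the remaining band pixels times the same area; TCA =
#' LA + SA exactly; CVI = 100 * LA / TCA; SFCT is the boundary separation at
#' the fovea times the axial spacing.
#'
#' @param boundaries a [choroid_boundaries()] object.
#' @param geometry a [scan_geometry()] object.
#' @param lumen_mask logical matrix from [niblack_binarize()].
#' @param roi_width_mm ROI width centred on the fovea (default 6 mm).
#' @param meridian label stored in the result.
#' @return a [choroid_metrics()] object.
#' @export
compute_choroid_metrics <- function(boundaries, geometry, lumen_mask,
                                    roi_width_mm = 6.0,
                                    meridian = c("horizontal", "vertical")) {
  stopifnot(inherits(boundaries, "choroid_boundaries"),
            inherits(geometry, "scan_geometry"))
  meridian <- match.arg(meridian)
  n_row <- nrow(lumen_mask)
  n_col <- ncol(lumen_mask)
  if (length(boundaries$upper_px) != n_col)
    stopf("boundaries cover %d columns but the mask has %d",
          length(boundaries$upper_px), n_col)
  scale <- magnification_scale(geometry$al_mm, geometry$reference_al_mm)
  lat_um <- geometry$lateral_um_per_px * scale
  half_w <- round(roi_width_mm / 2 * 1000 / lat_um)
  roi_cols <- (geometry$fovea_col - half_w):(geometry$fovea_col + half_w - 1L)
  if (roi_cols[1] < 1L || roi_cols[length(roi_cols)] > n_col)
    stopf("%.1f mm ROI (columns %d..%d) exceeds the image width %d",
          roi_width_mm, roi_cols[1], roi_cols[length(roi_cols)], n_col)
  band <- boundaries_to_mask(boundaries, n_row)
  pixel_area <- lat_um * geometry$axial_um_per_px
  band_roi <- band[, roi_cols]
  lumen_roi <- lumen_mask[, roi_cols] & band_roi
  LA <- sum(lumen_roi) * pixel_area
  SA <- (sum(band_roi) - sum(lumen_roi)) * pixel_area
  SFCT <- (boundaries$lower_px[geometry$fovea_col] -
             boundaries$upper_px[geometry$fovea_col]) * geometry$axial_um_per_px
  choroid_metrics(SFCT = SFCT, LA = LA, SA = SA, meridian = meridian)
}

#' Average the vertical and horizontal meridian metrics
#'
#' Arithmetic mean of every field, including CVI (the mean of the
#' per-meridian ratios, not the ratio of the averaged areas), matching the
#' per-meridian estimation followed by meridian averaging.
#'
#' @param m_vertical,m_horizontal single-meridian [choroid_metrics()] objects.
#' @return a [choroid_metrics()] object with `meridian = "averaged"` whose
#'   CVI is the mean of the two input CVIs.
#' @export
average_meridians <- function(m_vertical, m_horizontal) {
  stopifnot(inherits(m_vertical, "choroid_metrics"),
            inherits(m_horizontal, "choroid_metrics"))
  if (m_vertical$meridian == "averaged" || m_horizontal$meridian == "averaged")
    stopf("inputs must be single-meridian metrics")
  out <- choroid_metrics(SFCT = (m_vertical$SFCT + m_horizontal$SFCT) / 2,
                         LA = (m_vertical$LA + m_horizontal$LA) / 2,
                         SA = (m_vertical$SA + m_horizontal$SA) / 2,
                         meridian = "averaged")
  # CVI averages as the mean of per-meridian ratios
  out$CVI <- (m_vertical$CVI + m_horizontal$CVI) / 2
  out
}
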