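#' Choriocapillaris slab definition
#'
#' The choriocapillaris slab starts at the basal border of the RPE-Bruch's
#' membrane complex and extends a fixed distance below it (20 um by
#' default).
#'
#' @param offset_um start of the slab below the BM surface, um (>= 0).
#' @param thickness_um slab thickness, um (> 0).
#' @return validated list of class `slab_spec`.
#' @export
slab_spec <- function(offset_um = 0, thickness_um = 20) {
  if (offset_um < 0) stopf("offset_um must be >= 0")
  if (thickness_um <= 0) stopf("thickness_um must be positive")
  structure(list(offset_um = offset_um, thickness_um = thickness_um),
            class = "slab_spec")
}

#' En-face angiogram container
#'
#' @param image 8-bit gray matrix.
#' @param lateral_um_per_px nominal lateral pixel spacing, um.
#' @param fovea_center numeric (row, col) of the fovea; defaults to the
#'   image centre.
#' @param al_mm,reference_al_mm axial lengths, mm, for magnification
#'   correction of the analysis circle.
#' @return list of class `cc_enface` (no ground truth attached).
#' @export
enface_angio <- function(image, lateral_um_per_px, fovea_center = NULL,
                         al_mm = 24.385, reference_al_mm = 24.385) {
  if (is.null(fovea_center))
    fovea_center <- c((nrow(image) + 1) / 2, (ncol(image) + 1) / 2)
  structure(list(image = image,
                 lateral_um_per_px = lateral_um_per_px,
                 fovea_center = fovea_center,
                 al_mm = al_mm,
                 reference_al_mm = reference_al_mm,
                 truth = NULL),
            class = "cc_enface")
}

#' Project a choriocapillaris slab to an en-face image
#'
#' Each en-face pixel is the mean intensity over the depth run
#' `[bm_surface, bm_surface + thickness)` below the per-pixel BM surface,
#' with the slab converted from um to pixels by the axial spacing.
#'
#' @param volume 3-D array `[row, col, depth]` of gray values.
#' @param bm_surface integer matrix `[row, col]` of BM depth indices
#'   (1-based).
#' @param spec a [slab_spec()] object.
#' @param axial_um_per_px axial pixel spacing, um.
#' @param lateral_um_per_px lateral pixel spacing of the en-face grid, um.
#' @return a `cc_enface` object (see [enface_angio()]).
#' @export
project_cc_slab <- function(volume, bm_surface, spec = slab_spec(),
                            axial_um_per_px, lateral_um_per_px = 3000 / 512) {
  stopifnot(inherits(spec, "slab_spec"))
  d <- dim(volume)
  if (length(d) != 3L) stopf("volume must be a 3-D array [row, col, depth]")
  if (!all(dim(bm_surface) == d[1:2]))
    stopf("bm_surface must match the lateral dimensions of the volume")
  z0_off <- round(spec$offset_um / axial_um_per_px)
  n_z <- max(1L, round(spec$thickness_um / axial_um_per_px))
  z_start <- bm_surface + z0_off
  bad <- which(z_start < 1L | (z_start + n_z - 1L) > d[3], arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("slab leaves the volume depth range at %d position(s), first at (row %d, col %d)",
          nrow(bad), bad[1, 1], bad[1, 2])
  acc <- matrix(0, d[1], d[2])
  base_idx <- matrix(seq_len(d[1] * d[2]), d[1], d[2])
  for (k in seq_len(n_z) - 1L)
    acc <- acc + volume[base_idx + (z_start + k - 1L) * d[1] * d[2]]
  enface_angio(acc / n_z, lateral_um_per_px = lateral_um_per_px)
}

#' Compensate an en-face angiogram for shadow and projection artifacts
#'
#' Shadowing is adjusted by dividing the image by the smoothed co-registered
#' inner-retina reference normalized to its global median (regions the
#' overlying opacity darkens in the reference are brightened in the slab by
#' the same factor). Retinal-vessel projections are removed by replacing
#' pixels under `projection_mask` with the median of the surrounding
#' non-projection pixels in a ring around each pixel. The output is clipped
#' to `[0, 255]`.
#'
#' @param enface a `cc_enface` object.
#' @param reference co-registered inner-retina en-face gray matrix of the
#'   same size.
#' @param projection_mask optional logical matrix of projection pixels.
#' @param smooth_sigma_px Gaussian sigma (px) for smoothing the reference.
#' @param inpaint_radius_px half-width of the ring used for projection
#'   inpainting.
#' @return a `cc_enface` object with the compensated image.
#' @export
compensate_enface <- function(enface, reference, projection_mask = NULL,
                              smooth_sigma_px = 15, inpaint_radius_px = 6L) {
  stopifnot(inherits(enface, "cc_enface"))
  img <- enface$image
  if (!all(dim(reference) == dim(img)))
    stopf("reference dimensions differ from the en-face image")
  sref <- EBImage::gblur(reference / 255, sigma = smooth_sigma_px) * 255
  sref <- matrix(as.numeric(sref), nrow(img), ncol(img))
  if (min(sref) <= 0)
    stopf("smoothed reference contains non-positive values; cannot compensate")
  ratio <- sref / median(sref)
  out <- img / ratio

  if (!is.null(projection_mask) && any(projection_mask)) {
    if (!all(dim(projection_mask) == dim(img)))
      stopf("projection_mask dimensions differ from the en-face image")
    out[projection_mask] <- NA_real_
    idx <- which(projection_mask, arr.ind = TRUE)
    r <- as.integer(inpaint_radius_px)
    offs <- expand.grid(dr = -r:r, dc = -r:r)
    nbr <- matrix(NA_real_, nrow(idx), nrow(offs))
    for (o in seq_len(nrow(offs))) {
      rr <- idx[, 1] + offs$dr[o]
      cc <- idx[, 2] + offs$dc[o]
      ok <- rr >= 1L & rr <= nrow(out) & cc >= 1L & cc <= ncol(out)
      v <- rep(NA_real_, nrow(idx))
      v[ok] <- out[cbind(rr[ok], cc[ok])]
      nbr[, o] <- v
    }
    fill <- apply(nbr, 1L, median, na.rm = TRUE)
    # widen the ring for any pixel whose whole neighbourhood was projection
    still <- is.na(fill)
    if (any(still)) fill[still] <- median(out, na.rm = TRUE)
    out[projection_mask] <- fill
  }
  res <- enface
  res$image <- quantize_gray(out)
  res$truth <- NULL
  res
}

#' Flow-deficit threshold specification
#'
#' The deficit rule is an absolute cut on the compensated 8-bit image:
#' a pixel is a flow deficit iff its intensity is strictly below
#' `multiplier * sigma_ref` (ties count as perfused). `sigma_ref` is the
#' mean SD of a normative database of healthy scans, approximately 30 gray
#' levels for the device emulated here; the classic rule multiplies it
#' by 1.5.
#'
#' @param sigma_ref reference-population SD in gray levels (> 0).
#' @param multiplier threshold multiplier (> 0).
#' @return validated list of class `fd_threshold_spec`.
#' @export
fd_threshold_spec <- function(sigma_ref = 30, multiplier = 1.5) {
  if (sigma_ref <= 0) stopf("sigma_ref must be positive")
  if (multiplier <= 0) stopf("multiplier must be positive")
  structure(list(sigma_ref = sigma_ref, multiplier = multiplier),
            class = "fd_threshold_spec")
}

#' Compute the choriocapillaris flow-deficit percentage
#'
#' Applies the absolute `multiplier * sigma_ref` threshold to the en-face
#' image and reports the percentage of deficit pixels among the pixels
#' whose centres fall inside a circle of `circle_diameter_mm` centred on
#' the fovea. The circle is sized in magnification-corrected lateral units.
#'
#' @param enface a `cc_enface` object.
#' @param spec a [fd_threshold_spec()] object.
#' @param circle_diameter_mm analysis circle diameter (default 2.5 mm).
#' @return list of class `flow_deficit_result` with `ccfd_pct`,
#'   `deficit_mask` (confined to the circle), `roi` (centre, diameter,
#'   radius in px) and `n_roi_px`.
#' @export
compute_ccfd <- function(enface, spec = fd_threshold_spec(),
                         circle_diameter_mm = 2.5) {
  stopifnot(inherits(enface, "cc_enface"), inherits(spec, "fd_threshold_spec"))
  img <- enface$image
  scale <- magnification_scale(enface$al_mm, enface$reference_al_mm)
  radius_px <- circle_diameter_mm / 2 * 1000 /
    (enface$lateral_um_per_px * scale)
  ctr <- enface$fovea_center
  if (ctr[1] - radius_px < 0.5 || ctr[1] + radius_px > nrow(img) + 0.5 ||
      ctr[2] - radius_px < 0.5 || ctr[2] + radius_px > ncol(img) + 0.5)
    stopf("%.2f mm circle leaves the %d x %d field",
          circle_diameter_mm, nrow(img), ncol(img))
  circ <- circle_mask(nrow(img), ncol(img), ctr, radius_px)
  thr <- spec$multiplier * spec$sigma_ref
  deficit <- circ & (img < thr)
  structure(list(ccfd_pct = 100 * sum(deficit) / sum(circ),
                 deficit_mask = deficit,
                 roi = list(center = ctr, diameter_mm = circle_diameter_mm,
                            radius_px = radius_px),
                 n_roi_px = sum(circ)),
            class = "flow_deficit_result")
}

#' @export
print.flow_deficit_result <- function(x, ...) {
  cat(sprintf("<flow_deficit_result> CcFD %.2f%% in a %.1f mm circle (%d px)\n",
              x$ccfd_pct, x$roi$diameter_mm, x$n_roi_px))
  invisible(x)
}
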