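#' Parameters for a synthetic choriocapillaris en-face angiogram
#'
#' Describes a 3 mm x 3 mm en-face OCTA choriocapillaris slab image with a
#' known flow-deficit fraction inside the eventual 2.5-mm analysis circle,
#' plus optional shadowing (multiplicative attenuation under an overlying
#' opacity) and retinal-vessel projection artifacts (bright stripes copied
#' from the inner-retina flow image).
#'
#' @param image_size_px square field size in pixels (512 emulates a 3-mm
#'   raster of 512 B-scans x 512 A-scans).
#' @param lateral_um_per_px nominal pixel spacing, um.
#' @param target_fd_fraction desired deficit fraction inside the 2.5-mm
#'   circle, in `[0, 0.5]`.
#' @param deficit_blob_radius_um radius range of elliptical deficit blobs, um.
#' @param perfused_mean,deficit_mean gray levels of perfused and deficit
#'   pixels; `perfused_mean` must exceed `deficit_mean`.
#' @param noise_sd additive Gaussian texture noise, gray levels.
#' @param shadow_attenuation multiplicative factor in `[0, 1]` applied inside
#'   the shadow region; 1 means no shadow.
#' @param shadow_radius_um radius of the circular shadow region, um.
#' @param projection_vessel_width_um width of each projection stripe, um.
#' @param n_projection_vessels number of projection stripes (0 disables).
#' @param al_mm,reference_al_mm subject and device-reference axial length, mm.
#' @param seed integer seed.
#' @return validated parameter list of class `angio_params`.
#' @export
angio_params <- function(image_size_px = 512L,
                         lateral_um_per_px = 3000 / 512,
                         target_fd_fraction = 0.07,
                         deficit_blob_radius_um = c(15, 50),
                         perfused_mean = 180,
                         deficit_mean = 5,
                         noise_sd = 5,
                         shadow_attenuation = 1,
                         shadow_radius_um = 400,
                         projection_vessel_width_um = 25,
                         n_projection_vessels = 0L,
                         al_mm = 24.385,
                         reference_al_mm = 24.385,
                         seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            lateral_um_per_px = lateral_um_per_px,
            target_fd_fraction = target_fd_fraction,
            deficit_blob_radius_um = deficit_blob_radius_um,
            perfused_mean = perfused_mean,
            deficit_mean = deficit_mean,
            noise_sd = noise_sd,
            shadow_attenuation = shadow_attenuation,
            shadow_radius_um = shadow_radius_um,
            projection_vessel_width_um = projection_vessel_width_um,
            n_projection_vessels = as.integer(n_projection_vessels),
            al_mm = al_mm,
            reference_al_mm = reference_al_mm,
            seed = as.integer(seed))
  if (!is_count(p$image_size_px)) stopf("image_size_px must be a positive integer")
  if (p$lateral_um_per_px <= 0) stopf("lateral_um_per_px must be positive")
  if (p$target_fd_fraction < 0 || p$target_fd_fraction > 0.5)
    stopf("target_fd_fraction must lie in [0, 0.5]")
  if (length(p$deficit_blob_radius_um) != 2L ||
      any(p$deficit_blob_radius_um <= 0) || diff(p$deficit_blob_radius_um) < 0)
    stopf("deficit_blob_radius_um must be an increasing pair of positive values")
  if (p$perfused_mean <= p$deficit_mean)
    stopf("perfused_mean must exceed deficit_mean")
  if (p$noise_sd < 0) stopf("noise_sd must be non-negative")
  if (p$shadow_attenuation < 0 || p$shadow_attenuation > 1)
    stopf("shadow_attenuation must lie in [0, 1]")
  if (p$n_projection_vessels < 0) stopf("n_projection_vessels must be >= 0")
  class(p) <- "angio_params"
  p
}

# logical mask of pixels whose centres fall inside a circle
circle_mask <- function(n_row, n_col, center_rc, radius_px) {
  rows <- matrix(seq_len(n_row), n_row, n_col)
  cols <- matrix(seq_len(n_col), n_row, n_col, byrow = TRUE)
  (rows - center_rc[1])^2 + (cols - center_rc[2])^2 <= radius_px^2
}

#' Generate a synthetic en-face choriocapillaris angiogram with ground truth
#'
#' Perfused texture with inserted elliptical flow-deficit blobs; deficit
#' placement is re-drawn (at most 200 deterministic attempts) until the
#' realized deficit fraction inside the `circle_diameter_mm` analysis circle
#' is within +/-0.02 of the target. Optional multiplicative shadowing and
#' bright projection stripes are recorded in the truth, together with a
#' co-registered synthetic inner-retina reference image that carries the same
#' shadow dip and projection vessels (for [compensate_enface()]).
#'
#' @param params an [angio_params()] object.
#' @param circle_diameter_mm diameter of the calibration/analysis circle.
#' @return object of class `cc_enface`: list with `image` (8-bit gray
#'   matrix), `lateral_um_per_px`, `fovea_center` (row, col), and `truth`
#'   (deficit mask, realized fraction inside the circle, shadow map,
#'   projection mask, reference image, and the unshadowed render).
#' @export
generate_cc_enface <- function(params, circle_diameter_mm = 2.5) {
  stopifnot(inherits(params, "angio_params"))
  p <- params
  n <- p$image_size_px
  scale <- magnification_scale(p$al_mm, p$reference_al_mm)
  radius_px <- circle_diameter_mm / 2 * 1000 / (p$lateral_um_per_px * scale)
  center <- c((n + 1) / 2, (n + 1) / 2)
  if (2 * radius_px > n)
    stopf("%.2f mm circle (%.0f px) exceeds the %d px field",
          circle_diameter_mm, 2 * radius_px, n)
  circ <- circle_mask(n, n, center, radius_px)
  n_circ <- sum(circ)

  set.seed(p$seed)
  deficit <- matrix(FALSE, n, n)
  if (p$target_fd_fraction > 0) {
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      set.seed(p$seed + attempt)
      deficit <- matrix(FALSE, n, n)
      frac <- 0
      blob_i <- 0L
      while (frac < p$target_fd_fraction && blob_i < 50000L) {
        blob_i <- blob_i + 1L
        cx <- runif(1, 1, n)
        cy <- runif(1, 1, n)
        r_um <- runif(1, p$deficit_blob_radius_um[1], p$deficit_blob_radius_um[2])
        ecc <- runif(1, 1, 1.5)
        a <- r_um * sqrt(ecc) / p$lateral_um_per_px
        b <- r_um / sqrt(ecc) / p$lateral_um_per_px
        c_lo <- max(1L, floor(cx - a)); c_hi <- min(n, ceiling(cx + a))
        r_lo <- max(1L, floor(cy - b)); r_hi <- min(n, ceiling(cy + b))
        if (c_lo > c_hi || r_lo > r_hi) next
        rrs <- r_lo:r_hi
        ccs <- c_lo:c_hi
        inside <- outer(((rrs - cy) / b)^2, ((ccs - cx) / a)^2, `+`) <= 1
        deficit[rrs, ccs] <- deficit[rrs, ccs] | inside
        if (blob_i %% 10L == 0L) frac <- sum(deficit & circ) / n_circ
      }
      frac <- sum(deficit & circ) / n_circ
      if (abs(frac - p$target_fd_fraction) <= 0.02) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stopf("could not reach target_fd_fraction %.3f within +/-0.02 after 200 attempts",
            p$target_fd_fraction)
  }

  set.seed(p$seed + 1000L)
  base <- matrix(p$perfused_mean, n, n)
  base[deficit] <- p$deficit_mean
  image <- base + matrix(rnorm(n * n, 0, p$noise_sd), n, n)

  # projection stripes: bright near-vertical retinal vessels copied into the slab
  projection <- matrix(FALSE, n, n)
  if (p$n_projection_vessels > 0L) {
    w_px <- max(1L, round(p$projection_vessel_width_um / p$lateral_um_per_px))
    for (v in seq_len(p$n_projection_vessels)) {
      x0 <- runif(1, 0.1 * n, 0.9 * n)
      slope <- runif(1, -0.2, 0.2)
      rows <- seq_len(n)
      ctr <- x0 + slope * (rows - n / 2)
      for (dx in seq_len(w_px) - (w_px + 1L) %/% 2L) {
        cc <- round(ctr) + dx
        keep <- cc >= 1L & cc <= n
        projection[cbind(rows[keep], cc[keep])] <- TRUE
      }
    }
    image[projection] <- 200 + rnorm(sum(projection), 0, p$noise_sd)
  }

  unshadowed <- quantize_gray(image)

  # shadow: circular attenuation region, off-centre within the field
  shadow_map <- matrix(1, n, n)
  sh_center <- center + c(-0.12, 0.10) * n
  sh_rad <- p$shadow_radius_um / (p$lateral_um_per_px * scale)
  shadow_map[circle_mask(n, n, sh_center, sh_rad)] <- p$shadow_attenuation
  image <- quantize_gray(image * shadow_map)

  # co-registered inner-retina en-face: flat background + projection vessels,
  # attenuated by the same overlying shadow
  reference <- matrix(150, n, n)
  reference[projection] <- 230
  reference <- quantize_gray(reference * shadow_map)

  structure(list(image = image,
                 lateral_um_per_px = p$lateral_um_per_px,
                 fovea_center = center,
                 al_mm = p$al_mm,
                 reference_al_mm = p$reference_al_mm,
                 truth = list(deficit_mask = deficit,
                              realized_fd_fraction = sum(deficit & circ) / n_circ,
                              shadow_map = shadow_map,
                              projection_mask = projection,
                              reference = reference,
                              unshadowed = unshadowed),
                 params = p),
            class = "cc_enface")
}

#' @export
print.cc_enface <- function(x, ...) {
  cat(sprintf("<cc_enface> %d x %d px, true FD %.2f%%, shadow attenuation %.2f\n",
              nrow(x$image), ncol(x$image), 100 * x$truth$realized_fd_fraction,
              x$params$shadow_attenuation))
  invisible(x)
}
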