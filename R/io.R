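#' Write a B-scan scene to disk
#'
#' The image is stored as an 8-bit grayscale PNG and the scan geometry,
#' boundary curves and scalar ground truth as a JSON sidecar `<stem>.json`.
#'
#' @param scene a `bscan_scene` object.
#' @param stem file path without extension.
#' @return invisibly, the two file paths written.
#' @export
write_bscan_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "bscan_scene"))
  png_path <- paste0(stem, ".png")
  json_path <- paste0(stem, ".json")
  png::writePNG(scene$image / 255, png_path)
  sidecar <- list(
    type = "bscan_scene",
    geometry = unclass(scene$geometry),
    boundaries = list(upper_px = scene$boundaries$upper_px,
                      lower_px = scene$boundaries$lower_px),
    roi_width_mm = scene$roi_width_mm,
    truth = scene$truth[c("realized_lumen_fraction", "true_LA", "true_SA",
                          "true_TCA", "true_CVI", "true_SFCT")],
    seed = scene$params$seed)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}

#' Read a B-scan scene written by [write_bscan_scene()]
#'
#' Boundary CSVs with columns `column,upper_px,lower_px` are also accepted
#' in place of the JSON sidecar.
#'
#' @param stem file path without extension.
#' @return list with `image`, `boundaries`, `geometry`, `truth` (scalar
#'   ground truth, or NULL when the sidecar carries none).
#' @export
read_bscan_scene <- function(stem) {
  png_path <- paste0(stem, ".png")
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  if (!file.exists(png_path)) stopf("missing image file: %s", png_path)
  image <- round(png::readPNG(png_path) * 255)
  if (length(dim(image)) == 3L) image <- image[, , 1]
  if (file.exists(json_path)) {
    sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    g <- sc$geometry
    geometry <- scan_geometry(g$lateral_um_per_px, g$axial_um_per_px,
                              g$nominal_scan_length_mm, g$fovea_col,
                              g$al_mm, g$reference_al_mm)
    boundaries <- choroid_boundaries(sc$boundaries$upper_px,
                                     sc$boundaries$lower_px)
    truth <- sc$truth
    roi_width_mm <- sc$roi_width_mm
  } else if (file.exists(csv_path)) {
    b <- read.csv(csv_path)
    if (!all(c("column", "upper_px", "lower_px") %in% names(b)))
      stopf("boundary CSV %s must have columns column,upper_px,lower_px", csv_path)
    b <- b[order(b$column), ]
    boundaries <- choroid_boundaries(b$upper_px, b$lower_px)
    geometry <- NULL
    truth <- NULL
    roi_width_mm <- NULL
  } else {
    stopf("missing sidecar for %s (expected %s or %s)", png_path, json_path, csv_path)
  }
  list(image = image, boundaries = boundaries, geometry = geometry,
       truth = truth, roi_width_mm = roi_width_mm)
}

#' Write an en-face angiogram (and its artifact truth) to disk
#'
#' Writes `<stem>.png` (slab image), `<stem>_reference.png` (inner-retina
#' reference), `<stem>_projection.png` (binary projection mask) and a JSON
#' sidecar with scale, fovea centre and scalar truth.
#'
#' @param angio a `cc_enface` object with truth attached.
#' @param stem file path without extension.
#' @return invisibly, the file paths written.
#' @export
write_cc_enface <- function(angio, stem) {
  stopifnot(inherits(angio, "cc_enface"))
  paths <- paste0(stem, c(".png", "_reference.png", "_projection.png", ".json"))
  png::writePNG(angio$image / 255, paths[1])
  png::writePNG(angio$truth$reference / 255, paths[2])
  png::writePNG(angio$truth$projection_mask * 1, paths[3])
  sidecar <- list(
    type = "cc_enface",
    lateral_um_per_px = angio$lateral_um_per_px,
    fovea_center = angio$fovea_center,
    al_mm = angio$al_mm,
    reference_al_mm = angio$reference_al_mm,
    truth = list(realized_fd_fraction = angio$truth$realized_fd_fraction,
                 shadow_attenuation = angio$params$shadow_attenuation),
    seed = angio$params$seed)
  jsonlite::write_json(sidecar, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an en-face angiogram written by [write_cc_enface()]
#'
#' @param stem file path without extension.
#' @return a `cc_enface` object whose `truth` carries the reference image,
#'   projection mask and scalar truth.
#' @export
read_cc_enface <- function(stem) {
  paths <- paste0(stem, c(".png", "_reference.png", "_projection.png", ".json"))
  for (p in paths) if (!file.exists(p)) stopf("missing angiogram file: %s", p)
  img <- round(png::readPNG(paths[1]) * 255)
  ref <- round(png::readPNG(paths[2]) * 255)
  prj <- png::readPNG(paths[3]) > 0.5
  sc <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  out <- enface_angio(img, sc$lateral_um_per_px,
                      fovea_center = sc$fovea_center,
                      al_mm = sc$al_mm, reference_al_mm = sc$reference_al_mm)
  out$truth <- list(reference = ref, projection_mask = prj,
                    realized_fd_fraction = sc$truth$realized_fd_fraction,
                    shadow_attenuation = sc$truth$shadow_attenuation)
  out
}

# deterministic CSV writer used by every pipeline stage
write_csv_strict <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stopf("missing CSV: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss) > 0L)
    stopf("%s lacks required column(s): %s", path, paste(miss, collapse = ", "))
  df
}
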