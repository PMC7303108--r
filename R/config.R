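#' Default hematoxylin/eosin stain matrix
#'
#' Returns the standard Ruifrok–Johnston optical-density stain vectors for an
#' H&E slide: rows are hematoxylin, eosin, and a residual channel obtained as
#' the unit-normalized cross product of the first two (the usual completion
#' when only two stains are physically present). Rows are unit Euclidean norm.
#'
#' @return A 3x3 numeric matrix, rows named `hematoxylin`, `eosin`,
#'   `residual`, columns `R`, `G`, `B`.
#' @export
stain_matrix_he <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(h / sqrt(sum(h^2)), e / sqrt(sum(e^2)), r / sqrt(sum(r^2)))
  dimnames(m) <- list(c("hematoxylin", "eosin", "residual"), c("R", "G", "B"))
  m
}

#' Pipeline configuration
#'
#' Builds the configuration object shared by all pipeline stages. Defaults
#' reproduce the published operating conditions: 0.5 um/pixel scans, 480 um
#' (960 px) ROIs downsampled by 0.25 (nearest neighbor, effective 2 um/pixel),
#' slide-adaptive nucleus thresholds tuned on 2000 random 120 um tiles,
#' lumen RGB lower bounds (0.86, 0.71, 0.82), red-blood-cell
#' hue/saturation/value lower bounds (0.95, 0.72, 0.60) with a 4 um disk
#' dilation, and the 0.5 labeling and operating points.
#'
#' @param pixel_size_um physical size of one pixel at scan resolution (um).
#' @param downsample_ratio nearest-neighbor resize factor applied to each ROI
#'   before mapping and feature extraction, in (0, 1].
#' @param roi_size_um ROI side length in um; must map to an integer pixel
#'   count at `pixel_size_um`.
#' @param tuning_tile_um side length (um) of the tiles sampled per slide when
#'   tuning the adaptive nucleus threshold.
#' @param tuning_tile_count number of tuning tiles sampled per slide.
#' @param lumen_rgb_min length-3 RGB lower bounds in [0, 1] for lumen pixels.
#' @param rbc_hsi_min length-3 hue/saturation/value lower bounds in [0, 1]
#'   for red-blood-cell seed pixels.
#' @param rbc_dilate_radius_um disk radius (um) for RBC mask dilation.
#' @param stain_matrix 3x3 optical-density stain matrix, rows = hematoxylin,
#'   eosin, residual; rows are renormalized to unit length.
#' @param od_eps transmittance floor added before the log when computing
#'   optical density, avoiding log(0) on saturated black pixels.
#' @param tissue_bg_cutoff a tuning tile is rejected as background when its
#'   mean RGB is at or above this cutoff.
#' @param dye_hsv_band optional list(`h = c(lo, hi)`, `s_min =`, `cap =`)
#'   rejecting tiles whose fraction of marking-dye-colored pixels exceeds
#'   `cap`; `NULL` disables the filter.
#' @param label_threshold area fraction at or above which an ROI takes a
#'   positive ground-truth label.
#' @param operating_point confidence cutoff converting scores to hard labels.
#' @param rng_seed integer seed governing all stochastic steps.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(pixel_size_um = 0.5,
                            downsample_ratio = 0.25,
                            roi_size_um = 480,
                            tuning_tile_um = 120,
                            tuning_tile_count = 2000,
                            lumen_rgb_min = c(0.86, 0.71, 0.82),
                            rbc_hsi_min = c(0.95, 0.72, 0.60),
                            rbc_dilate_radius_um = 4,
                            stain_matrix = stain_matrix_he(),
                            od_eps = 1 / 256,
                            tissue_bg_cutoff = 0.9,
                            dye_hsv_band = NULL,
                            label_threshold = 0.5,
                            operating_point = 0.5,
                            rng_seed = 1L) {
  cfg <- list(
    pixel_size_um = pixel_size_um,
    downsample_ratio = downsample_ratio,
    roi_size_um = roi_size_um,
    tuning_tile_um = tuning_tile_um,
    tuning_tile_count = as.integer(tuning_tile_count),
    lumen_rgb_min = as.numeric(lumen_rgb_min),
    rbc_hsi_min = as.numeric(rbc_hsi_min),
    rbc_dilate_radius_um = rbc_dilate_radius_um,
    stain_matrix = normalize_stain_matrix(stain_matrix),
    od_eps = od_eps,
    tissue_bg_cutoff = tissue_bg_cutoff,
    dye_hsv_band = dye_hsv_band,
    label_threshold = label_threshold,
    operating_point = operating_point,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

normalize_stain_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || !is.numeric(m) || any(!is.finite(m))) {
    stop("`stain_matrix` must be a finite numeric 3x3 matrix", call. = FALSE)
  }
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("`stain_matrix` has a zero row", call. = FALSE)
  m <- m / norms
  if (abs(det(m)) < 1e-8) {
    stop("`stain_matrix` is singular after row normalization", call. = FALSE)
  }
  dimnames(m) <- list(c("hematoxylin", "eosin", "residual"), c("R", "G", "B"))
  m
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  with(cfg, {
    if (!(pixel_size_um > 0)) stop("pixel_size_um must be > 0", call. = FALSE)
    if (!(downsample_ratio > 0 && downsample_ratio <= 1)) {
      stop("downsample_ratio must lie in (0, 1]", call. = FALSE)
    }
    side <- roi_size_um / pixel_size_um
    if (abs(side - round(side)) > 1e-9) {
      stop("roi_size_um / pixel_size_um must be an integer pixel count",
           call. = FALSE)
    }
    if (length(lumen_rgb_min) != 3 || any(lumen_rgb_min < 0 | lumen_rgb_min > 1)) {
      stop("lumen_rgb_min must be three values in [0, 1]", call. = FALSE)
    }
    if (length(rbc_hsi_min) != 3 || any(rbc_hsi_min < 0 | rbc_hsi_min > 1)) {
      stop("rbc_hsi_min must be three values in [0, 1]", call. = FALSE)
    }
    if (rbc_dilate_radius_um < 0) stop("rbc_dilate_radius_um must be >= 0", call. = FALSE)
    if (!(label_threshold >= 0 && label_threshold <= 1)) {
      stop("label_threshold must lie in [0, 1]", call. = FALSE)
    }
    if (!(operating_point >= 0 && operating_point <= 1)) {
      stop("operating_point must lie in [0, 1]", call. = FALSE)
    }
    if (tuning_tile_count < 1) stop("tuning_tile_count must be >= 1", call. = FALSE)
  })
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  scan: %.3g um/px; ROI %g um (%d px); downsample x%g (eff. %.3g um/px)\n",
              x$pixel_size_um, x$roi_size_um, roi_side_px(x),
              x$downsample_ratio, effective_pixel_size(x)))
  cat(sprintf("  tuning: %d tiles of %g um; lumen RGB >= (%s); RBC HSV >= (%s), dilate %g um\n",
              x$tuning_tile_count, x$tuning_tile_um,
              paste(x$lumen_rgb_min, collapse = ", "),
              paste(x$rbc_hsi_min, collapse = ", "),
              x$rbc_dilate_radius_um))
  invisible(x)
}

#' ROI side length in pixels at scan resolution
#' @param config a [pipeline_config()].
#' @return integer pixel count.
#' @export
roi_side_px <- function(config) {
  as.integer(round(config$roi_size_um / config$pixel_size_um))
}

#' Effective pixel size after downsampling
#' @param config a [pipeline_config()].
#' @return um per pixel at the working (downsampled) resolution.
#' @export
effective_pixel_size <- function(config) {
  config$pixel_size_um / config$downsample_ratio
}

# micrometres -> pixels with round-half-up, the convention used everywhere
um_to_px <- function(um, pixel_size_um) {
  as.integer(floor(um / pixel_size_um + 0.5))
}
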