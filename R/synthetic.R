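#' Parameters of the synthetic H&E generator
#'
#' Controls the seeded generator that emulates the appearance cues the
#' pipeline exploits: dark basophilic nuclei, near-white gland lumina, pink
#' eosin stroma, occasional red-blood-cell blobs, per-slide stain-intensity
#' variability, and class-dependent morphology — benign tissue with sparse
#' nuclei and a few open glands, low-grade cancer with round open glands
#' ringed by nuclei, high-grade cancer with many small fused glands and
#' crowded nuclei.
#'
#' Densities are per mm^2 of tissue; radii in um. Stain strengths are
#' optical-density concentrations fed through the forward Beer–Lambert model
#' with the pipeline's stain matrix, so color deconvolution inverts the
#' rendering analytically. Noise is additive Gaussian in transmittance,
#' clipped to [0, 1].
#'
#' @param nucleus_density named vector, nuclei per mm^2 for benign / low /
#'   high tissue (beyond gland-ring nuclei).
#' @param nucleus_radius_um mean and sd of the nucleus semi-axis.
#' @param gland_density glands per mm^2 per class.
#' @param lumen_radius_um mean lumen radius per class.
#' @param ring_spacing_um spacing of nuclei along a gland boundary.
#' @param stain_od optical-density concentrations of the tissue compartments.
#' @param rbc_density RBC blobs per mm^2; `rbc_radius_um` their radius.
#' @param rbc_hsv hue/saturation/value of rendered blood; must fall inside
#'   the detector's threshold region.
#' @param brightness_range per-slide stain multiplier range (subset of
#'   [0.5, 1.5]); exercises the per-slide adaptive threshold.
#' @param noise_sd transmittance noise standard deviation.
#' @param class_mix tile class mixture used by [generate_cohort()].
#' @return object of class `synth_params`.
#' @export
synth_params <- function(nucleus_density = c(benign = 300, low = 900, high = 2200),
                         nucleus_radius_um = c(mean = 3.5, sd = 0.5),
                         gland_density = c(benign = 8, low = 25, high = 45),
                         lumen_radius_um = c(benign = 24, low = 20, high = 9),
                         ring_spacing_um = 8,
                         stain_od = list(nuclei = c(h = 0.85, e = 0.10),
                                         stroma = c(h = 0.05, e = 0.30),
                                         lumen = c(h = 0.02, e = 0.02)),
                         rbc_density = 1.5,
                         rbc_radius_um = 3.5,
                         rbc_hsv = c(h = 0.98, s = 0.85, v = 0.78),
                         brightness_range = c(0.8, 1.2),
                         noise_sd = 0.01,
                         class_mix = c(benign = 0.6, low = 0.2, high = 0.2)) {
  p <- list(nucleus_density = nucleus_density,
            nucleus_radius_um = nucleus_radius_um,
            gland_density = gland_density,
            lumen_radius_um = lumen_radius_um,
            ring_spacing_um = ring_spacing_um,
            stain_od = stain_od,
            rbc_density = rbc_density,
            rbc_radius_um = rbc_radius_um,
            rbc_hsv = rbc_hsv,
            brightness_range = brightness_range,
            noise_sd = noise_sd,
            class_mix = class_mix / sum(class_mix))
  stopifnot(all(p$nucleus_density >= 0), all(p$gland_density >= 0),
            p$brightness_range[1] >= 0.5, p$brightness_range[2] <= 1.5,
            p$brightness_range[1] <= p$brightness_range[2],
            p$noise_sd >= 0)
  class(p) <- "synth_params"
  p
}

# linear indices of a rotated ellipse clipped to an n x m matrix
ellipse_idx <- function(n, m, cy, cx, ry, rx, theta = 0) {
  r_ext <- ceiling(max(ry, rx))
  r0 <- max(1L, as.integer(floor(cy - r_ext)))
  r1 <- min(n, as.integer(ceiling(cy + r_ext)))
  c0 <- max(1L, as.integer(floor(cx - r_ext)))
  c1 <- min(m, as.integer(ceiling(cx + r_ext)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  yy <- rows - cy; xx <- cols - cx
  u <- outer(sin(theta) * yy, cos(theta) * xx, "+")
  v <- outer(cos(theta) * yy, -sin(theta) * xx, "+")
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  lin <- (rep(cols, each = length(rows)) - 1L) * n + rep(rows, length(cols))
  lin[as.vector(inside)]
}

#' Generate one synthetic H&E ROI with ground truth
#'
#' Renders a single ROI of the requested class at scan resolution and
#' returns both the RGB image and the ground-truth component masks.
#' Rendering is forward Beer–Lambert with the pipeline's stain matrix;
#' red-blood-cell blobs are painted in blood-red RGB on top; Gaussian
#' transmittance noise is added last.
#'
#' @param class_label `"benign"`, `"low"` or `"high"`.
#' @param params a [synth_params()].
#' @param config a [pipeline_config()]; fixes ROI size, resolution and
#'   stain matrix.
#' @param brightness per-slide stain multiplier.
#' @param size_px optional override of the square side in pixels.
#' @return list with `rgb` (array in [0, 1]), logical masks `nuclei`,
#'   `lumina`, `rbc`, and `class`.
#' @export
generate_roi <- function(class_label = c("benign", "low", "high"),
                         params = synth_params(),
                         config = pipeline_config(),
                         brightness = 1,
                         size_px = roi_side_px(config)) {
  class_label <- match.arg(class_label)
  px <- config$pixel_size_um
  n <- as.integer(size_px)
  area_mm2 <- (n * px / 1000)^2
  nuclei <- lumina <- rbc <- matrix(FALSE, n, n)
  nr_mu <- params$nucleus_radius_um[["mean"]] / px
  nr_sd <- params$nucleus_radius_um[["sd"]] / px

  # glands: open lumina ringed by nuclei
  n_gland <- stats::rpois(1, params$gland_density[[class_label]] * area_mm2)
  placed <- 0L; tries <- 0L
  while (placed < n_gland && tries < n_gland * 20L) {
    tries <- tries + 1L
    lr <- params$lumen_radius_um[[class_label]] / px * stats::runif(1, 0.7, 1.3)
    cy <- stats::runif(1, 1, n); cx <- stats::runif(1, 1, n)
    # low-grade glands stay separate (open round glands); high-grade may fuse
    if (class_label != "high" && lumina[pmin(n, pmax(1, round(cy))),
                                        pmin(n, pmax(1, round(cx)))]) next
    lumina[ellipse_idx(n, n, cy, cx, lr, lr * stats::runif(1, 0.75, 1),
                       stats::runif(1, 0, pi))] <- TRUE
    ring_r <- lr + nr_mu * 1.2
    k <- max(3L, floor(2 * pi * ring_r * px / params$ring_spacing_um))
    ang <- seq(0, 2 * pi, length.out = k + 1L)[-1] + stats::runif(1, 0, 2 * pi)
    for (a in ang) {
      nuclei[ellipse_idx(n, n, cy + ring_r * sin(a), cx + ring_r * cos(a),
                         max(1, stats::rnorm(1, nr_mu, nr_sd)),
                         max(1, stats::rnorm(1, nr_mu * 0.8, nr_sd)),
                         stats::runif(1, 0, pi))] <- TRUE
    }
    placed <- placed + 1L
  }
  if (n_gland > 0 && placed == 0L) {
    stop("gland placement failed after bounded retries; lower gland_density",
         call. = FALSE)
  }

  # scattered nuclei (crowded in high-grade tissue)
  n_nuc <- stats::rpois(1, params$nucleus_density[[class_label]] * area_mm2)
  if (n_nuc > 0) {
    cys <- stats::runif(n_nuc, 1, n); cxs <- stats::runif(n_nuc, 1, n)
    keep <- !lumina[cbind(round(cys), round(cxs))]   # not inside a lumen
    for (i in which(keep)) {
      nuclei[ellipse_idx(n, n, cys[i], cxs[i],
                         max(1, stats::rnorm(1, nr_mu, nr_sd)),
                         max(1, stats::rnorm(1, nr_mu * 0.8, nr_sd)),
                         stats::runif(1, 0, pi))] <- TRUE
    }
  }

  # red-blood-cell blobs
  n_rbc <- stats::rpois(1, params$rbc_density * area_mm2)
  for (i in seq_len(n_rbc)) {
    rbc[ellipse_idx(n, n, stats::runif(1, 1, n), stats::runif(1, 1, n),
                    params$rbc_radius_um / px * stats::runif(1, 0.8, 1.4),
                    params$rbc_radius_um / px * stats::runif(1, 0.8, 1.4))] <- TRUE
  }
  lumina <- lumina & !nuclei        # nuclei sit on top of gland boundaries
  nuclei_vis <- nuclei & !rbc       # blood covers what it overlaps
  lumina_vis <- lumina & !rbc

  # compartments are constant in stain concentration, so the Beer–Lambert
  # transmittance is computed once per compartment and painted by index
  so <- params$stain_od
  comp_rgb <- function(conc) {
    as.numeric(exp(-log(10) * (c(conc[["h"]], conc[["e"]], 0) * brightness) %*%
                     config$stain_matrix))
  }
  col_stroma <- comp_rgb(so$stroma)
  col_lumen <- comp_rgb(so$lumen)
  col_nuclei <- comp_rgb(so$nuclei)
  col_rbc <- as.numeric(grDevices::col2rgb(grDevices::hsv(
    params$rbc_hsv[["h"]], params$rbc_hsv[["s"]], params$rbc_hsv[["v"]]))) / 255
  rgb <- array(0, c(n, n, 3L))
  for (k in 1:3) {
    ch <- matrix(col_stroma[k], n, n)
    ch[lumina_vis] <- col_lumen[k]
    ch[nuclei_vis] <- col_nuclei[k]
    ch[rbc] <- col_rbc[k]
    rgb[, , k] <- ch
  }
  if (params$noise_sd > 0) {
    rgb <- rgb + stats::rnorm(length(rgb), 0, params$noise_sd)
    rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  }
  list(rgb = rgb, nuclei = nuclei, lumina = lumina, rbc = rbc,
       class = class_label)
}

synth_class_codes <- c(benign = 12L, low = 1L, high = 4L)

#' Generate a synthetic cohort plan
#'
#' Lays out a seeded cohort of patients and slides: each patient draws a
#' stain brightness multiplier (so slides differ in stain intensity and the
#' per-slide adaptive threshold has work to do), each slide is a mosaic of
#' `tiles x tiles` ROIs whose classes are drawn from `class_mix`, and every
#' tile gets its own sub-seed. Slides are materialized lazily with
#' [build_slide()], so planning a large cohort is cheap; the truth table
#' lists every tile's class up front.
#'
#' @param n_patients number of patients (>= 2).
#' @param slides_per_patient slides per patient.
#' @param tiles tiles per slide side (slides are `tiles x tiles` ROIs).
#' @param params a [synth_params()].
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @return object of class `synth_cohort`: list with `truth` (one row per
#'   tile: patient_id, slide_id, tile_row, tile_col, class, code,
#'   brightness, roi_seed), `params`, `config`, `tiles`, `seed`.
#' @export
generate_cohort <- function(n_patients = 20, slides_per_patient = 2,
                            tiles = 4, params = synth_params(),
                            config = pipeline_config(), seed = config$rng_seed) {
  stopifnot(n_patients >= 2, slides_per_patient >= 1, tiles >= 1)
  set.seed(seed)
  pats <- sprintf("P%03d", seq_len(n_patients))
  bright <- stats::runif(n_patients, params$brightness_range[1],
                         params$brightness_range[2])
  rows <- expand.grid(tile_col = seq_len(tiles) - 1L,
                      tile_row = seq_len(tiles) - 1L,
                      slide = seq_len(slides_per_patient),
                      patient = seq_len(n_patients))[, 4:1]
  n <- nrow(rows)
  cls <- sample(names(params$class_mix), n, replace = TRUE,
                prob = params$class_mix)
  truth <- data.frame(
    patient_id = pats[rows$patient],
    slide_id = sprintf("%s_S%d", pats[rows$patient], rows$slide),
    tile_row = rows$tile_row, tile_col = rows$tile_col,
    class = cls, code = unname(synth_class_codes[cls]),
    brightness = bright[rows$patient],
    roi_seed = sample.int(.Machine$integer.max - 1L, n),
    stringsAsFactors = FALSE
  )
  structure(list(truth = truth, params = params, config = config,
                 tiles = as.integer(tiles), seed = as.integer(seed)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d patients, %d slides, %d ROIs (%dx%d tiles/slide)\n",
              length(unique(x$truth$patient_id)),
              length(unique(x$truth$slide_id)), nrow(x$truth),
              x$tiles, x$tiles))
  print(table(x$truth$class))
  invisible(x)
}

#' Materialize one slide of a synthetic cohort
#'
#' Renders the slide's tile mosaic at scan resolution from the cohort plan's
#' per-tile seeds (bit-reproducible for a given cohort) together with its
#' annotation mask, which codes each tile with the tissue class it was
#' generated from (G3 for low-grade, G4 for high-grade, Healthy/BPH for
#' benign).
#'
#' @param cohort a `synth_cohort`.
#' @param slide_id one of `cohort$truth$slide_id`.
#' @return list with `rgb` (slide array), `mask` (integer annotation
#'   matrix) and `truth` (the slide's truth-table rows).
#' @export
build_slide <- function(cohort, slide_id) {
  tt <- cohort$truth[cohort$truth$slide_id == slide_id, , drop = FALSE]
  if (!nrow(tt)) stop("unknown slide_id: ", slide_id, call. = FALSE)
  side <- roi_side_px(cohort$config)
  n <- cohort$tiles * side
  rgb <- array(0, c(n, n, 3L))
  mask <- matrix(0L, n, n)
  for (i in seq_len(nrow(tt))) {
    set.seed(tt$roi_seed[i])
    roi <- generate_roi(tt$class[i], cohort$params, cohort$config,
                        brightness = tt$brightness[i])
    rr <- tt$tile_row[i] * side + seq_len(side)
    cc <- tt$tile_col[i] * side + seq_len(side)
    rgb[rr, cc, ] <- roi$rgb
    mask[rr, cc] <- tt$code[i]
  }
  list(rgb = rgb, mask = mask, truth = tt)
}
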