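#' Nearest-neighbor downsampling
#'
#' Decimates a matrix or RGB array by the given ratio using the standard
#' nearest-neighbor mapping: output pixel `i` reads source pixel
#' `floor((i - 0.5) / ratio) + 1`. For ratio 0.25 this keeps every fourth
#' pixel, so label masks decimated with the same call stay aligned with
#' decimated images bit-for-bit.
#'
#' @param img matrix or `h x w x 3` array.
#' @param ratio resize factor in (0, 1].
#' @return the decimated matrix/array.
#' @export
downsample_nn <- function(img, ratio) {
  stopifnot(ratio > 0, ratio <= 1)
  if (ratio == 1) return(img)
  d <- dim(img)
  nn_idx <- function(n) {
    n_out <- max(1L, as.integer(floor(n * ratio)))
    pmin(n, as.integer(floor((seq_len(n_out) - 0.5) / ratio)) + 1L)
  }
  ri <- nn_idx(d[1]); ci <- nn_idx(d[2])
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

#' Hue/saturation/value decomposition of an RGB image
#'
#' Wraps [grDevices::rgb2hsv()]: hue in [0, 1], saturation `(max - min)/max`,
#' value `max`. This is the color model under which the red-blood-cell
#' thresholds delimit a non-empty, blood-red region of RGB space.
#'
#' @param rgb RGB array `h x w x 3` in [0, 1].
#' @return list of matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv_img <- function(rgb) {
  check_rgb(rgb)
  d <- dim(rgb)
  hsv <- grDevices::rgb2hsv(t(matrix(rgb, ncol = 3L)), maxColorValue = 1)
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# disk structuring element: pixels whose center distance <= radius
disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  if (r < 1L) return(matrix(1, 1, 1))
  g <- seq(-r, r)
  outer(g, g, function(y, x) as.numeric(x^2 + y^2 <= r^2 + 1e-9))
}

#' Detect red-blood-cell pixels
#'
#' RBCs take up hematoxylin and would otherwise be segmented as nuclei, but
#' are far redder. Seed pixels satisfy all three hue/saturation/value lower
#' bounds (`config$rbc_hsi_min`, defaults 0.95/0.72/0.60); the seed mask is
#' then dilated with a disk of radius `rbc_dilate_radius_um` (default 4 um,
#' the approximate radius of a human erythrocyte) converted to pixels at the
#' working resolution.
#'
#' @param rgb_image RGB array in [0, 1] at resolution `pixel_size_um`.
#' @param config a [pipeline_config()].
#' @param pixel_size_um resolution of `rgb_image`; defaults to the effective
#'   (downsampled) pipeline resolution.
#' @return logical matrix marking RBC pixels.
#' @export
detect_rbc <- function(rgb_image, config = pipeline_config(),
                       pixel_size_um = effective_pixel_size(config)) {
  hsv <- rgb_to_hsv_img(rgb_image)
  b <- config$rbc_hsi_min
  seeds <- hsv$h >= b[1] & hsv$s >= b[2] & hsv$v >= b[3]
  r <- um_to_px(config$rbc_dilate_radius_um, pixel_size_um)
  if (r < 1L || !any(seeds)) return(seeds)
  dil <- EBImage::dilate(EBImage::Image(seeds * 1), disk_kernel(r))
  matrix(as.numeric(dil) > 0.5, nrow(seeds), ncol(seeds))
}

#' Segment gland lumina by global RGB thresholds
#'
#' A pixel is luminal iff red >= 0.86, green >= 0.71 and blue >= 0.82
#' (configurable via `config$lumen_rgb_min`); lumina are the near-white open
#' gland interiors.
#'
#' @param rgb_image RGB array in [0, 1].
#' @param config a [pipeline_config()].
#' @return logical matrix marking lumen pixels.
#' @export
segment_lumina <- function(rgb_image, config = pipeline_config()) {
  check_rgb(rgb_image)
  b <- config$lumen_rgb_min
  d <- dim(rgb_image)
  ch <- function(k) matrix(rgb_image[, , k], d[1], d[2])
  ch(1) >= b[1] & ch(2) >= b[2] & ch(3) >= b[3]
}

#' Sample tuning tiles from a slide
#'
#' Draws up to `tuning_tile_count` square tiles (side `tuning_tile_um`)
#' uniformly at random from a slide, keeping only tiles that look like
#' tissue (mean RGB below `tissue_bg_cutoff`) and, when the dye filter is
#' configured, tiles without marking-dye color. These tiles feed the
#' per-slide adaptive nucleus threshold.
#'
#' @param slide_image RGB array at resolution `pixel_size_um`.
#' @param config a [pipeline_config()].
#' @param pixel_size_um resolution of `slide_image` (defaults to the
#'   effective working resolution).
#' @return list of RGB tile arrays; attribute `origins` holds the 0-based
#'   (row, col) top-left corner of each tile.
#' @export
sample_tuning_tiles <- function(slide_image, config = pipeline_config(),
                                pixel_size_um = effective_pixel_size(config)) {
  check_rgb(slide_image)
  side <- um_to_px(config$tuning_tile_um, pixel_size_um)
  d <- dim(slide_image)
  if (d[1] < side || d[2] < side) {
    stop(sprintf("slide (%d x %d) smaller than one %d px tuning tile",
                 d[1], d[2], side), call. = FALSE)
  }
  want <- config$tuning_tile_count
  tiles <- vector("list", want)
  origins <- matrix(NA_integer_, want, 2L)
  got <- 0L
  tried <- 0L
  cap <- max(want * 50L, 1000L)
  while (got < want && tried < cap) {
    batch <- min(max(want - got, 64L) * 2L, cap - tried)
    rs <- sample.int(d[1] - side + 1L, batch, replace = TRUE)
    cs <- sample.int(d[2] - side + 1L, batch, replace = TRUE)
    tried <- tried + batch
    for (k in seq_len(batch)) {
      tile <- slide_image[rs[k]:(rs[k] + side - 1L), cs[k]:(cs[k] + side - 1L), , drop = FALSE]
      if (mean(tile) >= config$tissue_bg_cutoff) next
      if (!is.null(config$dye_hsv_band) && dye_fraction(tile, config$dye_hsv_band) >
          config$dye_hsv_band$cap) next
      got <- got + 1L
      tiles[[got]] <- tile
      origins[got, ] <- c(rs[k] - 1L, cs[k] - 1L)
      if (got == want) break
    }
  }
  if (got == 0L) {
    stop("no tuning tile passed the tissue/dye filters; ",
         "relax `tissue_bg_cutoff` or the dye band", call. = FALSE)
  }
  tiles <- tiles[seq_len(got)]
  attr(tiles, "origins") <- origins[seq_len(got), , drop = FALSE]
  tiles
}

dye_fraction <- function(tile, band) {
  hsv <- rgb_to_hsv_img(tile)
  mean(hsv$h >= band$h[1] & hsv$h <= band$h[2] & hsv$s >= band$s_min)
}

# Otsu threshold of a pooled 256-bin histogram spanning the observed range.
# The between-class variance is flat across empty histogram gaps; tied
# maximizing cuts are averaged, placing the threshold mid-gap. Bins track the
# data range, so the threshold is scale-equivariant.
pooled_otsu <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (!all(is.finite(rng)) || diff(rng) <= 0) {
    stop("degenerate slide: pooled hematoxylin histogram is constant",
         call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(values, edges, all.inside = TRUE), 1L),
                          n_bins), n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf
  sigma_b <- sigma_b[-n_bins]
  ks <- which(sigma_b == max(sigma_b))
  mean(edges[ks + 1L])
}

#' Slide-adaptive nucleus threshold
#'
#' Pools the deconvolved hematoxylin values of all tuning tiles into a single
#' 256-bin histogram and returns its Otsu threshold. Computing the threshold
#' per slide, from tiles spread across the whole section, compensates for
#' stain-intensity variability between slides that defeats any global
#' threshold.
#'
#' @param tiles list of RGB tile arrays from [sample_tuning_tiles()].
#' @param config a [pipeline_config()].
#' @return scalar threshold on the hematoxylin optical-density channel.
#' @export
adaptive_nucleus_threshold <- function(tiles, config = pipeline_config()) {
  if (!length(tiles)) stop("need at least one tuning tile", call. = FALSE)
  # pool all tile pixels and unmix once; only the hematoxylin column is needed
  flat <- do.call(rbind, lapply(tiles, function(t) matrix(t, ncol = 3L)))
  od <- -log10((flat + config$od_eps) / (1 + config$od_eps))
  od[od < 0] <- 0
  pooled <- as.numeric(od %*% solve(config$stain_matrix)[, 1L])
  pooled[pooled < 0] <- 0
  pooled_otsu(pooled)
}

#' Threshold the hematoxylin channel into a nuclei map
#'
#' A pixel is nuclear iff its hematoxylin optical density reaches the
#' slide-adaptive threshold and it is not inside the red-blood-cell mask.
#'
#' @param hematoxylin scalar matrix (from [color_deconvolve()]).
#' @param threshold slide threshold from [adaptive_nucleus_threshold()].
#' @param rbc_mask logical matrix of RBC pixels, same shape.
#' @return logical matrix marking nucleus pixels.
#' @export
segment_nuclei <- function(hematoxylin, threshold, rbc_mask) {
  if (!identical(dim(hematoxylin), dim(rbc_mask))) {
    stop("hematoxylin and RBC mask shapes differ", call. = FALSE)
  }
  hematoxylin >= threshold & !rbc_mask
}

#' Build the three-class tissue-component map of an ROI
#'
#' Downsamples the ROI (nearest neighbor, `downsample_ratio`), then runs
#' color deconvolution, RBC detection, lumen thresholding and nucleus
#' segmentation at the working resolution, and combines them into one label
#' image: 1 = nuclei, 2 = lumina, 3 = other. Nuclei take precedence over
#' lumina on the rare overlapping pixel.
#'
#' @param rgb_roi RGB array at scan resolution.
#' @param slide_threshold hematoxylin threshold of the ROI's parent slide.
#' @param config a [pipeline_config()].
#' @return object of class `tcm`: list with integer matrix `labels` and
#'   `pixel_size_um` (effective resolution).
#' @export
build_tcm <- function(rgb_roi, slide_threshold, config = pipeline_config()) {
  check_rgb(rgb_roi)
  small <- downsample_nn(rgb_roi, config$downsample_ratio)
  eff <- effective_pixel_size(config)
  stains <- color_deconvolve(small, config)
  rbc <- detect_rbc(small, config, pixel_size_um = eff)
  nuclei <- segment_nuclei(stains$hematoxylin, slide_threshold, rbc)
  lumina <- segment_lumina(small, config)
  labels <- matrix(3L, nrow(nuclei), ncol(nuclei))
  labels[lumina] <- 2L
  labels[nuclei] <- 1L          # nuclei win over lumina
  new_tcm(labels, eff)
}

#' Construct a tissue-component map object
#' @param labels integer matrix with values in {1, 2, 3}.
#' @param pixel_size_um effective resolution of the map.
#' @return object of class `tcm`.
#' @export
new_tcm <- function(labels, pixel_size_um = 2) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% 1:3)) stop("TCM labels must be in {1, 2, 3}", call. = FALSE)
  structure(list(labels = labels, pixel_size_um = pixel_size_um), class = "tcm")
}

#' @export
print.tcm <- function(x, ...) {
  f <- tabulate(x$labels, 3L) / length(x$labels)
  cat(sprintf("<tcm %d x %d @ %.3g um/px> nuclei %.1f%%, lumina %.1f%%, other %.1f%%\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              100 * f[1], 100 * f[2], 100 * f[3]))
  invisible(x)
}

#' Render a TCM as an RGB image
#'
#' Nuclei red, lumina blue, other green — the conventional coloring for
#' these maps.
#' @param tcm a `tcm` object.
#' @return RGB array.
#' @export
tcm_to_rgb <- function(tcm) {
  lab <- tcm$labels
  out <- array(0, c(nrow(lab), ncol(lab), 3L))
  out[, , 1][lab == 1L] <- 1
  out[, , 3][lab == 2L] <- 1
  out[, , 2][lab == 3L] <- 1
  out
}
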