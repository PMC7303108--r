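#' Convert transmittance RGB to optical density
#'
#' Beer–Lambert absorbance per channel: `-log10((v + eps) / (1 + eps))`.
#' The floor `eps` keeps saturated black pixels finite; white (1,1,1) maps
#' exactly to zero optical density.
#'
#' @param rgb numeric array `h x w x 3` in [0, 1].
#' @param eps transmittance floor.
#' @return array of the same shape, non-negative.
#' @export
rgb_to_od <- function(rgb, eps = 1 / 256) {
  check_rgb(rgb)
  od <- -log10((rgb + eps) / (1 + eps))
  od[od < 0] <- 0
  od
}

#' Unmix an H&E image into per-stain optical-density channels
#'
#' Color deconvolution after Ruifrok and Johnston: the RGB image is converted
#' to optical density and multiplied by the inverse of the row-normalized
#' stain matrix, yielding one scalar image per stain. Negative unmixed
#' contributions (noise outside the stain simplex) are clamped to zero.
#'
#' @param rgb_image numeric array `h x w x 3` in [0, 1].
#' @param config a [pipeline_config()]; supplies `stain_matrix` and `od_eps`.
#' @return list of class `stain_channels` with matrices `hematoxylin`,
#'   `eosin`, `residual`, each the spatial size of the input.
#' @export
color_deconvolve <- function(rgb_image, config = pipeline_config()) {
  check_rgb(rgb_image)
  m <- config$stain_matrix
  od <- rgb_to_od(rgb_image, config$od_eps)
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)           # pixels x RGB
  conc <- flat %*% solve(m)               # pixels x stains
  conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[, k], d[1], d[2]))
  names(out) <- rownames(m)
  structure(out, class = "stain_channels")
}

#' Render stain concentrations to transmittance RGB
#'
#' Forward Beer–Lambert model, the exact inverse of [color_deconvolve()]
#' (up to the optical-density floor): transmittance `10^-(C %*% M)` for
#' concentration images `C` and stain matrix `M`. Used by the synthetic
#' generator so that deconvolution has an analytic round trip.
#'
#' @param concentrations list or array of per-stain concentration matrices in
#'   optical-density units, ordered hematoxylin, eosin, residual.
#' @param config a [pipeline_config()].
#' @return RGB array `h x w x 3` in [0, 1].
#' @export
stains_to_rgb <- function(concentrations, config = pipeline_config()) {
  if (is.list(concentrations)) {
    d <- dim(concentrations[[1]])
    conc <- vapply(concentrations, as.numeric, numeric(prod(d)))
  } else {
    d <- dim(concentrations)[1:2]
    conc <- matrix(concentrations, ncol = 3L)
  }
  od <- conc %*% config$stain_matrix
  rgb <- exp(-log(10) * od)
  rgb[rgb > 1] <- 1
  dim(rgb) <- c(d[1], d[2], 3L)
  rgb
}

check_rgb <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("expected an RGB array of shape h x w x 3", call. = FALSE)
  }
  if (dim(x)[1] < 1L || dim(x)[2] < 1L) stop("empty image", call. = FALSE)
  if (!is.numeric(x) || any(x < -1e-9) || any(x > 1 + 1e-9)) {
    stop("RGB values must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
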