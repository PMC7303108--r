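#' Co-occurrence and run-length direction offsets
#'
#' The four direction offsets, in (row, col) convention with row 1 at the
#' top: d1 = (0,1) east, d2 = (-1,1) north-east, d3 = (-1,0) north,
#' d4 = (-1,-1) north-west. Texture matrices are computed per direction
#' without aggregation across directions.
#'
#' @return list of length-2 integer vectors named `d1`..`d4`.
#' @export
texture_directions <- function() {
  list(d1 = c(0L, 1L), d2 = c(-1L, 1L), d3 = c(-1L, 0L), d4 = c(-1L, -1L))
}

match_direction <- function(direction) {
  dirs <- texture_directions()
  for (nm in names(dirs)) {
    if (identical(as.integer(direction), dirs[[nm]])) return(nm)
  }
  stop("direction must be one of (0,1), (-1,1), (-1,0), (-1,-1)", call. = FALSE)
}

tcm_labels <- function(x) {
  if (inherits(x, "tcm")) x$labels else matrix(as.integer(x), nrow(x), ncol(x))
}

#' Grey-level co-occurrence matrix of a tissue-component map
#'
#' Counts ordered pairs of labels at pixel `p` and `p + direction * distance`
#' over all in-bounds `p`, accumulates symmetrically (each pair also counted
#' in the transposed cell), and normalizes to probabilities. Levels are the
#' three TCM codes directly.
#'
#' @param tcm a `tcm` object or integer label matrix (values 1..3).
#' @param direction length-2 offset, one of [texture_directions()].
#' @param distance neighbor distance in pixels (>= 1).
#' @return 3x3 probability matrix of class `cooc_matrix`; attributes
#'   `direction` and `distance`.
#' @export
glcm <- function(tcm, direction = c(0L, 1L), distance = 1L) {
  lab <- tcm_labels(tcm)
  match_direction(direction)
  stopifnot(distance >= 1L)
  dr <- as.integer(direction[1]) * distance
  dc <- as.integer(direction[2]) * distance
  n <- nrow(lab); m <- ncol(lab)
  r0 <- max(1L, 1L - dr):min(n, n - dr)
  c0 <- max(1L, 1L - dc):min(m, m - dc)
  counts <- matrix(0, 3L, 3L)
  if (n >= abs(dr) + 1L && m >= abs(dc) + 1L) {
    a <- lab[r0, c0, drop = FALSE]
    b <- lab[r0 + dr, c0 + dc, drop = FALSE]
    counts <- matrix(tabulate((a - 1L) * 3L + b, 9L), 3L, 3L, byrow = TRUE)
  } else {
    warning("image smaller than the co-occurrence offset; empty matrix")
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot > 0) counts <- counts / tot
  structure(counts, class = c("cooc_matrix", "matrix"),
            direction = as.integer(direction), distance = as.integer(distance))
}

#' The 22 co-occurrence statistics
#'
#' Computes the widely used 22-statistic set (Haralick's original measures
#' plus the Soh–Tsatsoulis and Clausi additions) from a normalized symmetric
#' co-occurrence matrix, in the fixed order: autocorrelation, contrast,
#' correlation (moment form), correlation (deviation form), cluster
#' prominence, cluster shade, dissimilarity, energy, entropy, homogeneity
#' (|i-j| form), homogeneity (inverse difference moment), maximum
#' probability, sum of squares variance, sum average, sum variance, sum
#' entropy, difference variance, difference entropy, information measure of
#' correlation 1 and 2, inverse difference normalized, inverse difference
#' moment normalized. Entropies use the natural logarithm. Statistics that
#' are undefined on a degenerate matrix (zero marginal variance) are mapped
#' to 0.
#'
#' @param m a normalized co-occurrence matrix (from [glcm()]).
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(m) {
  p <- unclass(m)
  ng <- nrow(p)
  if (sum(p) <= 0) {
    warning("all-zero co-occurrence matrix; features set to 0")
    return(stats::setNames(numeric(22L), glcm_feature_names()))
  }
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  # sum (k = i + j in 2..2ng) and difference (k = |i - j| in 0..ng-1) distributions
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  safe_div <- function(num, den) if (abs(den) < 1e-12) 0 else num / den
  sum_avg <- sum((2:(2 * ng)) * pxy_sum)
  sum_ent <- ent(pxy_sum)
  dif_avg <- sum((0:(ng - 1)) * pxy_dif)
  hxy <- ent(p)
  # cross entropies against the independence model, for the information
  # measures of correlation
  q1 <- outer(px, py)
  ok <- p > 0 & q1 > 0
  hxy1 <- -sum(p[ok] * log(q1[ok]))
  ok2 <- q1 > 0
  hxy2 <- -sum(q1[ok2] * log(q1[ok2]))
  hx <- ent(px); hy <- ent(py)
  imc1 <- safe_div(hxy - hxy1, max(hx, hy))
  imc2_arg <- 1 - exp(-2 * (hxy2 - hxy))
  imc2 <- sqrt(max(0, imc2_arg))
  out <- c(
    autocorrelation = sum(i * j * p),
    contrast = sum((i - j)^2 * p),
    correlation_m = safe_div(sum(i * j * p) - mu_x * mu_y, sd_x * sd_y),
    correlation_d = safe_div(sum((i - mu_x) * (j - mu_y) * p), sd_x * sd_y),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    entropy = hxy,
    homogeneity_a = sum(p / (1 + abs(i - j))),
    homogeneity_m = sum(p / (1 + (i - j)^2)),
    max_probability = max(p),
    variance_ss = sum((i - mu_x)^2 * p),
    sum_average = sum_avg,
    sum_variance = sum(((2:(2 * ng)) - sum_avg)^2 * pxy_sum),
    sum_entropy = sum_ent,
    difference_variance = sum(((0:(ng - 1)) - dif_avg)^2 * pxy_dif),
    difference_entropy = ent(pxy_dif),
    imc1 = imc1,
    imc2 = imc2,
    inverse_diff_norm = sum(p / (1 + abs(i - j) / ng)),
    inverse_diff_moment_norm = sum(p / (1 + (i - j)^2 / ng^2))
  )
  out
}

glcm_feature_names <- function() {
  c("autocorrelation", "contrast", "correlation_m", "correlation_d",
    "cluster_prominence", "cluster_shade", "dissimilarity", "energy",
    "entropy", "homogeneity_a", "homogeneity_m", "max_probability",
    "variance_ss", "sum_average", "sum_variance", "sum_entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2",
    "inverse_diff_norm", "inverse_diff_moment_norm")
}

#' Grey-level run-length matrix of a tissue-component map
#'
#' Counts maximal constant-label runs along the scan lines of one direction:
#' rows for (0,1), columns for (-1,0), anti-diagonals for (-1,1), main
#' diagonals for (-1,-1). Every pixel belongs to exactly one run per
#' direction.
#'
#' @param tcm a `tcm` object or integer label matrix (values 1..3).
#' @param direction length-2 offset, one of [texture_directions()].
#' @return matrix `levels x max run length` of run counts, class
#'   `runlength_matrix`, attribute `n_pixels`.
#' @export
glrlm <- function(tcm, direction = c(0L, 1L)) {
  lab <- tcm_labels(tcm)
  nm <- match_direction(direction)
  n <- nrow(lab); m <- ncol(lab)
  # serialize the map into scan-line traversal order plus a line id, then
  # find run boundaries in one vectorized pass
  if (nm == "d1") {
    v <- as.integer(t(lab)); line <- rep.int(seq_len(n), rep(m, n))
  } else if (nm == "d3") {
    v <- as.integer(lab); line <- rep.int(seq_len(m), rep(n, m))
  } else {
    key <- if (nm == "d2") row(lab) + col(lab) else row(lab) - col(lab)
    ord <- order(key, col(lab), method = "radix")
    v <- as.integer(lab)[ord]; line <- as.integer(key)[ord]
  }
  np <- length(v)
  new_run <- c(TRUE, v[-1L] != v[-np] | line[-1L] != line[-np])
  starts <- which(new_run)
  lens <- diff(c(starts, np + 1L))
  levs <- v[starts]
  max_len <- max(lens)
  counts <- matrix(tabulate((lens - 1L) * 3L + levs, 3L * max_len), 3L, max_len)
  structure(counts, class = c("runlength_matrix", "matrix"),
            direction = as.integer(direction), n_pixels = np)
}

#' The 11 run-length statistics
#'
#' Standard run-emphasis set, fixed order: SRE, LRE, GLN, RLN, RP, LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE (short/long-run emphasis, grey-level and
#' run-length non-uniformity, run percentage, low/high grey-level run
#' emphasis, and the four joint emphases).
#'
#' @param m run-length count matrix (from [glrlm()]).
#' @param n_pixels total pixel count of the source image; defaults to the
#'   matrix attribute.
#' @return named numeric vector of length 11.
#' @export
glrlm_features <- function(m, n_pixels = attr(m, "n_pixels")) {
  r <- unclass(m)
  nr <- sum(r)
  if (nr <= 0) stop("empty run-length matrix", call. = FALSE)
  if (is.null(n_pixels)) stop("n_pixels is required", call. = FALSE)
  g <- matrix(seq_len(nrow(r)), nrow(r), ncol(r))        # grey level
  l <- matrix(seq_len(ncol(r)), nrow(r), ncol(r), byrow = TRUE)  # run length
  c(sre = sum(r / l^2) / nr,
    lre = sum(r * l^2) / nr,
    gln = sum(rowSums(r)^2) / nr,
    rln = sum(colSums(r)^2) / nr,
    rp = nr / n_pixels,
    lgre = sum(r / g^2) / nr,
    hgre = sum(r * g^2) / nr,
    srlge = sum(r / (g^2 * l^2)) / nr,
    srhge = sum(r * g^2 / l^2) / nr,
    lrlge = sum(r * l^2 / g^2) / nr,
    lrhge = sum(r * l^2 * g^2) / nr)
}

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre", "srlge", "srhge",
    "lrlge", "lrhge")
}

#' The 24 first-order statistics
#'
#' Computes {mean, variance, skewness, kurtosis, energy, entropy} on each of
#' four derived images: the 3-level coded map itself and the three per-class
#' binary indicator maps (nuclei, lumina, other) — 6 x 4 = 24 values.
#' Variance is the population moment; skewness and kurtosis are the
#' standardized third and fourth moments (0 on a constant image); energy and
#' entropy are taken on the discrete value histogram, so a constant image
#' has energy 1 and entropy 0. Natural logarithm throughout.
#'
#' @param tcm a `tcm` object or integer label matrix (values 1..3).
#' @return named numeric vector of length 24.
#' @export
first_order_features <- function(tcm) {
  lab <- tcm_labels(tcm)
  if (!length(lab)) stop("empty map", call. = FALSE)
  frac <- tabulate(lab, 3L) / length(lab)
  out <- c(fo_stats(seq_len(3L), frac),                    # coded 3-level map
           fo_stats(c(0, 1), c(1 - frac[1], frac[1])),     # nuclei indicator
           fo_stats(c(0, 1), c(1 - frac[2], frac[2])),     # lumina indicator
           fo_stats(c(0, 1), c(1 - frac[3], frac[3])))     # other indicator
  names(out) <- as.vector(t(outer(c("coded", "nuclei", "lumina", "other"),
                                  c("mean", "variance", "skewness", "kurtosis",
                                    "energy", "entropy"), paste, sep = "_")))
  out
}

# moments and histogram statistics of a discrete image given its value
# distribution (values `v` with probabilities `p`)
fo_stats <- function(v, p) {
  mu <- sum(v * p)
  m2 <- sum((v - mu)^2 * p)
  m3 <- sum((v - mu)^3 * p)
  m4 <- sum((v - mu)^4 * p)
  q <- p[p > 0]
  c(mean = mu, variance = m2,
    skewness = if (m2 > 1e-12) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 1e-12) m4 / m2^2 else 0,
    energy = sum(q^2), entropy = -sum(q * log(q)))
}

#' Full 156-element texture descriptor of a tissue-component map
#'
#' Concatenates, in fixed order: the 24 first-order statistics, the 22
#' co-occurrence statistics for directions d1..d4 (88), and the 11
#' run-length statistics for directions d1..d4 (44) — 156 values total,
#' named `fo_*`, `glcm_d*_*` and `glrlm_d*_*`.
#'
#' @param tcm a `tcm` object or integer label matrix (values 1..3).
#' @return named numeric vector of length 156, all finite.
#' @export
feature_vector <- function(tcm) {
  lab <- tcm_labels(tcm)
  dirs <- texture_directions()
  fo <- first_order_features(lab)
  names(fo) <- paste0("fo_", names(fo))
  gl <- unlist(lapply(names(dirs), function(nm) {
    v <- glcm_features(glcm(lab, dirs[[nm]]))
    names(v) <- paste0("glcm_", nm, "_", names(v))
    v
  }))
  rl <- unlist(lapply(names(dirs), function(nm) {
    v <- glrlm_features(glrlm(lab, dirs[[nm]]))
    names(v) <- paste0("glrlm_", nm, "_", names(v))
    v
  }))
  out <- c(fo, gl, rl)
  stopifnot(length(out) == 156L)
  out
}

#' Names of the 156 features in canonical order
#' @return character vector of length 156.
#' @export
feature_names <- function() {
  dirs <- paste0("d", 1:4)
  c(paste0("fo_", as.vector(t(outer(c("coded", "nuclei", "lumina", "other"),
                                    c("mean", "variance", "skewness", "kurtosis",
                                      "energy", "entropy"), paste, sep = "_")))),
    as.vector(t(outer(dirs, glcm_feature_names(),
                      function(d, f) paste0("glcm_", d, "_", f)))),
    as.vector(t(outer(dirs, glrlm_feature_names(),
                      function(d, f) paste0("glrlm_", d, "_", f)))))
}
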