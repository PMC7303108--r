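# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementations.

# co-occurrence: double loop over every pixel pair at the offset, plus the
# transposed count, normalized
brute_glcm <- function(lab, offset, distance = 1L) {
  n <- nrow(lab); m <- ncol(lab)
  counts <- matrix(0, 3, 3)
  for (r in seq_len(n)) {
    for (c in seq_len(m)) {
      r2 <- r + offset[1] * distance
      c2 <- c + offset[2] * distance
      if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m) {
        a <- lab[r, c]; b <- lab[r2, c2]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# textbook GLCM statistics, recomputed with explicit element loops
brute_glcm_features <- function(p) {
  ng <- nrow(p)
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) for (j in 1:ng) { mu_x <- mu_x + i * p[i, j]; mu_y <- mu_y + j * p[i, j] }
  var_x <- 0; var_y <- 0
  for (i in 1:ng) for (j in 1:ng) {
    var_x <- var_x + (i - mu_x)^2 * p[i, j]
    var_y <- var_y + (j - mu_y)^2 * p[i, j]
  }
  sd_x <- sqrt(var_x); sd_y <- sqrt(var_y)
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  H <- function(q) { s <- 0; for (x in q) if (x > 0) s <- s - x * log(x); s }
  sdiv <- function(a, b) if (abs(b) < 1e-12) 0 else a / b
  acc <- ctr <- dis <- ene <- hom_a <- hom_m <- ssq <- idn <- idmn <- 0
  cp <- cs <- cor_num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    acc <- acc + i * j * v
    ctr <- ctr + (i - j)^2 * v
    dis <- dis + abs(i - j) * v
    ene <- ene + v^2
    hom_a <- hom_a + v / (1 + abs(i - j))
    hom_m <- hom_m + v / (1 + (i - j)^2)
    ssq <- ssq + (i - mu_x)^2 * v
    cp <- cp + (i + j - mu_x - mu_y)^4 * v
    cs <- cs + (i + j - mu_x - mu_y)^3 * v
    cor_num <- cor_num + (i - mu_x) * (j - mu_y) * v
    idn <- idn + v / (1 + abs(i - j) / ng)
    idmn <- idmn + v / (1 + (i - j)^2 / ng^2)
  }
  savg <- 0; for (k in 2:(2 * ng)) savg <- savg + k * psum[k]
  svar <- 0; for (k in 2:(2 * ng)) svar <- svar + (k - savg)^2 * psum[k]
  davg <- 0; for (k in 0:(ng - 1)) davg <- davg + k * pdif[k + 1]
  dvar <- 0; for (k in 0:(ng - 1)) dvar <- dvar + (k - davg)^2 * pdif[k + 1]
  px <- rowSums(p); py <- colSums(p)
  hxy <- H(p); hx <- H(px); hy <- H(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log(q)
      hxy2 <- hxy2 - q * log(q)
    }
  }
  c(autocorrelation = acc, contrast = ctr,
    correlation_m = sdiv(acc - mu_x * mu_y, sd_x * sd_y),
    correlation_d = sdiv(cor_num, sd_x * sd_y),
    cluster_prominence = cp, cluster_shade = cs, dissimilarity = dis,
    energy = ene, entropy = hxy, homogeneity_a = hom_a, homogeneity_m = hom_m,
    max_probability = max(p), variance_ss = ssq, sum_average = savg,
    sum_variance = svar, sum_entropy = H(psum), difference_variance = dvar,
    difference_entropy = H(pdif),
    imc1 = sdiv(hxy - hxy1, max(hx, hy)),
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    inverse_diff_norm = idn, inverse_diff_moment_norm = idmn)
}

# run-length matrix by explicit per-line scans
brute_glrlm <- function(lab, offset) {
  n <- nrow(lab); m <- ncol(lab)
  lines <- if (identical(offset, c(0L, 1L))) {
    lapply(seq_len(n), function(r) lab[r, ])
  } else if (identical(offset, c(-1L, 0L))) {
    lapply(seq_len(m), function(c) lab[, c])
  } else if (identical(offset, c(-1L, 1L))) {
    lapply(2:(n + m), function(s) {
      cs <- max(1, s - n):min(m, s - 1); lab[cbind(s - cs, cs)]
    })
  } else {
    lapply((1 - m):(n - 1), function(d) {
      cs <- max(1, 1 - d):min(m, n - d); lab[cbind(d + cs, cs)]
    })
  }
  max_len <- max(n, m)
  counts <- matrix(0, 3, max_len)
  for (ln in lines) {
    run_val <- ln[1]; run_len <- 1
    for (k in seq_along(ln)[-1]) {
      if (ln[k] == run_val) run_len <- run_len + 1
      else {
        counts[run_val, run_len] <- counts[run_val, run_len] + 1
        run_val <- ln[k]; run_len <- 1
      }
    }
    counts[run_val, run_len] <- counts[run_val, run_len] + 1
  }
  counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
}

brute_glrlm_features <- function(counts, n_pixels) {
  nr <- sum(counts)
  out <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = nr / n_pixels,
           lgre = 0, hgre = 0, srlge = 0, srhge = 0, lrlge = 0, lrhge = 0)
  for (g in seq_len(nrow(counts))) for (l in seq_len(ncol(counts))) {
    v <- counts[g, l]
    out["sre"] <- out["sre"] + v / l^2
    out["lre"] <- out["lre"] + v * l^2
    out["lgre"] <- out["lgre"] + v / g^2
    out["hgre"] <- out["hgre"] + v * g^2
    out["srlge"] <- out["srlge"] + v / (g^2 * l^2)
    out["srhge"] <- out["srhge"] + v * g^2 / l^2
    out["lrlge"] <- out["lrlge"] + v * l^2 / g^2
    out["lrhge"] <- out["lrhge"] + v * l^2 * g^2
  }
  for (g in seq_len(nrow(counts))) out["gln"] <- out["gln"] + sum(counts[g, ])^2
  for (l in seq_len(ncol(counts))) out["rln"] <- out["rln"] + sum(counts[, l])^2
  out[c("sre", "lre", "gln", "rln", "lgre", "hgre", "srlge", "srhge",
        "lrlge", "lrhge")] <-
    out[c("sre", "lre", "gln", "rln", "lgre", "hgre", "srlge", "srhge",
          "lrlge", "lrhge")] / nr
  out
}

# AUC as the pairwise concordance statistic with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

# Otsu by exhaustive search: for every histogram cut, compute the
# between-class variance directly from class moments
brute_otsu <- function(values, n_bins = 256L) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, all.inside = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  v <- rep(-Inf, n_bins - 1L)
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    v[k] <- n0 * n1 * (mu0 - mu1)^2
  }
  mean(edges[which(v == max(v)) + 1L])   # tied cuts average to mid-gap
}

# disk rasterization by scanning every pixel of the bounding square
brute_disk_mask <- function(n, m, cy, cx, r) {
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if ((i - cy)^2 + (j - cx)^2 <= r^2 + 1e-9) out[i, j] <- TRUE
  }
  out
}

# small working configuration: 60 um (120 px) ROIs keep image tests cheap
# while preserving the 0.5 um scan / 0.25 downsampling geometry
cfg_small <- function(...) {
  pipeline_config(roi_size_um = 60, tuning_tile_um = 15,
                  tuning_tile_count = 200, ...)
}

random_tcm <- function(n = 8, m = n, prob = c(1, 1, 1)) {
  new_tcm(matrix(sample(1:3, n * m, replace = TRUE, prob = prob), n, m))
}
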