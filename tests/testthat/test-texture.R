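test_that("co-occurrence probabilities match hand enumeration", {
  m <- glcm(matrix(c(1L, 2L, 1L, 3L), 2, 2), c(0L, 1L))   # rows [1,1],[2,3]
  expect_equal(m[1, 1], 0.5)
  expect_equal(m[2, 3], 0.25)
  expect_equal(m[3, 2], 0.25)
  expect_equal(sum(m), 1)
  # constant map concentrates all mass on the diagonal
  mc <- glcm(matrix(2L, 4, 4), c(-1L, 0L))
  expect_equal(mc[2, 2], 1)
  f <- glcm_features(mc)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation_m"]), 0)   # undefined -> 0 by the error rule
})

test_that("energy of the worked 3-level example is 0.375", {
  m <- glcm(matrix(c(1L, 2L, 1L, 3L), 2, 2), c(0L, 1L))
  expect_equal(unname(glcm_features(m)["energy"]), 0.5^2 + 0.25^2 + 0.25^2)
})

test_that("GLCM matrices and statistics equal brute force on random maps", {
  set.seed(201)
  dirs <- texture_directions()
  for (rep in 1:25) {
    n <- sample(c(8, 16), 1)
    lab <- matrix(sample(1:3, n * n, replace = TRUE), n, n)
    for (d in dirs) {
      got <- glcm(lab, d)
      expect_equal(unclass(got), brute_glcm(lab, d), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(glcm_features(got), brute_glcm_features(unclass(got)),
                   tolerance = 1e-10)
    }
  }
})

test_that("small images yield an all-zero co-occurrence matrix with warning", {
  expect_warning(m <- glcm(matrix(1L, 1, 1), c(-1L, 0L)), "smaller")
  expect_equal(sum(m), 0)
  expect_warning(f <- glcm_features(m), "all-zero")
  expect_true(all(f == 0))
})

test_that("run-length matrices follow hand examples and partition pixels", {
  m <- glrlm(matrix(c(1L, 1L, 1L, 2L), 1, 4), c(0L, 1L))
  expect_equal(m[1, 3], 1)
  expect_equal(m[2, 1], 1)
  expect_equal(sum(m), 2)
  mc <- glrlm(matrix(3L, 4, 4), c(0L, 1L))
  expect_equal(mc[3, 4], 4)                       # n runs of length n
  f <- glrlm_features(mc)
  expect_equal(unname(f["lre"]), 16)
  expect_equal(unname(f["rp"]), 0.25)
})

test_that("run-length statistics match direct formula evaluation", {
  counts <- matrix(0, 3, 3); counts[1, 3] <- 1; counts[2, 1] <- 1
  f <- glrlm_features(counts, n_pixels = 4)
  expect_equal(unname(f["sre"]), (1 / 9 + 1) / 2, tolerance = 1e-12)
  expect_equal(unname(f["rp"]), 0.5)
  expect_error(glrlm_features(matrix(0, 3, 2), 4), "empty")
})

test_that("GLRLM matrices and statistics equal brute force on random maps", {
  set.seed(202)
  dirs <- texture_directions()
  for (rep in 1:25) {
    n <- sample(c(8, 16), 1)
    lab <- matrix(sample(1:3, n * n, replace = TRUE), n, n)
    for (d in dirs) {
      got <- glrlm(lab, d)
      ref <- brute_glrlm(lab, d)
      expect_equal(unclass(got)[, seq_len(ncol(ref)), drop = FALSE], ref,
                   ignore_attr = TRUE)
      # run partition: lengths weighted by counts cover every pixel
      lens <- matrix(seq_len(ncol(got)), 3, ncol(got), byrow = TRUE)
      expect_equal(sum(unclass(got) * lens), n * n)
      expect_equal(glrlm_features(got),
                   brute_glrlm_features(ref, n * n), tolerance = 1e-10)
    }
  }
})

test_that("first-order block reports class fractions and degenerate moments", {
  f <- first_order_features(matrix(3L, 5, 5))     # all "other"
  expect_equal(unname(f["other_energy"]), 1)
  expect_equal(unname(f["other_entropy"]), 0)
  expect_equal(unname(f["coded_variance"]), 0)
  expect_equal(unname(f["coded_skewness"]), 0)
  lab <- matrix(c(rep(1L, 4), rep(2L, 4), rep(3L, 8)), 4, 4)
  f2 <- first_order_features(lab)
  expect_equal(unname(f2["nuclei_mean"]), 0.25)
  expect_equal(unname(f2["lumina_mean"]), 0.25)
  expect_equal(unname(f2["other_mean"]), 0.5)
  # balanced binary indicator is symmetric
  lab3 <- matrix(c(rep(1L, 8), rep(3L, 8)), 4, 4)
  expect_equal(unname(first_order_features(lab3)["nuclei_skewness"]), 0)
})

test_that("feature vector has the fixed 156-element schema", {
  set.seed(203)
  tcm <- random_tcm(24)
  fv <- feature_vector(tcm)
  expect_length(fv, 156L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv)[1:24], feature_names()[1:24])
  expect_match(names(fv)[25], "^glcm_d1_")
  expect_match(names(fv)[113], "^glrlm_d1_")
  # schema decomposition: 24 first-order + (22 + 11) x 4 directions
  expect_length(grep("^fo_", names(fv)), 24L)
  expect_length(grep("^glcm_", names(fv)), 88L)
  expect_length(grep("^glrlm_", names(fv)), 44L)
  for (d in paste0("d", 1:4)) {
    expect_length(grep(paste0("^glcm_", d, "_"), names(fv)), 22L)
    expect_length(grep(paste0("^glrlm_", d, "_"), names(fv)), 11L)
  }
})

test_that("all 156 features stay finite on degenerate single-class maps", {
  for (cls in 1:3) {
    fv <- suppressWarnings(feature_vector(matrix(cls, 12L, 12L)))
    expect_true(all(is.finite(fv)))
  }
})

test_that("swapping class codes permutes indicator blocks and GLCM cells", {
  set.seed(204)
  lab <- tcm_labels(random_tcm(10))
  swapped <- lab
  swapped[lab == 1L] <- 2L
  swapped[lab == 2L] <- 1L
  f1 <- first_order_features(lab)
  f2 <- first_order_features(swapped)
  expect_equal(unname(f2[grep("^lumina_", names(f2))]),
               unname(f1[grep("^nuclei_", names(f1))]))
  expect_equal(unname(f2[grep("^nuclei_", names(f2))]),
               unname(f1[grep("^lumina_", names(f1))]))
  perm <- c(2L, 1L, 3L)
  for (d in texture_directions()) {
    m1 <- unclass(glcm(lab, d))
    m2 <- unclass(glcm(swapped, d))
    expect_equal(m2, m1[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("translation within a constant border preserves co-occurrence", {
  set.seed(206)
  n <- 20L
  for (rep in 1:5) {
    pat <- matrix(sample(1:2, 36, TRUE), 6, 6)
    m1 <- matrix(3L, n, n); m1[6:11, 6:11] <- pat
    m2 <- matrix(3L, n, n); m2[8:13, 9:14] <- pat   # shifted, still interior
    for (d in texture_directions()) {
      expect_equal(unclass(glcm(m1, d)), unclass(glcm(m2, d)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    # content touching the image edge may differ, but only through pairs on
    # the perimeter of the moved content
    m3 <- matrix(3L, n, n); m3[1:6, 1:6] <- pat
    for (d in texture_directions()) {
      l1 <- sum(abs(unclass(glcm(m1, d)) - unclass(glcm(m3, d))))
      expect_lte(l1, 4 * 4 * 7 / (2 * (n - 1) * n))
    }
  }
})

test_that("180-degree rotation leaves each symmetric GLCM invariant", {
  set.seed(205)
  lab <- tcm_labels(random_tcm(12))
  rot <- lab[nrow(lab):1, ncol(lab):1]
  for (d in texture_directions()) {
    expect_equal(unclass(glcm(lab, d)), unclass(glcm(rot, d)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})
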