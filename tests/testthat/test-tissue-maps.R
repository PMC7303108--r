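test_that("pooled Otsu matches an exhaustive between-class-variance search", {
  set.seed(101)
  for (rep in 1:5) {
    vals <- c(rnorm(3000, 0.2, 0.02), rnorm(3000, 0.9, 0.02))
    tiles_thr <- histotcm:::pooled_otsu(vals)
    expect_equal(tiles_thr, brute_otsu(vals), tolerance = 1e-12)
    expect_gt(tiles_thr, 0.3)
    expect_lt(tiles_thr, 0.8)
  }
})

test_that("pooled Otsu is scale-equivariant and rejects constant input", {
  set.seed(102)
  vals <- c(rnorm(4000, 0.2, 0.02), rnorm(4000, 0.9, 0.02))
  expect_equal(histotcm:::pooled_otsu(vals * 1.3),
               1.3 * histotcm:::pooled_otsu(vals), tolerance = 1e-12)
  expect_error(histotcm:::pooled_otsu(rep(0.5, 100)), "constant")
})

test_that("adaptive threshold separates a bimodal hematoxylin mixture", {
  cfg <- cfg_small()
  set.seed(103)
  # tiles rendered from known concentrations: half dim stroma, half nuclei
  mk_tile <- function(h) stains_to_rgb(list(matrix(h, 10, 10),
                                            matrix(0, 10, 10),
                                            matrix(0, 10, 10)), cfg)
  tiles <- c(lapply(rnorm(30, 0.2, 0.02), mk_tile),
             lapply(rnorm(30, 0.9, 0.02), mk_tile))
  thr <- adaptive_nucleus_threshold(tiles, cfg)
  expect_gt(thr, 0.3); expect_lt(thr, 0.8)
  expect_error(adaptive_nucleus_threshold(tiles[1], cfg), "constant")
})

test_that("RBC seeds follow the HSV lower bounds", {
  cfg <- pipeline_config()
  mk <- function(h, s, v) {
    col <- as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
    array(rep(col, each = 1), c(1, 1, 3))
  }
  expect_true(detect_rbc(mk(0.97, 0.80, 0.65), cfg, pixel_size_um = 2)[1, 1])
  expect_false(detect_rbc(mk(0.50, 0.90, 0.90), cfg, pixel_size_um = 2)[1, 1])
  expect_false(detect_rbc(mk(0.97, 0.50, 0.90), cfg, pixel_size_um = 2)[1, 1])
  expect_false(detect_rbc(mk(0.97, 0.90, 0.30), cfg, pixel_size_um = 2)[1, 1])
})

test_that("RBC dilation is a rasterized disk of the configured radius", {
  cfg <- pipeline_config()  # 4 um at 2 um/px -> radius 2 px
  img <- array(1, c(11, 11, 3))
  col <- as.numeric(grDevices::col2rgb(grDevices::hsv(0.97, 0.85, 0.8))) / 255
  for (k in 1:3) img[6, 6, k] <- col[k]
  mask <- detect_rbc(img, cfg, pixel_size_um = 2)
  expect_equal(mask, brute_disk_mask(11, 11, 6, 6, 2))
  # at 1 um/px the same physical radius is 4 px
  mask4 <- detect_rbc(img, cfg, pixel_size_um = 1)
  expect_equal(mask4, brute_disk_mask(11, 11, 6, 6, 4))
})

test_that("lumen thresholding applies the three RGB lower bounds", {
  cfg <- pipeline_config()
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_true(segment_lumina(px(0.90, 0.75, 0.85), cfg)[1, 1])
  expect_false(segment_lumina(px(0.80, 0.95, 0.95), cfg)[1, 1])
  expect_true(all(segment_lumina(array(1, c(4, 4, 3)), cfg)))
})

test_that("nucleus map is hematoxylin >= threshold minus the RBC mask", {
  h <- matrix(c(0, 0.5, 0.9, 0.9), 2, 2)
  rbc <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(segment_nuclei(h, 0.6, rbc),
               matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
  expect_equal(sum(segment_nuclei(matrix(0, 3, 3), 0.5, matrix(FALSE, 3, 3))), 0)
  expect_error(segment_nuclei(h, 0.6, matrix(FALSE, 3, 3)), "shape")
})

test_that("tuning-tile sampling filters background and is seed-reproducible", {
  cfg <- cfg_small()
  eff <- effective_pixel_size(cfg)
  expect_error(sample_tuning_tiles(array(1, c(100, 100, 3)), cfg,
                                   pixel_size_um = eff), "no tuning tile")
  slide <- array(0.6, c(100, 100, 3))       # all tissue
  set.seed(7); t1 <- sample_tuning_tiles(slide, cfg, pixel_size_um = eff)
  set.seed(7); t2 <- sample_tuning_tiles(slide, cfg, pixel_size_um = eff)
  expect_length(t1, cfg$tuning_tile_count)
  expect_identical(attr(t1, "origins"), attr(t2, "origins"))
  expect_error(sample_tuning_tiles(array(0.5, c(4, 4, 3)), cfg,
                                   pixel_size_um = eff), "smaller")
})

test_that("TCM partitions every pixel with nuclei taking precedence", {
  cfg <- cfg_small()
  white <- array(1, c(120, 120, 3))
  tcm <- build_tcm(white, slide_threshold = 0.5, config = cfg)
  expect_equal(dim(tcm$labels), c(30L, 30L))       # 120 px x 0.25
  expect_true(all(tcm$labels == 2L))               # all lumina
  set.seed(11)
  roi <- generate_roi("low", synth_params(), cfg)
  tcm2 <- build_tcm(roi$rgb, 0.4, cfg)
  counts <- tabulate(tcm2$labels, 3L)
  expect_equal(sum(counts), 30L * 30L)
  expect_true(all(tcm2$labels %in% 1:3))
})

test_that("full-size ROI maps to the 240 x 240 working grid", {
  cfg <- pipeline_config()
  set.seed(12)
  roi <- generate_roi("benign", synth_params(), cfg)
  tcm <- build_tcm(roi$rgb, 0.4, cfg)
  expect_equal(dim(tcm$labels), c(240L, 240L))
  expect_equal(sum(tabulate(tcm$labels, 3L)), 240L * 240L)
})

test_that("segmentation recovers generator masks and RBCs never add nuclei", {
  cfg <- cfg_small()
  p <- synth_params(rbc_density = 0)
  set.seed(21)
  roi <- generate_roi("low", p, cfg)
  small <- downsample_nn(roi$rgb, cfg$downsample_ratio)
  set.seed(22)
  thr <- slide_threshold(roi$rgb, cfg)
  tcm <- build_tcm(roi$rgb, thr, cfg)
  dn <- downsample_nn(roi$nuclei, cfg$downsample_ratio)
  dl <- downsample_nn(roi$lumina, cfg$downsample_ratio)
  expect_gte(dice(tcm$labels == 1L, dn), 0.9)
  expect_gte(dice(tcm$labels == 2L, dl), 0.9)

  # same tissue with blood blobs painted in: nucleus count must not rise
  p_rbc <- synth_params(rbc_density = 2000)   # dense blood on a small test ROI
  set.seed(21)
  roi_rbc <- generate_roi("low", p_rbc, cfg)
  tcm_rbc <- build_tcm(roi_rbc$rgb, thr, cfg)
  expect_true(any(roi_rbc$rbc))
  expect_lte(sum(tcm_rbc$labels == 1L), sum(tcm$labels == 1L))
})

test_that("maps are bit-identical across identical seeded runs", {
  cfg <- cfg_small()
  set.seed(31); roi1 <- generate_roi("high", synth_params(), cfg)
  set.seed(31); roi2 <- generate_roi("high", synth_params(), cfg)
  expect_identical(roi1$rgb, roi2$rgb)
  t1 <- build_tcm(roi1$rgb, 0.4, cfg)
  t2 <- build_tcm(roi2$rgb, 0.4, cfg)
  expect_identical(t1$labels, t2$labels)
})
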