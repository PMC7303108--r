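mask_config <- function() pipeline_config(roi_size_um = 10, pixel_size_um = 1)
# 10 x 10 px tiles on small integer masks

test_that("ROI labels follow the 50% area rules including the exact half", {
  cfg <- mask_config()
  mask <- matrix(0L, 10, 20)
  mask[, 1:10] <- 1L                      # tile 1: 100% G3
  mask[, 11:16] <- 1L; mask[, 17:20] <- 12L   # tile 2: 60% G3, 40% healthy
  rec <- label_rois(mask, cfg)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$detection_label))
  expect_equal(rec$grading_label_g4, c(FALSE, FALSE))  # G3 is the low-grade class
  # pure confounder tile: negative and grading-ineligible
  rec2 <- label_rois(matrix(10L, 10, 10), cfg)
  expect_false(rec2$detection_label)
  expect_true(is.na(rec2$grading_label_g4))
  expect_equal(rec2$tissue_type, "Atrophy")
  # exactly 50% cancer counts as positive
  half <- matrix(0L, 10, 10); half[1:5, ] <- 4L; half[6:10, ] <- 12L
  rec3 <- label_rois(half, cfg)
  expect_true(rec3$detection_label)
  expect_true(rec3$grading_label_g4)
})

test_that("mixed-pattern and G4&G5 pooling rules are applied", {
  cfg <- mask_config()
  # 60% G3+4: cancerous for detection, excluded from grading
  m <- matrix(12L, 10, 10); m[1:6, ] <- 2L
  rec <- label_rois(m, cfg)
  expect_true(rec$detection_label)
  expect_true(is.na(rec$grading_label_g4))
  expect_true(is.na(rec$grading_label_g45))
  # 30% G4 + 30% G5: pooled high-grade for the G4&G5 experiment only
  m2 <- matrix(12L, 10, 10); m2[1:3, ] <- 4L; m2[4:6, ] <- 7L
  rec2 <- label_rois(m2, cfg)
  expect_true(is.na(rec2$grading_label_g4))
  expect_true(rec2$grading_label_g45)
  # unknown annotation code is rejected by name
  m3 <- matrix(55L, 10, 10)
  expect_error(label_rois(m3, cfg), "55")
})

test_that("LOPO folds cover each ROI once with disjoint patients", {
  ids <- rep(paste0("P", 1:8), times = c(3, 5, 2, 4, 4, 3, 2, 5))
  folds <- lopo_folds(ids)
  expect_length(folds, 8L)
  expect_true(assert_patient_integrity(folds, ids))
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tested, seq_along(ids))
  for (f in folds) {
    expect_length(intersect(ids[f$train], ids[f$test]), 0L)
  }
  expect_error(lopo_folds(rep("P1", 5)), ">= 2 patients")
})

test_that("a patient straddling folds trips the integrity assertion", {
  ids <- rep(c("A", "B", "C"), each = 4)
  folds <- lopo_folds(ids)
  folds[[1]]$train <- c(folds[[1]]$train, folds[[1]]$test[1])  # leak A into train
  expect_error(assert_patient_integrity(folds, ids), "both train and test")
})

test_that("pooled ROC/AUC matches hand counts, ties and brute force", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))$auc, 0.5)
  expect_error(roc_auc(1:3 / 3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(501)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5) > 0
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external reference implementation", {
  set.seed(502)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.4) > 0
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("error metrics at the operating point match direct counts", {
  conf <- c(rep(0.9, 8), rep(0.1, 2),      # 10 positives, 2 missed
            rep(0.9, 9), rep(0.1, 81))     # 90 negatives, 9 false alarms
  y <- c(rep(TRUE, 10), rep(FALSE, 90))
  em <- error_metrics(conf, y, 0.5)
  expect_equal(em$fnr, 0.20)
  expect_equal(em$fpr, 0.10)
  expect_equal(em$error_rate, 0.11)
  perfect <- error_metrics(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$error_rate, 0)
  allpos <- error_metrics(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(allpos$fnr, 0)
  expect_equal(allpos$fpr, 1)
  expect_error(error_metrics(numeric(0), logical(0)), "empty")
})

test_that("per-tissue errors recover a planted miss rate", {
  set.seed(503)
  n <- 400
  rec <- data.frame(
    tissue_type = sample(c("G3", "G4", "Atrophy", "Healthy/BPH"), n, TRUE),
    stringsAsFactors = FALSE)
  rec$detection_label <- rec$tissue_type %in% c("G3", "G4")
  conf <- ifelse(rec$detection_label, 0.9, 0.1)
  flip <- rec$tissue_type == "G3" & runif(n) < 0.2   # planted 20% misses on G3
  conf[flip] <- 0.1
  tab <- per_tissue_error(rec, conf)
  expect_equal(sum(tab$n), n)
  g3 <- tab[tab$tissue_type == "G3", ]
  expect_equal(g3$metric, "FNR")
  n_g3 <- sum(rec$tissue_type == "G3")
  ci <- qbinom(c(0.005, 0.995), n_g3, 0.2) / n_g3
  expect_gte(g3$error_rate, ci[1]); expect_lte(g3$error_rate, ci[2])
  expect_equal(tab$error_rate[tab$tissue_type == "G4"], 0)
  expect_equal(tab$metric[tab$tissue_type == "Atrophy"], "FPR")
  expect_error(per_tissue_error(data.frame(tissue_type = "Bogus",
                                           detection_label = TRUE),
                                0.9), "Bogus")
})

test_that("label maps render the tile grid in the task's palette", {
  cfg <- mask_config()
  rec <- expand.grid(roi_col = c(0L, 10L), roi_row = c(0L, 10L))[, 2:1]
  conf <- c(1, 0, 0, 1)                       # checkerboard
  m <- render_label_map(rec, conf, "detection", cfg)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m, matrix(c(1, 0, 0, 1), 2, 2))
  allpos <- render_label_map(rec, rep(1, 4), "detection", cfg)
  expect_true(all(allpos == 1))
  g <- render_label_map(rec, c(1, 0, NA, 1), "grading", cfg)
  expect_equal(sort(unique(as.numeric(g))), c(0, 0.5, 1))
})

test_that("evaluate_lopo pools confidences across patient folds", {
  set.seed(504)
  n_pat <- 8; n_roi <- 12
  patient <- rep(seq_len(n_pat), each = n_roi)
  y <- rbinom(n_pat * n_roi, 1, 0.5) > 0
  x <- cbind(ifelse(y, 1.5, -1.5) + rnorm(n_pat * n_roi), rnorm(n_pat * n_roi))
  rep_out <- evaluate_lopo(x, y, patient, kind = "fisher", task = "detection")
  expect_s3_class(rep_out, "eval_report")
  expect_gt(rep_out$auc, 0.8)
  expect_equal(nrow(rep_out$fold_log), n_pat)
  expect_equal(sum(rep_out$counts), n_pat * n_roi)
  expect_true(all(rep_out$confidences >= 0 & rep_out$confidences <= 1))
  # NA labels are neither trained on nor scored
  y_na <- y; y_na[1:5] <- NA
  rep2 <- evaluate_lopo(x, y_na, patient, kind = "fisher", task = "detection")
  expect_true(all(is.na(rep2$confidences[1:5])))
  expect_equal(sum(rep2$counts), sum(!is.na(y_na)))
})
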