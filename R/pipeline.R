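#' Per-slide nucleus threshold of a slide image
#'
#' Downsamples the slide to the working resolution, samples the configured
#' number of tuning tiles and pools their hematoxylin values into the
#' slide-adaptive Otsu threshold.
#'
#' @param slide_rgb slide RGB array at scan resolution.
#' @param config a [pipeline_config()].
#' @return scalar hematoxylin threshold.
#' @export
slide_threshold <- function(slide_rgb, config = pipeline_config()) {
  small <- downsample_nn(slide_rgb, config$downsample_ratio)
  tiles <- sample_tuning_tiles(small, config,
                               pixel_size_um = effective_pixel_size(config))
  # deconvolution is pixelwise, so unmixing the slide once and pooling the
  # sampled tile footprints gives the same histogram as per-tile unmixing
  hema <- color_deconvolve(small, config)$hematoxylin
  side <- um_to_px(config$tuning_tile_um, effective_pixel_size(config))
  origins <- attr(tiles, "origins")
  pooled <- unlist(lapply(seq_len(nrow(origins)), function(i) {
    hema[(origins[i, 1] + 1L):(origins[i, 1] + side),
         (origins[i, 2] + 1L):(origins[i, 2] + side)]
  }), use.names = FALSE)
  pooled_otsu(pooled)
}

#' Extract labeled features from one slide
#'
#' Runs the mapping-and-features front end on a slide: per-slide adaptive
#' threshold, ROI tiling, tissue-component map and 156-feature descriptor
#' per ROI, and ROI labels from the annotation mask. Record rows and
#' feature rows are aligned (row-major tile order).
#'
#' @param slide_rgb slide RGB array at scan resolution.
#' @param annotation_mask integer annotation matrix aligned to the slide.
#' @param config a [pipeline_config()].
#' @param patient_id,slide_id identifiers for the records.
#' @return list with `records` (data frame), `features` (matrix) and
#'   `threshold`.
#' @export
slide_features <- function(slide_rgb, annotation_mask,
                           config = pipeline_config(),
                           patient_id = NA, slide_id = NA) {
  thr <- slide_threshold(slide_rgb, config)
  tiling <- tile_slide(slide_rgb, config)
  feats <- t(vapply(seq_len(nrow(tiling$grid)), function(i) {
    feature_vector(build_tcm(tiling$tile(i), thr, config))
  }, numeric(156L)))
  records <- label_rois(annotation_mask, config, patient_id, slide_id)
  stopifnot(nrow(records) == nrow(feats),
            all(records$roi_row == tiling$grid$roi_row),
            all(records$roi_col == tiling$grid$roi_col))
  list(records = records, features = feats, threshold = thr)
}

#' Extract features for a whole synthetic cohort
#'
#' Materializes each slide of a [generate_cohort()] plan in turn (slides are
#' regenerated from their seeds, so memory stays at one slide), computes its
#' adaptive threshold and per-ROI features, and labels ROIs from the
#' generated annotation masks. Sampling of tuning tiles is seeded per slide
#' from the cohort seed, so the whole extraction is reproducible.
#'
#' @param cohort a `synth_cohort`.
#' @param progress print one line per slide.
#' @return list with `records`, `features` and `thresholds` (named by
#'   slide).
#' @export
cohort_features <- function(cohort, progress = FALSE) {
  config <- cohort$config
  slide_ids <- unique(cohort$truth$slide_id)
  all_rec <- list(); all_feat <- list()
  thresholds <- numeric(0)
  for (sid in slide_ids) {
    sl <- build_slide(cohort, sid)
    set.seed((cohort$seed + 7L * match(sid, slide_ids)) %% .Machine$integer.max)
    sf <- slide_features(sl$rgb, sl$mask, config,
                         patient_id = sl$truth$patient_id[1], slide_id = sid)
    all_rec[[sid]] <- sf$records
    all_feat[[sid]] <- sf$features
    thresholds[sid] <- sf$threshold
    if (progress) {
      message(sprintf("%s: threshold %.3f, %d ROIs", sid, sf$threshold,
                      nrow(sf$records)))
    }
    rm(sl); gc(FALSE)
  }
  list(records = do.call(rbind, all_rec),
       features = do.call(rbind, all_feat),
       thresholds = thresholds)
}

#' Dice overlap of two binary masks
#' @param a,b logical matrices of equal shape.
#' @return 2|A∩B| / (|A| + |B|); 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Run one detection or grading experiment on extracted features
#'
#' Thin wrapper gluing the extraction output to [evaluate_lopo()]: picks
#' the task's label column (`detection_label`, `grading_label_g4` or
#' `grading_label_g45`), seeds the balancing RNG and returns the pooled
#' report.
#'
#' @param extraction list from [cohort_features()] / [slide_features()].
#' @param task `"detection"`, `"grading_g4"` or `"grading_g45"`.
#' @param kind classifier kind.
#' @param seed RNG seed for balancing.
#' @param operating_point hard-label cutoff.
#' @return an `eval_report`.
#' @export
run_experiment <- function(extraction, task = "detection", kind = "fisher",
                           seed = 1L, operating_point = 0.5) {
  rec <- extraction$records
  labels <- switch(task,
    detection = rec$detection_label,
    grading_g4 = rec$grading_label_g4,
    grading_g45 = rec$grading_label_g45,
    stop("unknown task: ", task, call. = FALSE))
  set.seed(seed)
  evaluate_lopo(extraction$features, labels, rec$patient_id, kind = kind,
                task = if (task == "detection") "detection" else "grading",
                records = if (task == "detection") rec else NULL,
                operating_point = operating_point)
}
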