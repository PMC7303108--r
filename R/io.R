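#' Tile a slide into a grid of ROIs
#'
#' Partitions a slide into non-overlapping square tiles of side
#' `roi_size_um / pixel_size_um` pixels, row-major, with 0-based half-open
#' pixel coordinates. Partial tiles at the right/bottom edge are dropped.
#'
#' @param slide_image RGB array (or matrix) at scan resolution.
#' @param config a [pipeline_config()].
#' @return list with `grid` (data frame `roi_row`, `roi_col` of tile
#'   origins), `side` (tile side in px) and `tile(i)` — a function
#'   extracting the i-th tile image.
#' @export
tile_slide <- function(slide_image, config = pipeline_config()) {
  d <- dim(slide_image)
  side <- roi_side_px(config)
  grid <- tile_grid(d[1:2], side)
  tile <- function(i) {
    r <- grid$roi_row[i]; c <- grid$roi_col[i]
    if (length(d) == 3L) {
      slide_image[(r + 1L):(r + side), (c + 1L):(c + side), , drop = FALSE]
    } else {
      slide_image[(r + 1L):(r + side), (c + 1L):(c + side), drop = FALSE]
    }
  }
  list(grid = grid, side = side, tile = tile)
}

#' Read an RGB image (PNG or TIFF) as an array in [0, 1]
#' @param path file path; format chosen by extension.
#' @return `h x w x 3` numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image (PNG or TIFF)
#' @param img `h x w x 3` array in [0, 1].
#' @param path destination; format chosen by extension.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Read / write integer label masks as PNG
#'
#' Label codes are stored in the 8-bit grey channel directly (code k as
#' intensity k/255), so masks survive a write/read round trip exactly.
#'
#' @param mask integer matrix of codes in 0..255.
#' @param path PNG path.
#' @return `read_mask` returns the integer matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask <= 255))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Read / write the pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `read_config` returns a validated [pipeline_config()].
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$stain_matrix <- as.numeric(lst$stain_matrix)   # column-major 9-vector
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)
  required <- c("pixel_size_um", "downsample_ratio", "roi_size_um")
  missing <- setdiff(required, names(lst))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(lst$stain_matrix)) {
    lst$stain_matrix <- matrix(as.numeric(lst$stain_matrix), 3L, 3L)
  }
  do.call(pipeline_config, lst[names(lst) %in% names(formals(pipeline_config))])
}

#' Write / read a feature table as CSV
#'
#' One row per ROI: the metadata columns (patient_id, slide_id, roi_row,
#' roi_col, tissue_type, label columns) followed by the 156 named feature
#' columns.
#'
#' @param records ROI record data frame.
#' @param features numeric matrix with [feature_names()] columns, rows
#'   aligned to `records`.
#' @param path CSV path.
#' @return `read_features` returns `list(records, features)`.
#' @export
write_features <- function(records, features, path) {
  stopifnot(nrow(records) == nrow(features))
  colnames(features) <- feature_names()
  utils::write.csv(cbind(records, as.data.frame(features)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fn <- feature_names()
  missing <- setdiff(fn, colnames(df))
  if (length(missing)) {
    stop("feature CSV is missing column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  list(records = df[, setdiff(colnames(df), fn), drop = FALSE],
       features = as.matrix(df[, fn]))
}

#' Serialize a trained classifier to JSON
#'
#' Stores standardization parameters, the calibration link and the
#' kind-specific decision function (Fisher direction, logistic
#' coefficients, or SVM support vectors / coefficients / rho), so a model
#' written to disk predicts identically after [read_model()].
#'
#' @param model a `tcm_classifier`.
#' @param path JSON path.
#' @return `read_model` returns a `tcm_classifier`.
#' @export
write_model <- function(model, path) {
  m <- model$model
  core <- list(kind = model$kind, task = model$task,
               center = model$center, scale = model$scale,
               n_features = model$n_features,
               feature_names = model$feature_names)
  extra <- switch(model$kind,
    fisher = list(w = as.numeric(m$w), calib = as.list(m$calib)),
    logistic = list(beta = as.numeric(m$beta)),
    svm = list(sv = as.numeric(m$fit$SV), sv_dim = dim(m$fit$SV),
               coefs = as.numeric(m$fit$coefs), rho = m$fit$rho,
               gamma = m$fit$gamma,
               kernel = if (m$fit$kernel == 2) "radial" else "linear",
               hyper = m$hyper, calib = as.list(m$calib)))
  jsonlite::write_json(c(core, extra), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- switch(j$kind,
    fisher = list(w = j$w, calib = unlist(j$calib)),
    logistic = list(beta = as.numeric(j$beta)),
    svm = list(sv = matrix(j$sv, j$sv_dim[1], j$sv_dim[2]),
               coefs = j$coefs, rho = j$rho, gamma = j$gamma,
               kernel = j$kernel, hyper = j$hyper, calib = unlist(j$calib)),
    stop("unknown model kind: ", j$kind, call. = FALSE))
  structure(list(kind = j$kind, task = j$task, model = model,
                 center = j$center, scale = j$scale,
                 n_features = j$n_features, feature_names = j$feature_names),
            class = "tcm_classifier")
}

#' Write an evaluation report (JSON + CSV tables)
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(kind = report$kind, task = report$task, auc = report$auc,
         error_rate = report$error_rate, fnr = report$fnr, fpr = report$fpr,
         counts = as.list(report$counts)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  if (!is.null(report$per_tissue)) {
    utils::write.csv(report$per_tissue, file.path(dir, "per_tissue.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$fold_log, file.path(dir, "folds.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, the seed, and md5 hashes of the
#' stage's input and output files, enabling a stage to be re-run and its
#' provenance chained.
#'
#' @param dir directory the manifest describes.
#' @param config a [pipeline_config()].
#' @param seed the seed the stage ran with.
#' @param inputs,outputs character vectors of file paths.
#' @return invisibly the manifest path.
#' @export
write_manifest <- function(dir, config, seed, inputs = character(0),
                           outputs = character(0)) {
  hash <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  cfg <- unclass(config)
  cfg$stain_matrix <- as.numeric(cfg$stain_matrix)
  jsonlite::write_json(
    list(tool = "histotcm",
         version = as.character(utils::packageVersion("histotcm")),
         seed = seed, config = cfg,
         inputs = hash(inputs), outputs = hash(outputs)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
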