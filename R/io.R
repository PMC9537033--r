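#' Read a grayscale image as a CT slice
#'
#' Reads 8- or 16-bit PNG or TIFF; multi-channel images are averaged to
#' one gray channel. Values are returned on the 0--255 scale (16-bit
#' images keep their relative scale).
#'
#' @param path file path (`.png`, `.tif`, `.tiff`)
#' @param roi optional ROI attached to the result
#' @return a [ct_slice()]
#' @export
read_slice <- function(path, roi = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3L, dim(arr)[3L]), drop = FALSE],
                                           c(1L, 2L), mean)
  ct_slice(arr * 255, roi = roi)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical or 0/1 numeric matrix
#' @param path output path
#' @return the path, invisibly
#' @export
write_mask <- function(mask, path) {
  png::writePNG((as_mask(mask) * 1), path)
  invisible(path)
}

#' Read a 0/255 PNG mask
#'
#' @param path input path
#' @return logical matrix
#' @export
read_mask <- function(path) {
  read_slice(path)$pixels > 127.5
}

#' Write a probability map as a plain-text matrix
#'
#' Values in `[-1, 1]`, whitespace-separated, one image row per line.
#'
#' @param F numeric matrix of random-walker probabilities
#' @param path output path
#' @return the path, invisibly
#' @export
write_probability_map <- function(F, path) {
  write.table(format(F, digits = 8), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a seed visualization PNG
#'
#' Gray underlay with nodule seeds in red and background seeds in blue.
#'
#' @param slice the underlying [ct_slice()] (ROI-cropped automatically)
#' @param seeds a `seed_set`
#' @param path output path
#' @return the path, invisibly
#' @export
write_seed_overlay <- function(slice, seeds, path) {
  px <- normalize_intensity(crop_roi(as_ct_slice(slice))$pixels)$pixels / 255
  rgb <- array(px, c(dim(px), 3L))
  nf <- seeds$nodule; nb <- seeds$background
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[nf] <- if (ch == 1L) 1 else 0
    plane[nb] <- if (ch == 3L) 1 else 0
    rgb[, , ch] <- plane
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Serialize / restore a pipeline configuration
#'
#' Plain-text YAML; `read_config(write_config(cfg, f))` restores an
#' identical configuration.
#'
#' @param config an [rw_config()]
#' @param path file path
#' @return `write_config`: the path, invisibly; `read_config`: an
#'   [rw_config()]
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rw_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(rw_config, raw)
}

#' Run the segmentation pipeline on image files
#'
#' Reads the input image, segments it, and writes the artifacts: the
#' binary mask (`mask.png`), a seed visualization (`seeds.png`), the
#' probability map (`probability.txt`), a YAML run log with the full
#' configuration, seed counts and stage timings (`run.yaml`), and, when a
#' ground-truth mask is supplied, a one-row metrics CSV (`metrics.csv`).
#'
#' @param input path to the input PNG/TIFF image
#' @param out_dir output directory (created if missing)
#' @param truth optional path to a ground-truth 0/255 PNG mask
#' @param roi optional ROI `c(row0, col0, n_rows, n_cols)`, 0-based
#' @param config an [rw_config()]
#' @param case_id identifier used in the metrics CSV (input basename by
#'   default)
#' @return invisibly, a list with the `rw_segmentation`, the metrics
#'   tibble (or `NULL`) and the paths written
#' @export
run_pipeline <- function(input, out_dir, truth = NULL, roi = NULL,
                         config = rw_config(), case_id = NULL) {
  seg <- segment(input, config = config, roi = roi)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(mask = file.path(out_dir, "mask.png"),
                seeds = file.path(out_dir, "seeds.png"),
                probability = file.path(out_dir, "probability.txt"),
                log = file.path(out_dir, "run.yaml"))
  write_mask(seg$mask, paths$mask)
  write_seed_overlay(seg$slice, seg$seeds, paths$seeds)
  write_probability_map(seg$solution$F, paths$probability)
  metrics <- NULL
  if (!is.null(truth)) {
    tm <- read_mask(truth)
    metrics <- evaluate_masks(seg$mask, tm, beta = config$evaluation$beta,
                              case_id = case_id %||% basename(input))
    paths$metrics <- file.path(out_dir, "metrics.csv")
    write.csv(metrics, paths$metrics, row.names = FALSE)
  }
  log <- list(input = input, roi = as.list(roi),
              config = unclass(config),
              n_seeds_nodule = sum(seg$seeds$nodule),
              n_seeds_background = sum(seg$seeds$background),
              solver_residual = seg$solution$residual,
              timings = as.list(seg$timings))
  yaml::write_yaml(log, paths$log)
  invisible(list(segmentation = seg, metrics = metrics, paths = paths))
}
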