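#' Pipeline configuration with the published defaults
#'
#' Collects every stage parameter in one nested list. Defaults follow the
#' published operating point: geodesic band width `T = 2`, background ring
#' radius `T1 = 100`, similarity thresholds `kappa = 10` and `eta = 5`,
#' trade-off `alpha = 100`, F-measure weight `beta = 0.3`, 8-connectivity
#' throughout.
#'
#' @param ... named overrides, e.g. `seeding = list(T = 1)`; nested lists
#'   are merged into the defaults
#' @return object of class `rw_config`
#' @export
rw_config <- function(...) {
  cfg <- list(
    preprocess = list(filter = "coherence", iters = 5L, contrast = 1, dt = 0.15),
    features = list(glcm = list(levels = 16L, distance = 1L, window = 7L),
                    gabor = list(thetas = (0:7) * pi / 8, lambdas = c(1, 2),
                                 sigmas = c(1, 2), phase = 0, gamma = 0.5),
                    lbp = list(radius = 1L, n_points = 8L)),
    seeding = list(T = 2, T1 = 100, kappa = 10, eta = 5, max_background = NULL),
    affinity = list(beta_i = 90),
    solver = list(alpha = 100, n_components = 2L, eps = 1e-6),
    evaluation = list(beta = 0.3),
    seed = 42L,
    verbosity = 0L
  )
  dots <- list(...)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_in(base[[nm]], over[[nm]])
      else base[nm] <- list(over[[nm]])  # keeps NULL values as entries
    }
    base
  }
  structure(merge_in(cfg, dots), class = "rw_config")
}

#' @export
print.rw_config <- function(x, ...) {
  cat(sprintf(
    "<rw_config> filter=%s T=%g T1=%g kappa=%g eta=%g alpha=%g beta=%g seed=%d\n",
    x$preprocess$filter, x$seeding$T, x$seeding$T1, x$seeding$kappa,
    x$seeding$eta, x$solver$alpha, x$evaluation$beta, x$seed))
  invisible(x)
}

#' Segment a GGO nodule in a CT slice
#'
#' Runs the full pipeline: intensity normalization and coherence
#' filtering, feature extraction, automatic seed acquisition, affinity
#' graph construction, GMM fitting and membership weighting, the
#' label-constrained random-walker solve, and thresholding at 0. When the
#' slice carries an ROI, segmentation runs on the ROI sub-image and the
#' mask is embedded back into the full frame.
#'
#' @param slice a [ct_slice()], matrix, or path to a PNG/TIFF image
#' @param config an [rw_config()]
#' @param roi optional ROI `c(row0, col0, n_rows, n_cols)` (0-based,
#'   half-open) overriding the slice's own
#' @param normalized set `TRUE` when the input is already on 0--255 and
#'   should not be re-scaled (default `FALSE`)
#' @param baseline also run the conventional hard-seed random walker and
#'   attach it as `$baseline` (default `FALSE`)
#' @return object of class `rw_segmentation`: list with the full-frame
#'   logical `mask`, the `solution` (`rw_solution`), `seeds` (`seed_set`),
#'   `field`, `gmms`, `config`, per-stage `timings` (seconds)
#' @export
segment <- function(slice, config = rw_config(), roi = NULL,
                    normalized = FALSE, baseline = FALSE) {
  if (is.character(slice)) slice <- read_slice(slice)
  slice <- as_ct_slice(slice, roi = roi %||% (if (inherits(slice, "ct_slice")) slice$roi))
  full_dim <- dim(slice$pixels)
  roi <- slice$roi
  tm <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  work <- crop_roi(slice)
  work <- if (normalized) ct_slice(pmin(pmax(work$pixels, 0), 255))
          else normalize_intensity(work$pixels)
  pp <- config$preprocess
  work <- coherence_filter(work, n_iter = pp$iters, contrast = pp$contrast,
                           dt = pp$dt,
                           method = if (pp$filter == "none") "none" else pp$filter)
  tm["preprocess"] <- tic() - t0; t0 <- tic()
  fg <- config$features
  bank <- gabor_bank(fg$gabor$thetas, fg$gabor$lambdas, fg$gabor$sigmas,
                     fg$gabor$phase, fg$gabor$gamma)
  field <- build_feature_field(work, glcm_levels = fg$glcm$levels,
                               glcm_distance = fg$glcm$distance,
                               glcm_window = fg$glcm$window, bank = bank)
  tm["features"] <- tic() - t0; t0 <- tic()
  sd_ <- config$seeding
  seeds <- acquire_seeds(work, field, T = sd_$T, T1 = sd_$T1,
                         kappa = sd_$kappa, eta = sd_$eta,
                         max_background = sd_$max_background)
  tm["seeding"] <- tic() - t0; t0 <- tic()
  graph <- affinity_matrix(field, beta_i = config$affinity$beta_i)
  gmms <- fit_gmms(seeds, field, n_components = config$solver$n_components,
                   rng_seed = config$seed, eps = config$solver$eps)
  u <- membership_weights(gmms, seeds)
  sol <- solve_random_walker(graph, seeds, u, alpha = config$solver$alpha)
  base <- if (baseline) conventional_random_walker(graph, seeds) else NULL
  tm["solve"] <- tic() - t0
  mask <- array(FALSE, full_dim)
  if (is.null(roi)) mask[] <- sol$mask
  else mask[(roi[1L] + 1L):(roi[1L] + roi[3L]),
            (roi[2L] + 1L):(roi[2L] + roi[4L])] <- sol$mask
  structure(list(mask = mask, solution = sol, seeds = seeds, field = field,
                 gmms = gmms, baseline = base, config = config, roi = roi,
                 slice = slice, work = work, timings = tm),
            class = "rw_segmentation")
}

#' @export
print.rw_segmentation <- function(x, ...) {
  cat(sprintf("<rw_segmentation> %d x %d, %d foreground pixels, %d+%d seeds (%.2fs)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              sum(x$seeds$nodule), sum(x$seeds$background), sum(x$timings)))
  invisible(x)
}

#' One-row summary of a segmentation
#'
#' @param x an `rw_segmentation`
#' @param ... unused
#' @return a one-row tibble: image size, seed counts, mask area, alpha,
#'   solver residual, total time
#' @export
glance.rw_segmentation <- function(x, ...) {
  tibble::tibble(
    n_pixels = length(x$solution$F),
    n_seeds_nodule = sum(x$seeds$nodule),
    n_seeds_background = sum(x$seeds$background),
    mask_area = sum(x$mask),
    alpha = x$solution$alpha,
    residual = x$solution$residual,
    elapsed = sum(x$timings)
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a segmentation result
#'
#' Gray image with the segmentation mask outline and, optionally, the
#' nodule (red) and background (blue) seeds.
#'
#' @param object an `rw_segmentation`
#' @param show_seeds overlay the seed sets (default `TRUE`)
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.rw_segmentation <- function(object, show_seeds = TRUE, ...) {
  px <- crop_roi(object$slice)$pixels
  df <- data.frame(
    row = as.vector(row(px)), col = as.vector(col(px)),
    intensity = as.vector(normalize_intensity(px)$pixels),
    mask = as.vector(object$solution$mask),
    seed = ifelse(as.vector(object$seeds$nodule), "nodule",
                  ifelse(as.vector(object$seeds$background), "background", NA))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$mask)),
                          breaks = 0.5, colour = "yellow", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_seeds && any(!is.na(df$seed)))
    p <- p + ggplot2::geom_point(
      data = df[!is.na(df$seed), ],
      ggplot2::aes(colour = .data$seed), size = 0.2) +
      ggplot2::scale_colour_manual(values = c(nodule = "red", background = "blue"))
  p
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
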