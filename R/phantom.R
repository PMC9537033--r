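#' Specification of a synthetic GGO phantom
#'
#' Describes a ground-glass-like blob: elevated, optionally two-level
#' (inhomogeneous) intensity, an irregular star-convex outline from a
#' low-order Fourier perturbation of the radius, a Gaussian-blurred
#' boundary, a textured darker background and additive Gaussian noise.
#'
#' @param size image side length in pixels (default 128)
#' @param center 1-based `c(row, col)` nodule centre (image centre when
#'   `NULL`)
#' @param radius mean nodule radius in pixels (default 18)
#' @param irregularity amplitude of the angular radius modulation as a
#'   fraction of the radius (default 0.2)
#' @param levels one or two nodule plateau intensities in `[0, 255]`
#'   (default 175; two levels split the interior into two lobes)
#' @param blur boundary blur, Gaussian sigma in pixels (default 1.5)
#' @param background background gray level (default 70)
#' @param bg_texture amplitude (sd) of the smooth background texture
#'   (default 6)
#' @param noise additive Gaussian noise sigma (default 8)
#' @param seed RNG seed making the phantom reproducible (default 1)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(size = 128L, center = NULL, radius = 18,
                         irregularity = 0.2, levels = 175, blur = 1.5,
                         background = 70, bg_texture = 6, noise = 8,
                         seed = 1L) {
  center <- center %||% rep((size + 1) / 2, 2L)
  if (any(levels < 0 | levels > 255) || background < 0 || background > 255)
    stop("intensity levels must lie in [0, 255]", call. = FALSE)
  if (length(levels) > 2L) stop("at most two plateau levels", call. = FALSE)
  max_r <- radius * (1 + irregularity)
  if (center[1L] - max_r < 5 || center[2L] - max_r < 5 ||
      center[1L] + max_r > size - 4 || center[2L] + max_r > size - 4)
    stop("nodule must fit inside the image with a 5-pixel margin", call. = FALSE)
  structure(list(size = as.integer(size), center = center, radius = radius,
                 irregularity = irregularity, levels = levels, blur = blur,
                 background = background, bg_texture = bg_texture,
                 noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

gaussian_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma,
                                      boundary = "replicate")))
}

#' Generate a synthetic GGO phantom and its exact ground truth
#'
#' The ground truth is the star-convex region whose radius is the mean
#' radius modulated by a random low-order (2--4) Fourier perturbation.
#' The image places the plateau level(s) inside the truth on a smoothly
#' textured background, blurs the whole frame to soften the boundary, and
#' adds Gaussian noise. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()]; additional arguments override its
#'   fields
#' @param ... passed to [phantom_spec()] when `spec` is missing
#' @return list with `image` (a [ct_slice()] on 0--255), `truth` (logical
#'   matrix) and `spec`
#' @export
make_phantom <- function(spec = NULL, ...) {
  spec <- spec %||% phantom_spec(...)
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  n <- spec$size
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  dy <- rr - spec$center[1L]
  dx <- cc - spec$center[2L]
  th <- atan2(dy, dx)
  # low-order Fourier modulation of the radius, bounded by `irregularity`
  modes <- 2:4
  a <- stats::runif(length(modes), -1, 1)
  ph <- stats::runif(length(modes), 0, 2 * pi)
  ssum <- sum(abs(a))
  mod <- matrix(0, n, n)
  if (ssum > 0) {
    for (k in seq_along(modes))
      mod <- mod + (a[k] / ssum) * cos(modes[k] * th + ph[k])
  }
  rad <- spec$radius * (1 + spec$irregularity * mod)
  truth <- sqrt(dy^2 + dx^2) <= rad
  # background: flat level plus smooth random texture
  img <- matrix(spec$background, n, n)
  if (spec$bg_texture > 0) {
    tex <- gaussian_blur_mat(matrix(stats::rnorm(n * n), n, n), 6)
    tex <- tex / max(stats::sd(tex), 1e-12) * spec$bg_texture
    img <- img + tex
  }
  # nodule plateau(s): two levels split by a random diameter
  if (length(spec$levels) == 2L) {
    split_th <- stats::runif(1, 0, pi)
    lobe <- (dy * cos(split_th) + dx * sin(split_th)) >= 0
    img[truth & lobe] <- spec$levels[1L]
    img[truth & !lobe] <- spec$levels[2L]
  } else {
    img[truth] <- spec$levels[1L]
  }
  img <- gaussian_blur_mat(img, spec$blur)
  if (spec$noise > 0) img <- img + matrix(stats::rnorm(n * n, 0, spec$noise), n, n)
  img <- pmin(pmax(img, 0), 255)
  list(image = ct_slice(img), truth = truth, spec = spec)
}

#' Simulated rater masks around a ground truth
#'
#' Each rater redraws the boundary with an independent, smoothly varying
#' dilation/erosion of up to `jitter` pixels: the rater's mask is the
#' sublevel set of the signed boundary distance at a smooth zero-mean
#' random offset field. Because the offsets are zero-mean, the 50%
#' consensus of several raters stays centred on the truth. With
#' `jitter = 0` every rater reproduces the truth exactly.
#'
#' @param truth logical ground-truth mask
#' @param n_raters number of raters (default 4)
#' @param jitter maximal boundary perturbation in pixels (default 1)
#' @param seed RNG seed (default 1)
#' @return list of `n_raters` logical masks
#' @export
make_rater_masks <- function(truth, n_raters = 4L, jitter = 1L, seed = 1L) {
  if (n_raters < 1L) stop("n_raters must be >= 1", call. = FALSE)
  truth <- as_mask(truth, "truth")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  all_px <- array(TRUE, dim(truth))
  d_out <- cpp_geodesic(all_px, truth)    # 0 inside the truth
  d_in <- cpp_geodesic(all_px, !truth)    # 0 outside
  signed <- d_out - d_in                  # negative strictly inside
  lapply(seq_len(n_raters), function(i) {
    if (jitter == 0) return(truth)
    g <- gaussian_blur_mat(matrix(stats::rnorm(length(truth)), nrow(truth)), 4)
    g <- g / max(abs(g))
    signed <= jitter * g
  })
}
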