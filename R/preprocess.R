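#' CT slice container
#'
#' A `ct_slice` is a thin wrapper around a numeric matrix of gray values on
#' the 0--255 scale, optionally carrying a rectangular region of interest.
#' Rows index the vertical image axis, columns the horizontal axis.
#'
#' @param pixels numeric matrix of intensities
#' @param roi optional integer vector `c(row0, col0, n_rows, n_cols)` in
#'   0-based, half-open convention; must lie fully inside the image
#' @return an object of class `ct_slice` with fields `pixels` and `roi`
#' @export
ct_slice <- function(pixels, roi = NULL) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("empty image", call. = FALSE)
  if (!all(is.finite(pixels))) stop("image contains non-finite values", call. = FALSE)
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 4L) stop("roi must be c(row0, col0, n_rows, n_cols)", call. = FALSE)
    if (roi[1L] < 0L || roi[2L] < 0L || roi[3L] < 1L || roi[4L] < 1L ||
        roi[1L] + roi[3L] > nrow(pixels) || roi[2L] + roi[4L] > ncol(pixels))
      stop("roi must lie inside the image", call. = FALSE)
  }
  structure(list(pixels = pixels, roi = roi), class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d, intensity [%.1f, %.1f]%s\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (is.null(x$roi)) "" else
                sprintf(", roi (%d,%d)+%dx%d", x$roi[1], x$roi[2], x$roi[3], x$roi[4])))
  invisible(x)
}

as_ct_slice <- function(x, roi = NULL) {
  if (inherits(x, "ct_slice")) x else ct_slice(x, roi)
}

#' Extract the ROI sub-image of a slice
#'
#' @param slice a [ct_slice()]
#' @return a `ct_slice` cropped to the ROI (the slice itself when no ROI)
#' @export
crop_roi <- function(slice) {
  slice <- as_ct_slice(slice)
  if (is.null(slice$roi)) return(slice)
  r <- slice$roi
  ct_slice(slice$pixels[(r[1L] + 1L):(r[1L] + r[3L]),
                        (r[2L] + 1L):(r[2L] + r[4L]), drop = FALSE])
}

#' Linearly rescale intensities to the 0--255 gray scale
#'
#' Maps the input range `[min, max]` linearly onto `[0, 255]`. A constant
#' image maps to all zeros so that degenerate inputs do not abort a batch
#' run.
#'
#' @param image numeric matrix (or `ct_slice`) of raw intensities
#' @param roi optional ROI passed through to the result
#' @return a [ct_slice()] with intensities in `[0, 255]`
#' @examples
#' normalize_intensity(matrix(c(0, 100, 200, 400), 2))$pixels
#' @export
normalize_intensity <- function(image, roi = NULL) {
  if (inherits(image, "ct_slice")) {
    roi <- roi %||% image$roi
    image <- image$pixels
  }
  image <- as.matrix(image)
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  rng <- range(image)
  px <- if (rng[2L] > rng[1L]) 255 * (image - rng[1L]) / (rng[2L] - rng[1L])
        else array(0, dim(image))
  ct_slice(px, roi)
}

# replicate-pad a matrix by k pixels on every side
pad_replicate <- function(m, k) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * k) - k, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * k) - k, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 3x3 separable [1 2 1]/4 smoothing with replicate boundary
smooth3 <- function(m) {
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  h <- (p[1:nr, ] + 2 * p[2:(nr + 1L), ] + p[3:(nr + 2L), ]) / 4
  (h[, 1:nc] + 2 * h[, 2:(nc + 1L)] + h[, 3:(nc + 2L)]) / 4
}

# central-difference gradients with replicate boundary
grad_central <- function(m) {
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  list(gr = (p[3:(nr + 2L), 2:(nc + 1L)] - p[1:nr, 2:(nc + 1L)]) / 2,
       gc = (p[2:(nr + 1L), 3:(nc + 2L)] - p[2:(nr + 1L), 1:nc]) / 2)
}

#' Edge-preserving noise suppression
#'
#' Coherence-enhancing anisotropic diffusion: the local structure tensor
#' (smoothed outer product of the intensity gradient) steers a diffusion
#' tensor that smooths strongly along image structures and weakly across
#' them, so noise is removed while nodule boundaries stay in place. A plain
#' Gaussian filter and a pass-through are available as alternatives.
#'
#' @param slice a [ct_slice()] (or matrix), normally intensity-normalized
#' @param n_iter number of explicit diffusion steps (default 5); 0 returns
#'   the input unchanged
#' @param contrast positive contrast parameter of the coherence response
#'   (gray-value units on the gradient magnitude; default 1)
#' @param dt explicit time step (default 0.15; stability requires <= 0.25)
#' @param method `"coherence"` (default), `"gaussian"` (sigma = 1), or
#'   `"none"`
#' @return a smoothed [ct_slice()] of identical shape
#' @export
coherence_filter <- function(slice, n_iter = 5L, contrast = 1,
                             dt = 0.15, method = c("coherence", "gaussian", "none")) {
  method <- match.arg(method)
  slice <- as_ct_slice(slice)
  if (n_iter < 0) stop("n_iter must be >= 0", call. = FALSE)
  if (contrast <= 0) stop("contrast must be positive", call. = FALSE)
  if (method == "none" || n_iter == 0L) return(slice)
  u <- slice$pixels
  if (method == "gaussian") {
    for (i in seq_len(n_iter)) u <- smooth3(u)
    return(ct_slice(u, slice$roi))
  }
  eps <- 1e-10
  for (it in seq_len(n_iter)) {
    g <- grad_central(smooth3(u))
    # structure tensor, component-wise smoothed
    j11 <- smooth3(g$gr * g$gr)
    j22 <- smooth3(g$gc * g$gc)
    j12 <- smooth3(g$gr * g$gc)
    # eigenvalues mu1 >= mu2 of [[j11, j12], [j12, j22]]
    tr <- j11 + j22
    dq <- sqrt(pmax((j11 - j22)^2 + 4 * j12^2, 0))
    mu1 <- (tr + dq) / 2
    mu2 <- (tr - dq) / 2
    # principal eigenvector (v1r, v1c); arbitrary where isotropic
    v1r <- 2 * j12
    v1c <- j22 - j11 + dq
    nv <- sqrt(v1r^2 + v1c^2)
    iso <- nv < eps
    v1r <- ifelse(iso, 1, v1r / pmax(nv, eps))
    v1c <- ifelse(iso, 0, v1c / pmax(nv, eps))
    # diffusivities: weak across structures (lam1), strong along (lam2);
    # `contrast` scales a reference gradient of ~7 gray levels/pixel, so
    # coherence values (squared-gradient units) are compared against
    # (7 * contrast)^2
    c1 <- 0.02
    coh <- (mu1 - mu2)
    lam1 <- c1 + (1 - c1) * exp(-coh / (49 * contrast^2))
    lam2 <- rep(1, length(lam1))
    # diffusion tensor D = lam1 v1 v1' + lam2 v2 v2', v2 = (-v1c, v1r)
    d11 <- lam1 * v1r^2 + lam2 * v1c^2
    d22 <- lam1 * v1c^2 + lam2 * v1r^2
    d12 <- (lam1 - lam2) * v1r * v1c
    dim(d11) <- dim(d22) <- dim(d12) <- dim(u)
    # staggered scheme: fluxes on the half-grid (forward differences),
    # divergence by backward differences. Unlike a central/central
    # discretization this damps the highest spatial frequencies, and the
    # zero-flux borders conserve the image mean exactly.
    nr <- nrow(u); nc <- ncol(u)
    gu <- grad_central(u)
    dr_f <- u[2:nr, , drop = FALSE] - u[1:(nr - 1L), , drop = FALSE]
    d11h <- (d11[2:nr, , drop = FALSE] + d11[1:(nr - 1L), , drop = FALSE]) / 2
    d12hr <- (d12[2:nr, , drop = FALSE] + d12[1:(nr - 1L), , drop = FALSE]) / 2
    gch <- (gu$gc[2:nr, , drop = FALSE] + gu$gc[1:(nr - 1L), , drop = FALSE]) / 2
    fr <- d11h * dr_f + d12hr * gch
    dc_f <- u[, 2:nc, drop = FALSE] - u[, 1:(nc - 1L), drop = FALSE]
    d22h <- (d22[, 2:nc, drop = FALSE] + d22[, 1:(nc - 1L), drop = FALSE]) / 2
    d12hc <- (d12[, 2:nc, drop = FALSE] + d12[, 1:(nc - 1L), drop = FALSE]) / 2
    grh <- (gu$gr[, 2:nc, drop = FALSE] + gu$gr[, 1:(nc - 1L), drop = FALSE]) / 2
    fc <- d12hc * grh + d22h * dc_f
    div <- rbind(fr, 0) - rbind(0, fr) + cbind(fc, 0) - cbind(0, fc)
    u <- u + dt * div
  }
  ct_slice(u, slice$roi)
}
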