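#' Quantize a 0--255 image to l gray levels
#'
#' Uniform binning of `[0, 255]` into `l` equal-width bins; returns 0-based
#' levels `0 .. l-1`.
#'
#' @param pixels numeric matrix on the 0--255 scale
#' @param levels number of gray levels `l >= 2`
#' @return integer matrix of levels
#' @keywords internal
quantize_levels <- function(pixels, levels) {
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  q <- pmin(pmax(floor(pixels / (256 / levels)), 0), levels - 1L)
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts all ordered pairs of distinct pixels within Chebyshev distance
#' `d` of each other (both endpoints inside the window when one is given),
#' on the image quantized to `l` uniform gray levels, and normalizes the
#' counts to sum to one. Counting both orders makes the matrix symmetric.
#'
#' @param slice a [ct_slice()] or matrix on the 0--255 scale
#' @param levels number of gray levels `l` (default 16)
#' @param distance neighbour distance `d` in pixels, Chebyshev (default 1)
#' @param window optional logical matrix restricting the co-occurrence
#'   counts to a pixel subset
#' @return an object of class `glcm_matrix`: list with `P` (l x l
#'   normalized co-occurrence matrix), `levels`, `distance`
#' @export
glcm <- function(slice, levels = 16L, distance = 1L, window = NULL) {
  px <- as_ct_slice(slice)$pixels
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  q <- quantize_levels(px, levels)
  if (is.null(window)) window <- array(TRUE, dim(q))
  if (sum(window) < 2L) stop("window must contain at least 2 pixels", call. = FALSE)
  l <- as.integer(levels)
  nr <- nrow(q); nc <- ncol(q)
  counts <- numeric(l * l)
  for (dr in -distance:distance) {
    for (dc in -distance:distance) {
      if (dr == 0L && dc == 0L) next
      r1 <- max(1L, 1L - dr):min(nr, nr - dr)
      c1 <- max(1L, 1L - dc):min(nc, nc - dc)
      a <- q[r1, c1, drop = FALSE]
      b <- q[r1 + dr, c1 + dc, drop = FALSE]
      ok <- window[r1, c1, drop = FALSE] & window[r1 + dr, c1 + dc, drop = FALSE]
      if (!any(ok)) next
      idx <- a[ok] * l + b[ok] + 1L
      tab <- tabulate(idx, nbins = l * l)
      counts <- counts + tab
    }
  }
  tot <- sum(counts)
  if (tot == 0) stop("no co-occurring pixel pairs in window", call. = FALSE)
  structure(list(P = matrix(counts / tot, l, l, byrow = TRUE),
                 levels = l, distance = as.integer(distance)),
            class = "glcm_matrix")
}

#' Contrast and energy of a co-occurrence matrix
#'
#' Contrast is `sum P(i,j) (i-j)^2`; energy (angular second moment) is
#' `sum P(i,j)^2`.
#'
#' @param g a `glcm_matrix` from [glcm()]
#' @return named numeric vector with elements `contrast` and `energy`
#' @export
glcm_statistics <- function(g) {
  stopifnot(inherits(g, "glcm_matrix"))
  l <- g$levels
  i <- matrix(0:(l - 1L), l, l)
  j <- t(i)
  c(contrast = sum(g$P * (i - j)^2), energy = sum(g$P^2))
}

#' A single Gabor kernel
#'
#' Gaussian envelope times a cosine carrier along the orientation `theta`:
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + phi)`
#' with `x' = x cos(theta) + y sin(theta)`, evaluated on a square grid of
#' half-width `ceiling(3 sigma)` centred at the origin.
#'
#' @param sigma standard deviation of the Gaussian envelope (pixels)
#' @param lambda carrier wavelength (pixels)
#' @param theta orientation (radians)
#' @param phi phase offset (radians, default 0)
#' @param gamma spatial aspect ratio (default 0.5)
#' @return numeric matrix (rows = y, columns = x)
#' @export
gabor_kernel <- function(sigma, lambda, theta, phi = 0, gamma = 0.5) {
  if (sigma <= 0 || lambda <= 0 || gamma <= 0)
    stop("sigma, lambda and gamma must be positive", call. = FALSE)
  hw <- ceiling(3 * sigma)
  x <- matrix(-hw:hw, 2L * hw + 1L, 2L * hw + 1L, byrow = TRUE)
  y <- t(x)
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + phi)
}

#' A bank of Gabor kernels
#'
#' The default bank uses eight orientations `0, pi/8, ..., 7 pi/8`, two
#' wavelengths `1, 2` and two envelope widths `1, 2` (32 kernels).
#'
#' @param thetas orientations in radians
#' @param lambdas wavelengths
#' @param sigmas envelope standard deviations
#' @param phi common phase offset
#' @param gamma common aspect ratio
#' @return object of class `gabor_bank`: list of kernels plus the parameter
#'   grid
#' @export
gabor_bank <- function(thetas = (0:7) * pi / 8, lambdas = c(1, 2),
                       sigmas = c(1, 2), phi = 0, gamma = 0.5) {
  grid <- expand.grid(theta = thetas, lambda = lambdas, sigma = sigmas,
                      KEEP.OUT.ATTRS = FALSE)
  kernels <- lapply(seq_len(nrow(grid)), function(i)
    gabor_kernel(grid$sigma[i], grid$lambda[i], grid$theta[i], phi, gamma))
  structure(list(kernels = kernels, grid = grid, phi = phi, gamma = gamma),
            class = "gabor_bank")
}

#' Maximum Gabor filter magnitude per pixel
#'
#' Filters the image with every kernel in the bank and takes, per pixel,
#' the maximum of the absolute responses.
#'
#' @param slice a [ct_slice()] or matrix
#' @param bank a [gabor_bank()]
#' @return numeric matrix of the same shape
#' @export
gabor_max_response <- function(slice, bank = gabor_bank()) {
  px <- as_ct_slice(slice)$pixels
  if (!inherits(bank, "gabor_bank") || length(bank$kernels) == 0L)
    stop("bank must be a non-empty gabor_bank", call. = FALSE)
  # replicate-pad by the largest kernel half-width so the convolution is
  # well defined near borders and for images smaller than a kernel
  hw <- max(vapply(bank$kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1L)))
  padded <- pad_replicate(px, hw)
  img <- EBImage::Image(t(padded))
  rows <- hw + seq_len(nrow(px))
  cols <- hw + seq_len(ncol(px))
  out <- array(0, dim(px))
  for (k in bank$kernels) {
    resp <- abs(t(EBImage::imageData(
      EBImage::filter2(img, k, boundary = "circular"))))
    out <- pmax(out, resp[rows, cols, drop = FALSE])
  }
  out
}

#' Local binary pattern map
#'
#' Rotation-invariant uniform LBP on the 8-pixel, radius-1 neighbourhood:
#' each neighbour is thresholded against the centre (strictly greater, so
#' flat regions code as 0); patterns with
#' at most two 0/1 transitions along the circle get the code "number of set
#' bits" (0--8), all other patterns share the non-uniform code 9. Borders
#' are handled by replicate padding. Codes are invariant under adding a
#' constant to the image.
#'
#' @param slice a [ct_slice()] or matrix
#' @return integer matrix of codes in `0..9`
#' @export
lbp_map <- function(slice) {
  px <- as_ct_slice(slice)$pixels
  nr <- nrow(px); nc <- ncol(px)
  p <- pad_replicate(px, 1L)
  # neighbours in circular order starting East, counter-clockwise in image
  # coordinates (E, NE, N, NW, W, SW, S, SE)
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
               c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  bits <- lapply(offs, function(o)
    p[(2L + o[1L]):(nr + 1L + o[1L]), (2L + o[2L]):(nc + 1L + o[2L])] > px)
  nset <- Reduce(`+`, bits)
  trans <- array(0L, dim(px))
  for (k in seq_len(8L)) {
    nxt <- if (k == 8L) 1L else k + 1L
    trans <- trans + (bits[[k]] != bits[[nxt]])
  }
  code <- ifelse(trans <= 2L, nset, 9L)
  storage.mode(code) <- "integer"
  code
}

scale01 <- function(m, mask = NULL) {
  v <- if (is.null(mask)) m else m[mask]
  rng <- range(v)
  if (rng[2L] <= rng[1L]) return(array(0, dim(m)))
  pmin(pmax((m - rng[1L]) / (rng[2L] - rng[1L]), 0), 1)
}

#' Per-pixel feature field
#'
#' Assembles the per-pixel descriptors used by seeding and by the affinity
#' matrix: intensity (0--255 and min--max scaled to `[0, 1]`), windowed
#' GLCM contrast and energy, maximum Gabor magnitude, and the LBP code.
#' Every texture component is min--max scaled to `[0, 1]` over the image.
#'
#' @param slice a preprocessed [ct_slice()] or matrix
#' @param glcm_levels gray levels for the windowed GLCM (default 16)
#' @param glcm_distance GLCM neighbour distance (default 1)
#' @param glcm_window odd sliding-window side length (default 7)
#' @param bank a [gabor_bank()] (default bank when `NULL`)
#' @return object of class `feature_field`: list of same-shape matrices
#'   `intensity`, `intensity01`, `glcm_contrast`, `glcm_energy`, `gabor`,
#'   `lbp`, `lbp_code`, plus `dim`
#' @export
build_feature_field <- function(slice, glcm_levels = 16L, glcm_distance = 1L,
                                glcm_window = 7L, bank = NULL) {
  slice <- as_ct_slice(slice)
  px <- slice$pixels
  if (glcm_window %% 2L != 1L || glcm_window < 3L)
    stop("glcm_window must be an odd integer >= 3", call. = FALSE)
  if (nrow(px) < glcm_window || ncol(px) < glcm_window)
    stop("image smaller than the GLCM window", call. = FALSE)
  q <- quantize_levels(px, glcm_levels)
  gl <- cpp_glcm_window(q, as.integer(glcm_levels), as.integer(glcm_distance),
                        as.integer(glcm_window))
  gb <- gabor_max_response(px, bank %||% gabor_bank())
  lbp <- lbp_map(px)
  stopifnot(all(is.finite(gl$contrast)), all(is.finite(gl$energy)),
            all(is.finite(gb)))
  structure(list(
    intensity = px,
    intensity01 = scale01(px),
    glcm_contrast = scale01(gl$contrast),
    glcm_energy = scale01(gl$energy),
    gabor = scale01(gb),
    lbp = scale01(lbp + 0),
    lbp_code = lbp,
    dim = dim(px)
  ), class = "feature_field")
}

#' @export
print.feature_field <- function(x, ...) {
  cat(sprintf("<feature_field> %d x %d (intensity + 4 texture components)\n",
              x$dim[1L], x$dim[2L]))
  invisible(x)
}
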