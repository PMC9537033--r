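#' Adaptive (Otsu) threshold mask
#'
#' Finds one global threshold from the gray-level histogram and marks
#' pixels strictly above it as candidate nodule foreground. A constant
#' image has no threshold; it yields an empty mask with a warning.
#'
#' @param slice a preprocessed [ct_slice()] or matrix on 0--255
#' @return logical matrix of the slice shape
#' @export
adaptive_threshold_mask <- function(slice) {
  px <- as_ct_slice(slice)$pixels
  if (length(px) == 0L) stop("empty image", call. = FALSE)
  rng <- range(px)
  if (rng[2L] <= rng[1L]) {
    warning("constant image: no threshold exists, returning empty mask")
    return(array(FALSE, dim(px)))
  }
  th <- EBImage::otsu(EBImage::Image(t(px) / 255), range = c(0, 1), levels = 256L)
  px > th * 255
}

component_centroids <- function(lab) {
  n <- max(lab)
  idx <- which(lab > 0)
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  c <- ((idx - 1L) %/% nrow(lab)) + 1L
  g <- lab[idx]
  cbind(r = tapply(r, g, mean), c = tapply(c, g, mean),
        size = tabulate(g, nbins = n))
}

#' Clean up an initial threshold mask
#'
#' Morphological opening (disc of radius 1) removes specks and thin
#' bridges; of the remaining 8-connected components, the one whose centroid
#' lies closest to the ROI centre (image centre by default) is kept.
#'
#' @param mask logical matrix from [adaptive_threshold_mask()]
#' @param center optional 1-based `c(row, col)` reference point
#' @return logical matrix containing a single 8-connected component
#' @export
refine_initial_mask <- function(mask, center = NULL) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  br <- EBImage::makeBrush(3L, shape = "disc")
  op <- t(EBImage::imageData(EBImage::opening(EBImage::Image(t(mask * 1)), br))) > 0.5
  lab <- cpp_label8(op)
  if (max(lab) == 0L) stop("all components removed by opening", call. = FALSE)
  center <- center %||% ((dim(mask) + 1) / 2)
  cen <- component_centroids(lab)
  d <- sqrt((cen[, "r"] - center[1L])^2 + (cen[, "c"] - center[2L])^2)
  # nearest to the centre; ties broken towards the larger, then first label
  keep <- order(round(d, 9), -cen[, "size"])[1L]
  lab == keep
}

#' Boundary pixels of a mask
#'
#' Pixels of the mask with at least one 8-neighbour outside it (pixels on
#' the image border count as boundary).
#'
#' @param mask logical matrix
#' @return logical matrix
#' @export
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- array(FALSE, c(nr + 2L, nc + 2L))
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  allnb <- array(TRUE, dim(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    allnb <- allnb & p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  mask & !allnb
}

#' Geodesic core of an initial segmentation
#'
#' Computes the geodesic distance `g` from the boundary of `O` inward
#' (8-connected grid, unit and sqrt(2) step costs), takes the band
#' `M - T <= g <= M` where `M = max g`, and returns its largest connected
#' component. When the region is so thin that `M = 0`, `O` itself is
#' returned with a warning.
#'
#' @param O logical matrix, non-empty initial segmentation
#' @param T band width in geodesic distance units (default 2)
#' @return list with `core` (logical matrix `O_0`), `distance` (matrix of
#'   geodesic distances, `NA` outside `O`) and `M`
#' @export
geodesic_core <- function(O, T = 2) {
  if (!any(O)) stop("O must be non-empty", call. = FALSE)
  bd <- mask_boundary(O)
  g <- cpp_geodesic(O, bd)
  M <- max(g, na.rm = TRUE)
  if (M <= 0) {
    warning("region too thin (max geodesic distance 0); core = region")
    return(list(core = O, distance = g, M = M))
  }
  band <- O & !is.na(g) & g >= M - T & g <= M
  lab <- cpp_label8(band)
  sizes <- tabulate(lab[lab > 0])
  core <- lab == which.max(sizes)
  list(core = core, distance = g, M = M)
}

seed_feat <- function(field) {
  # seeding texture components: windowed GLCM contrast + energy and Gabor
  # magnitude (scaled to [0,1]); intensity on the 0-255 scale
  list(I = field$intensity,
       T1 = field$glcm_contrast, T2 = field$glcm_energy, T3 = field$gabor)
}

sim_pairs <- function(f, i, j, clip = 50) {
  # Local similarity S between linear index vectors i and j:
  # ||T_i - T_j||^2 * exp(min(|I_i - I_j|^2, clip))
  td2 <- (f$T1[i] - f$T1[j])^2 + (f$T2[i] - f$T2[j])^2 + (f$T3[i] - f$T3[j])^2
  td2 * exp(pmin((f$I[i] - f$I[j])^2, clip))
}

#' Local feature similarity between two adjacent pixels
#'
#' `S(i, j) = ||T_i - T_j||^2 * exp(||I_i - I_j||^2)` where `T` is the
#' seeding texture vector (windowed GLCM contrast and energy, Gabor
#' magnitude; each scaled to `[0, 1]`) and `I` the 0--255 intensity. The
#' exponent is clipped at 50 to avoid overflow; pixels that dissimilar are
#' far beyond any useful threshold anyway. Small values mean similar
#' pixels; the measure is symmetric and non-negative.
#'
#' @param i,j 0-based `c(row, col)` coordinates of two 8-adjacent pixels
#' @param field a [build_feature_field()] result
#' @return scalar `S(i, j) >= 0`
#' @export
local_similarity <- function(i, j, field) {
  stopifnot(inherits(field, "feature_field"))
  if (max(abs(i - j)) != 1L || all(i == j))
    stop("pixels must be 8-adjacent", call. = FALSE)
  nr <- field$dim[1L]
  li <- i[2L] * nr + i[1L] + 1L
  lj <- j[2L] * nr + j[1L] + 1L
  f <- seed_feat(field)
  unname(sim_pairs(f, li, lj))
}

# min over core pixels k of S(j, k): the "similar to some pixel of O_0"
# test. The core is subsampled deterministically (evenly spaced in linear
# index order, at most 200 pixels) to bound the cost.
core_min_sim <- function(f, core, idx, clip = 50) {
  ci <- which(core)
  if (length(ci) > 200L)
    ci <- ci[unique(round(seq(1L, length(ci), length.out = 200L)))]
  best <- rep(Inf, length(idx))
  for (k in ci) {
    td2 <- (f$T1[idx] - f$T1[k])^2 + (f$T2[idx] - f$T2[k])^2 +
      (f$T3[idx] - f$T3[k])^2
    best <- pmin(best, td2 * exp(pmin((f$I[idx] - f$I[k])^2, clip)))
  }
  best
}

#' Grow the nodule seed set by local search
#'
#' Starting from the geodesic core `O_0`, boundary pixels of `O` propose
#' their 8-neighbours: a neighbour `j` of a frontier pixel `i` joins the
#' nodule seed set when `S(i, j) < kappa` and `j` is similar to some core
#' pixel, `min_k S(j, k) < kappa` over `k` in `O_0` (the core is
#' deterministically subsampled to at most 200 pixels). Newly accepted
#' pixels join the frontier, so the search walks across inhomogeneous
#' nodule interiors until no pixel is added. Deterministic for a fixed
#' input (frontier processed in column-major order).
#'
#' @param O logical initial-segmentation mask
#' @param core logical geodesic core `O_0` (subset of `O`)
#' @param field a [build_feature_field()] result
#' @param kappa similarity threshold (default 10)
#' @return logical matrix of nodule seeds (`V_M^F`), a superset of `core`
#' @export
grow_nodule_seeds <- function(O, core, field, kappa = 10) {
  if (!any(core)) stop("empty core O_0", call. = FALSE)
  f <- seed_feat(field)
  seeds <- core
  dm <- field$dim
  # the search starts from the boundary of O and from the core's own
  # boundary (the core pixels are accepted seeds, so their neighbourhoods
  # are explored from the first pass)
  frontier <- which(mask_boundary(O) | mask_boundary(core))
  visited <- array(FALSE, dm)
  visited[frontier] <- TRUE
  while (length(frontier) > 0L) {
    np <- neighbour_pairs(sort(frontier), dm)
    cand <- np[!seeds[np[, "to"]], , drop = FALSE]
    if (nrow(cand) == 0L) break
    ok <- sim_pairs(f, cand[, "from"], cand[, "to"]) < kappa
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) > 0L)
      cand <- cand[core_min_sim(f, core, cand[, "to"]) < kappa, , drop = FALSE]
    add <- unique(cand[, "to"])
    if (length(add) == 0L) break
    seeds[add] <- TRUE
    frontier <- add[!visited[add]]
    visited[frontier] <- TRUE
  }
  seeds
}

#' Grow the background seed set by local search
#'
#' Candidate pixels live in the ring `O_b`: outside `O` but within
#' Euclidean distance `T1` of the centroid of `O`. A candidate `j` next to
#' a frontier pixel `i` (initially the boundary of `O`) joins the
#' background seed set when `S(i, j) > eta` and `j` is dissimilar from
#' every core pixel, `min_k S(j, k) > eta` over `k` in `O_0`; accepted
#' pixels join the frontier so acceptance spreads through `O_b`. When the rule admits no
#' pixel (or `O_b` is empty because `T1` is too small) the image-border
#' ring is used as a fallback, with a warning.
#'
#' @param O logical initial-segmentation mask
#' @param core logical geodesic core `O_0`
#' @param field a [build_feature_field()] result
#' @param eta dissimilarity threshold (default 5)
#' @param T1 background ring radius in pixels (default 100)
#' @param fallback use the image-border ring when no seed is found
#'   (default `TRUE`)
#' @param max_seeds optional cap on the number of background seeds; when
#'   set, the seeds closest to `O` are kept
#' @return logical matrix of background seeds (`V_M^B`), disjoint from `O`
#' @export
grow_background_seeds <- function(O, core, field, eta = 5, T1 = 100,
                                  fallback = TRUE, max_seeds = NULL) {
  if (!any(O)) stop("empty O", call. = FALSE)
  f <- seed_feat(field)
  dm <- field$dim
  idx <- which(O)
  cen <- c(mean(((idx - 1L) %% dm[1L]) + 1L), mean(((idx - 1L) %/% dm[1L]) + 1L))
  rr <- matrix(seq_len(dm[1L]), dm[1L], dm[2L])
  cc <- matrix(seq_len(dm[2L]), dm[1L], dm[2L], byrow = TRUE)
  dist_cen <- sqrt((rr - cen[1L])^2 + (cc - cen[2L])^2)
  Ob <- !O & dist_cen <= T1
  seeds <- array(FALSE, dm)
  if (any(Ob)) {
    frontier <- which(mask_boundary(O))
    visited <- array(FALSE, dm)
    visited[frontier] <- TRUE
    while (length(frontier) > 0L) {
      np <- neighbour_pairs(sort(frontier), dm)
      keep <- Ob[np[, "to"]] & !core[np[, "to"]] & !seeds[np[, "to"]]
      cand <- np[keep, , drop = FALSE]
      if (nrow(cand) == 0L) break
      ok <- sim_pairs(f, cand[, "from"], cand[, "to"]) > eta
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) > 0L)
        cand <- cand[core_min_sim(f, core, cand[, "to"]) > eta, , drop = FALSE]
      add <- unique(cand[, "to"])
      if (length(add) == 0L) break
      seeds[add] <- TRUE
      frontier <- add[!visited[add]]
      visited[frontier] <- TRUE
    }
  }
  if (!any(seeds)) {
    if (!fallback) return(seeds)
    warning("no background seed admitted by the similarity rule; ",
            "falling back to the image-border ring")
    seeds[c(1L, dm[1L]), ] <- TRUE
    seeds[, c(1L, dm[2L])] <- TRUE
    seeds <- seeds & !O
  }
  if (!is.null(max_seeds) && sum(seeds) > max_seeds) {
    g <- cpp_geodesic(!O, outer_boundary(O))
    ds <- g[which(seeds)]
    keep <- which(seeds)[order(ds)][seq_len(max_seeds)]
    seeds <- array(FALSE, dm)
    seeds[keep] <- TRUE
  }
  seeds
}

outer_boundary <- function(mask) mask_boundary(!mask) & !mask

#' Acquire nodule and background seeds automatically
#'
#' Full seeding stage: adaptive threshold, morphological refinement,
#' geodesic core, then local-search growth of the nodule and background
#' seed sets. Conflicting pixels are assigned to the nodule set.
#'
#' @param slice a preprocessed [ct_slice()] or matrix
#' @param field a [build_feature_field()] result for the same slice
#' @param T geodesic band width (default 2)
#' @param T1 background ring radius in pixels (default 100)
#' @param kappa nodule similarity threshold (default 10)
#' @param eta background dissimilarity threshold (default 5)
#' @param max_background optional cap on background seed count
#' @return object of class `seed_set`: list with logical matrices `nodule`
#'   and `background`, label matrix `b` (+1 nodule, -1 background, 0
#'   unlabeled), and the intermediate masks `O`, `core`
#' @export
acquire_seeds <- function(slice, field, T = 2, T1 = 100, kappa = 10, eta = 5,
                          max_background = NULL) {
  slice <- as_ct_slice(slice)
  m0 <- adaptive_threshold_mask(slice)
  if (!any(m0)) stop("adaptive threshold produced an empty mask", call. = FALSE)
  O <- refine_initial_mask(m0)
  gc <- geodesic_core(O, T = T)
  vf <- grow_nodule_seeds(O, gc$core, field, kappa = kappa)
  vb <- grow_background_seeds(O, gc$core, field, eta = eta, T1 = T1,
                              max_seeds = max_background)
  vb <- vb & !vf  # conflicts resolved in favour of the nodule set
  if (!any(vf) || !any(vb))
    stop("seed acquisition failed: one of the seed sets is empty", call. = FALSE)
  b <- array(0, dim(vf))
  b[vf] <- 1
  b[vb] <- -1
  structure(list(nodule = vf, background = vb, b = b, O = O, core = gc$core,
                 geodesic = gc$distance),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d nodule, %d background seeds (%d x %d image)\n",
              sum(x$nodule), sum(x$background), nrow(x$b), ncol(x$b)))
  invisible(x)
}
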