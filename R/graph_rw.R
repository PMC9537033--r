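#' Pixel graph with the multi-feature affinity matrix
#'
#' Builds the 8-connected pixel graph whose edge weights combine a spatial
#' adjacency term and feature terms by point-wise multiplication:
#' `w_ij = exp(-||z_i - z_j||^2) exp(-beta_i ||I_i - I_j||^2)
#' exp(-||T_i - T_j||^2)` with coordinates `z` in pixels, intensity `I`
#' scaled to `[0, 1]`, and the affinity texture vector `T` = (LBP, Gabor
#' magnitude), both scaled to `[0, 1]`.
#'
#' The intensity gain `beta_i` sets the gray-level contrast at which an
#' edge becomes a barrier to the walker. On the `[0, 1]` scale a unit gain
#' would let the walker cross even a full-range step almost freely
#' (`exp(-1)` at worst), so the customary seeded-random-walker default of
#' 90 is used: a boundary contrast of ~0.1 then costs `exp(-0.9)` per
#' edge while filtered-noise fluctuations (~0.01) remain free.
#'
#' @param field a [build_feature_field()] result
#' @param beta_i intensity gain of the affinity kernel (default 90)
#' @return object of class `pixel_graph`: list with sparse symmetric `W`,
#'   degree vector `d`, Laplacian `L = D - W`, node count `n` and `dim`
#' @export
affinity_matrix <- function(field, beta_i = 90) {
  stopifnot(inherits(field, "feature_field"))
  dm <- field$dim
  nr <- dm[1L]; nc <- dm[2L]
  n <- nr * nc
  I <- field$intensity01
  Tl <- field$lbp
  Tg <- field$gabor
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  # unique forward offsets; symmetry added once at matrix construction
  offs <- cbind(dr = c(0L, 1L, 1L, 1L), dc = c(1L, -1L, 0L, 1L))
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    from <- as.vector(outer(r1, (c1 - 1L) * nr, `+`))
    to <- from + dr + dc * nr
    sp2 <- dr * dr + dc * dc
    w <- exp(-sp2) * exp(-beta_i * (I[from] - I[to])^2) *
      exp(-((Tl[from] - Tl[to])^2 + (Tg[from] - Tg[to])^2))
    ii <- c(ii, from); jj <- c(jj, to); ww <- c(ww, w)
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  d <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(n, d) - W
  structure(list(W = W, d = d, L = L, n = n, dim = dm), class = "pixel_graph")
}

#' Construct a pixel_graph from an explicit weight matrix
#'
#' Mostly for testing and for running the solver on arbitrary graphs.
#'
#' @param W symmetric non-negative (sparse or dense) weight matrix with a
#'   zero diagonal
#' @return a `pixel_graph`
#' @export
pixel_graph <- function(W) {
  W <- methods::as(methods::as(Matrix::Matrix(W), "generalMatrix"), "CsparseMatrix")
  if (!Matrix::isSymmetric(W)) stop("W must be symmetric", call. = FALSE)
  Matrix::diag(W) <- 0
  n <- nrow(W)
  d <- Matrix::rowSums(W)
  structure(list(W = W, d = d, L = Matrix::Diagonal(n, d) - W, n = n,
                 dim = NULL), class = "pixel_graph")
}

gmm_train <- function(h, n_components, rng_seed, max_train = 1000L) {
  # deterministic subsample for speed on large seed sets
  if (nrow(h) > max_train) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(rng_seed)
    h <- h[sort(sample.int(nrow(h), max_train)), , drop = FALSE]
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  G <- n_components
  # single-Gaussian fallback for very small seed sets
  if (nrow(h) < G * (ncol(h) + 1L)) G <- 1L
  fit <- tryCatch(
    suppressWarnings(mclust::densityMclust(
      h, G = G, modelNames = "VVI", verbose = FALSE, plot = FALSE,
      prior = mclust::priorControl())),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters))
    fit <- tryCatch(
      suppressWarnings(mclust::densityMclust(
        h, G = 1L, modelNames = "XII", verbose = FALSE, plot = FALSE,
        prior = mclust::priorControl())),
      error = function(e) NULL)
  if (!is.null(fit)) return(list(kind = "mclust", fit = fit))
  # manual diagonal Gaussian with variance floor (degenerate training data)
  list(kind = "diag", mu = colMeans(h),
       var = pmax(apply(h, 2L, stats::var), 1e-4))
}

gmm_logdens <- function(model, h) {
  if (model$kind == "mclust") {
    d <- mclust::dens(modelName = model$fit$modelName, data = h,
                      parameters = model$fit$parameters, logarithm = TRUE)
    return(as.numeric(d))
  }
  rowSums(vapply(seq_along(model$mu), function(k)
    stats::dnorm(h[, k], model$mu[k], sqrt(model$var[k]), log = TRUE),
    numeric(nrow(h))))
}

#' Fit foreground and background Gaussian mixture models from seeds
#'
#' Trains one GMM on the augmented feature vectors `h = [I, T]` of the
#' nodule seeds and one on the background seeds (diagonal covariances,
#' 2 components by default, single-Gaussian fallback for tiny seed sets),
#' then evaluates, for every pixel, the posterior probability of the
#' foreground under equal class priors, floored into `[eps, 1 - eps]`.
#'
#' @param seeds a `seed_set` from [acquire_seeds()]
#' @param field a [build_feature_field()] result
#' @param n_components mixture components per class (default 2)
#' @param rng_seed seed for the deterministic training subsample
#' @param eps posterior floor (default 1e-6)
#' @return object of class `gmm_pair`: list with the two models and the
#'   matrix `post_f` of foreground posteriors (image shape)
#' @export
fit_gmms <- function(seeds, field, n_components = 2L, rng_seed = 42L,
                     eps = 1e-6) {
  stopifnot(inherits(seeds, "seed_set"), inherits(field, "feature_field"))
  if (!any(seeds$nodule) || !any(seeds$background))
    stop("both seed classes must be non-empty", call. = FALSE)
  h_all <- cbind(I = as.vector(field$intensity01),
                 con = as.vector(field$glcm_contrast),
                 ene = as.vector(field$glcm_energy),
                 gab = as.vector(field$gabor),
                 lbp = as.vector(field$lbp))
  mf <- gmm_train(h_all[which(seeds$nodule), , drop = FALSE], n_components, rng_seed)
  mb <- gmm_train(h_all[which(seeds$background), , drop = FALSE], n_components, rng_seed)
  lf <- gmm_logdens(mf, h_all)
  lb <- gmm_logdens(mb, h_all)
  # equal class priors: P(F | h) = dF / (dF + dB), computed stably
  pf <- 1 / (1 + exp(pmin(pmax(lb - lf, -700), 700)))
  pf <- pmin(pmax(pf, eps), 1 - eps)
  structure(list(foreground = mf, background = mb,
                 post_f = array(pf, field$dim %||% c(length(pf), 1L)),
                 eps = eps),
            class = "gmm_pair")
}

#' Fuzzy membership weights for the label-constraint term
#'
#' For each seed pixel `i` with preassigned label `b(i)`,
#' `u_i = exp(-log P(h_i, b_i) / (log P(h_i, +1) + log P(h_i, -1)))`, the
#' GMM-posterior-based confidence that the preassigned label is right
#' (1 = confident, exp(-1) = confidently wrong). Non-seed pixels get 0 so
#' the constraint term vanishes off the seed set.
#'
#' @param gmms a [fit_gmms()] result
#' @param seeds a `seed_set`
#' @return numeric vector `u` over all pixels (column-major order)
#' @export
membership_weights <- function(gmms, seeds) {
  stopifnot(inherits(gmms, "gmm_pair"), inherits(seeds, "seed_set"))
  pf <- as.vector(gmms$post_f)
  if (any(pf <= 0 | pf >= 1))
    stop("internal error: posterior outside (0, 1) after flooring", call. = FALSE)
  pb <- 1 - pf
  b <- as.vector(seeds$b)
  u <- numeric(length(pf))
  on <- b != 0
  pcorrect <- ifelse(b[on] > 0, pf[on], pb[on])
  u[on] <- exp(-log(pcorrect) / (log(pf[on]) + log(pb[on])))
  u
}

#' Solve the label-constrained random-walker system
#'
#' Minimizes `E(F) = 1/2 F' L F + alpha/2 (F - b)' U (F - b)` by solving
#' the stationarity system `(D - W + alpha U) F = alpha U b` with a sparse
#' symmetric positive-definite factorization. `U = diag(u)` is non-zero
#' only on seeds and `b` is +1 / -1 on seeds, 0 elsewhere, so the maximum
#' principle bounds `F` in `[-1, 1]`.
#'
#' @param graph a `pixel_graph`
#' @param seeds a `seed_set`, or a numeric vector `b` of labels in
#'   `{-1, 0, +1}` over the nodes
#' @param u numeric membership weights over the nodes (0 off seeds)
#' @param alpha positive trade-off parameter (default 100)
#' @return object of class `rw_solution`: list with probability vector `F`
#'   (matrix when the graph has image shape), binary `mask` (`F >= 0`),
#'   `u`, `alpha`, solver `residual`
#' @export
solve_random_walker <- function(graph, seeds, u, alpha = 100) {
  stopifnot(inherits(graph, "pixel_graph"))
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  b <- if (inherits(seeds, "seed_set")) as.vector(seeds$b) else as.numeric(seeds)
  if (length(b) != graph$n || length(u) != graph$n)
    stop("b and u must have one entry per graph node", call. = FALSE)
  if (!any(u > 0 & b != 0))
    stop("no weighted seed: system is singular", call. = FALSE)
  A <- Matrix::forceSymmetric(graph$L + Matrix::Diagonal(graph$n, alpha * u))
  rhs <- alpha * u * b
  F <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e) stop("singular system: ", conditionMessage(e),
                                         call. = FALSE))
  res <- sqrt(sum((as.numeric(A %*% F) - rhs)^2))
  tol <- 1e-8 * max(sqrt(sum(rhs^2)), 1e-300)
  if (res > tol) {
    # conjugate-gradient style refinement via iterative solve fallback
    F2 <- tryCatch(as.numeric(Matrix::solve(A, Matrix::Matrix(rhs, ncol = 1),
                                            sparse = FALSE)),
                   error = function(e) F)
    res2 <- sqrt(sum((as.numeric(A %*% F2) - rhs)^2))
    if (res2 < res) { F <- F2; res <- res2 }
    if (res > tol)
      stop(sprintf("solver did not converge: residual %.3e > %.3e", res, tol),
           call. = FALSE)
  }
  new_rw_solution(F, u, alpha, graph, residual = res)
}

new_rw_solution <- function(F, u, alpha, graph, residual) {
  mask <- F >= 0
  if (!is.null(graph$dim)) {
    F <- array(F, graph$dim)
    mask <- array(mask, graph$dim)
  }
  structure(list(F = F, u = u, alpha = alpha, mask = mask,
                 residual = residual),
            class = "rw_solution")
}

#' @export
print.rw_solution <- function(x, ...) {
  cat(sprintf("<rw_solution> %d nodes, F in [%.3f, %.3f], %d foreground, residual %.2e\n",
              length(x$F), min(x$F), max(x$F), sum(x$mask), x$residual))
  invisible(x)
}

#' Conventional hard-seed random walker (comparison baseline)
#'
#' The classical seeded formulation: probabilities are fixed to the seed
#' labels and the harmonic extension is solved on the unlabeled nodes,
#' `L_U F_U = -B' F_M`. Unlabeled nodes in components that contain no seed
#' cannot be reached by any walk; they are assigned background with a
#' warning.
#'
#' @inheritParams solve_random_walker
#' @return an `rw_solution` (with `u` of 1 on seeds, `alpha = Inf`)
#' @export
conventional_random_walker <- function(graph, seeds) {
  stopifnot(inherits(graph, "pixel_graph"))
  b <- if (inherits(seeds, "seed_set")) as.vector(seeds$b) else as.numeric(seeds)
  if (!any(b > 0) || !any(b < 0))
    stop("both seed classes must be non-empty", call. = FALSE)
  m <- which(b != 0)
  un <- which(b == 0)
  F <- b
  if (length(un) > 0L) {
    # nodes with no path to a seed make L_UU singular; detach them first
    g <- igraph::graph_from_adjacency_matrix(graph$W > 0, mode = "undirected")
    comp <- igraph::components(g)$membership
    seeded_comps <- unique(comp[m])
    orphan <- un[!(comp[un] %in% seeded_comps)]
    if (length(orphan) > 0L) {
      warning(sprintf("%d unlabeled nodes are disconnected from all seeds; assigned background",
                      length(orphan)))
      F[orphan] <- -1
      un <- setdiff(un, orphan)
    }
    if (length(un) > 0L) {
      Luu <- graph$L[un, un, drop = FALSE]
      Lum <- graph$L[un, m, drop = FALSE]
      F[un] <- as.numeric(Matrix::solve(Matrix::forceSymmetric(Luu),
                                        -Lum %*% b[m]))
    }
  }
  u <- as.numeric(b != 0)
  new_rw_solution(F, u, Inf, graph, residual = 0)
}

#' Random-walker energy of a labelling
#'
#' `E(F) = 1/2 F' L F + alpha/2 (F - b)' U (F - b)`.
#'
#' @param graph a `pixel_graph`
#' @param F numeric probability vector
#' @param b seed label vector
#' @param u membership weights
#' @param alpha trade-off parameter
#' @return scalar energy
#' @export
rw_energy <- function(graph, F, b, u, alpha) {
  F <- as.vector(F)
  0.5 * as.numeric(Matrix::crossprod(F, graph$L %*% F)) +
    0.5 * alpha * sum(u * (F - b)^2)
}

#' Threshold a probability vector into a binary mask
#'
#' Foreground where `F >= 0` (ties go to foreground).
#'
#' @param F numeric vector or matrix of probabilities in `[-1, 1]`
#' @return logical vector or matrix
#' @export
assign_labels <- function(F) {
  if (!all(is.finite(F))) stop("F must be finite", call. = FALSE)
  F >= 0
}
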