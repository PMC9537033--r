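# Shared fixtures, built in code at test time.

# disk mask centred in an n x n frame
disk_mask <- function(n, radius, center = rep((n + 1) / 2, 2)) {
  sqrt((row(matrix(0, n, n)) - center[1])^2 +
       (col(matrix(0, n, n)) - center[2])^2) <= radius
}

# feature field with hand-set components (all matrices shape dm)
fake_field <- function(intensity, glcm_contrast = NULL, glcm_energy = NULL,
                       gabor = NULL, lbp = NULL, intensity01 = NULL) {
  z <- array(0, dim(intensity))
  structure(list(
    intensity = intensity,
    intensity01 = intensity01 %||% (intensity / 255),
    glcm_contrast = glcm_contrast %||% z,
    glcm_energy = glcm_energy %||% z,
    gabor = gabor %||% z,
    lbp = lbp %||% z,
    lbp_code = (lbp %||% z) * 9L,
    dim = dim(intensity)
  ), class = "feature_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seed set from explicit logical masks
fake_seeds <- function(nodule, background) {
  b <- array(0, dim(nodule))
  b[nodule] <- 1
  b[background] <- -1
  structure(list(nodule = nodule, background = background, b = b,
                 O = nodule, core = nodule),
            class = "seed_set")
}

# random 8-connected grid graph with uniform(0,1] edge weights
rand_grid_graph <- function(nr, nc, seed) {
  set.seed(seed)
  n <- nr * nc
  pairs <- ggoseg:::neighbour_pairs(seq_len(n), c(nr, nc))
  pairs <- pairs[pairs[, "from"] < pairs[, "to"], , drop = FALSE]
  w <- runif(nrow(pairs), min = 1e-3, max = 1)
  W <- Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                            j = c(pairs[, 2], pairs[, 1]),
                            x = c(w, w), dims = c(n, n))
  pixel_graph(W)
}

# random seed labelling: at least one +1 and one -1 seed
rand_seed_labels <- function(n, n_seeds = max(2L, n %/% 10L)) {
  idx <- sample.int(n, n_seeds)
  b <- numeric(n)
  b[idx] <- sample(c(-1, 1), n_seeds, replace = TRUE)
  b[idx[1L]] <- 1
  b[idx[2L]] <- -1
  b
}

# dense direct solve of (L + alpha U) F = alpha U b (independent oracle)
dense_rw_solve <- function(graph, b, u, alpha) {
  A <- as.matrix(graph$L) + diag(alpha * u, graph$n)
  solve(A, alpha * u * b)
}

# path to the packaged printed-table fixtures
table_fixture <- function(name) {
  system.file("extdata", name, package = "ggoseg", mustWork = TRUE)
}
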