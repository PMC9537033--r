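test_that("affinity matrix combines spatial, intensity and texture kernels", {
  f <- fake_field(intensity = matrix(100, 3, 3))  # identical features
  g <- affinity_matrix(f)
  W <- as.matrix(g$W)
  expect_equal(W[1, 4], exp(-1))        # 4-adjacent, spatial term only
  expect_equal(W[1, 5], exp(-2))        # diagonal neighbours
  expect_equal(W[1, 9], 0)              # not adjacent
  expect_equal(diag(W), rep(0, 9))
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
  # Laplacian row sums vanish
  expect_lt(max(abs(Matrix::rowSums(g$L))), 1e-9)

  # intensity term: w = exp(-1) * exp(-beta_i * dI^2)
  I01 <- matrix(0, 3, 3); I01[, 2] <- 0.1
  f2 <- fake_field(intensity = I01 * 255, intensity01 = I01)
  g2 <- affinity_matrix(f2, beta_i = 90)
  expect_equal(as.matrix(g2$W)[1, 4], exp(-1) * exp(-90 * 0.01))
  g3 <- affinity_matrix(f2, beta_i = 1)
  expect_equal(as.matrix(g3$W)[1, 4], exp(-1) * exp(-0.01))
  # texture term
  Tg <- matrix(0, 3, 3); Tg[, 2] <- 1
  f4 <- fake_field(intensity = matrix(0, 3, 3), gabor = Tg)
  expect_equal(as.matrix(affinity_matrix(f4)$W)[1, 4], exp(-1) * exp(-1))
})

test_that("GMM pair separates well-separated clusters and is deterministic", {
  set.seed(41)
  n <- 20
  I <- matrix(0, n, n)
  I[, 1:10] <- 10 + rnorm(10 * n, 0, 0.5)   # foreground features around 10
  I[, 11:20] <- rnorm(10 * n, 0, 0.5)       # background around 0
  f <- fake_field(intensity = I * 20, intensity01 = I / 10)
  nod <- col(I) <= 8
  bg <- col(I) >= 13
  seeds <- fake_seeds(nod, bg)
  gm <- fit_gmms(seeds, f, rng_seed = 7)
  expect_true(all(gm$post_f[nod] > 0.5))
  expect_true(all(gm$post_f[bg] < 0.5))
  expect_true(all(gm$post_f >= gm$eps & gm$post_f <= 1 - gm$eps))
  gm2 <- fit_gmms(seeds, f, rng_seed = 7)
  expect_identical(gm$post_f, gm2$post_f)
  expect_error(fit_gmms(fake_seeds(nod, matrix(FALSE, n, n)), f), "non-empty")
})

test_that("identical training data for both classes gives 0.5 posteriors", {
  f <- fake_field(intensity = matrix(100, 10, 10))
  seeds <- fake_seeds(col(matrix(0, 10, 10)) <= 3, col(matrix(0, 10, 10)) >= 8)
  gm <- fit_gmms(seeds, f)
  expect_equal(as.vector(gm$post_f), rep(0.5, 100), tolerance = 1e-9)
})

test_that("membership weights implement the log-posterior ratio form", {
  dm <- c(2, 2)
  mk_gmm <- function(pf) structure(list(post_f = matrix(pf, 2, 2), eps = 1e-6),
                                   class = "gmm_pair")
  seeds <- fake_seeds(matrix(c(TRUE, FALSE, FALSE, FALSE), 2),
                      matrix(c(FALSE, TRUE, FALSE, FALSE), 2))
  # symmetric posteriors: u = exp(-1/2) on every seed
  u <- membership_weights(mk_gmm(0.5), seeds)
  expect_equal(u[1], exp(-0.5))
  expect_equal(u[2], exp(-0.5))
  expect_equal(u[3:4], c(0, 0))      # non-seeds get 0
  # confident correct label: u -> 1
  u2 <- membership_weights(mk_gmm(1 - 1e-6), seeds)
  expect_gt(u2[1], 0.999)
  # confident wrong label: u -> exp(-1)
  expect_equal(u2[2], exp(-1), tolerance = 1e-4)
  u3 <- membership_weights(mk_gmm(1e-6), seeds)
  expect_equal(u3[1], exp(-1), tolerance = 1e-4)
})

test_that("label-constrained solve matches the dense 2x2 oracle", {
  W <- matrix(c(0, exp(-1), exp(-1), 0), 2)
  g <- pixel_graph(W)
  b <- c(1, -1); u <- c(1, 1)
  sol <- solve_random_walker(g, b, u, alpha = 100)
  oracle <- dense_rw_solve(g, b, u, 100)
  expect_equal(as.vector(sol$F), as.vector(oracle), tolerance = 1e-10)
  expect_lt(abs(sol$F[1] - 1), 0.02)
  expect_lt(abs(sol$F[2] + 1), 0.02)
  expect_identical(as.vector(sol$mask), c(TRUE, FALSE))
})

test_that("alpha -> infinity pins the solution to the labels on seeds", {
  g <- rand_grid_graph(6, 8, seed = 50)
  set.seed(51)
  b <- rand_seed_labels(g$n)
  u <- as.numeric(b != 0)
  sol <- solve_random_walker(g, b, u, alpha = 1e8)
  on <- b != 0
  expect_lt(max(abs(sol$F[on] - b[on])), 1e-6)
})

test_that("single-class seeding floods the connected component", {
  g <- rand_grid_graph(5, 5, seed = 52)
  b <- numeric(25); b[c(3, 12)] <- 1
  u <- as.numeric(b != 0)
  sol <- solve_random_walker(g, b, u, alpha = 100)
  expect_true(all(sol$F >= -1e-12 & sol$F <= 1 + 1e-12))
  expect_true(all(sol$mask))
})

test_that("solver validates its inputs", {
  g <- rand_grid_graph(4, 4, seed = 53)
  expect_error(solve_random_walker(g, numeric(16), numeric(16), 100), "seed")
  expect_error(solve_random_walker(g, rand_seed_labels(16), rep(1, 16), -1),
               "alpha")
})

test_that("increasing alpha tightens the fit to the seed labels", {
  g <- rand_grid_graph(8, 10, seed = 54)
  set.seed(55)
  b <- rand_seed_labels(g$n, 12)
  u <- runif(g$n) * (b != 0)
  u[b != 0] <- pmax(u[b != 0], 0.1)
  dev <- sapply(c(1, 10, 100, 1000, 1e4), function(a)
    sum(abs(solve_random_walker(g, b, u, a)$F[b != 0] - b[b != 0])))
  expect_true(all(diff(dev) <= 1e-9))
})

test_that("conventional random walker solves the harmonic Dirichlet problem", {
  # path of 3 nodes, ends seeded +1/-1, equal weights: middle is 0
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 0.5
  sol <- conventional_random_walker(pixel_graph(W), c(1, 0, -1))
  expect_equal(as.vector(sol$F), c(1, 0, -1), tolerance = 1e-12)
  # all-seeded graph returns b exactly
  sol2 <- conventional_random_walker(pixel_graph(W), c(1, -1, 1))
  expect_identical(as.vector(sol2$F), c(1, -1, 1))
  # 4-cycle with opposite seeds: unlabeled nodes sit at 0 by symmetry
  W4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W4[e[1], e[2]] <- W4[e[2], e[1]] <- 1
  sol4 <- conventional_random_walker(pixel_graph(W4), c(1, 0, -1, 0))
  expect_equal(as.vector(sol4$F)[c(2, 4)], c(0, 0), tolerance = 1e-12)
  expect_error(conventional_random_walker(pixel_graph(W4), c(1, 0, 0, 0)),
               "both seed classes")
})

test_that("unlabeled nodes disconnected from all seeds become background", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1      # component {1,2} carries both seeds
  W[3, 4] <- W[4, 3] <- 1      # component {3,4} has none
  expect_warning(sol <- conventional_random_walker(pixel_graph(W), c(1, -1, 0, 0)),
                 "disconnected")
  expect_equal(as.vector(sol$F)[3:4], c(-1, -1))
})

test_that("assign_labels thresholds at zero with ties to foreground", {
  expect_identical(assign_labels(c(0.3, -0.2, 0)), c(TRUE, FALSE, TRUE))
  expect_identical(assign_labels(c(-0.5, -1)), c(FALSE, FALSE))
  set.seed(56)
  F <- matrix(runif(36, -1, 1), 6)
  expect_identical(assign_labels(F), F >= 0)
  expect_error(assign_labels(c(1, NaN)), "finite")
})

test_that("soft solution converges to the hard-seed walker as alpha grows", {
  g <- rand_grid_graph(8, 8, seed = 57)
  set.seed(58)
  b <- rand_seed_labels(g$n, 10)
  soft <- solve_random_walker(g, b, as.numeric(b != 0), alpha = 1e6)
  hard <- conventional_random_walker(g, b)
  expect_lt(max(abs(soft$F - hard$F)), 1e-3)
})

test_that("returned solution minimizes the constrained energy locally", {
  g <- rand_grid_graph(6, 6, seed = 59)
  set.seed(60)
  b <- rand_seed_labels(g$n, 8)
  u <- as.numeric(b != 0) * runif(g$n, 0.5, 1)
  sol <- solve_random_walker(g, b, u, alpha = 100)
  e0 <- rw_energy(g, sol$F, b, u, 100)
  for (k in 1:25) {
    d <- rnorm(g$n); d <- d / sqrt(sum(d^2)) * 0.01
    expect_gt(rw_energy(g, as.vector(sol$F) + d, b, u, 100), e0)
  }
})
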