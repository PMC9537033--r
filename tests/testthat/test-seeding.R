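test_that("adaptive threshold separates a bimodal image exactly", {
  img <- matrix(50, 20, 20)
  img[6:12, 7:15] <- 200
  mask <- adaptive_threshold_mask(ct_slice(img))
  expect_identical(mask, img == 200)
  expect_warning(m0 <- adaptive_threshold_mask(ct_slice(matrix(5, 8, 8))),
                 "constant")
  expect_false(any(m0))
})

test_that("adaptive threshold recovers most of a phantom nodule", {
  ph <- make_phantom(phantom_spec(seed = 21))
  sl <- coherence_filter(normalize_intensity(ph$image$pixels))
  mask <- adaptive_threshold_mask(sl)
  expect_gte(sum(mask & ph$truth) / sum(ph$truth | mask), 0.5)
})

test_that("refine_initial_mask keeps the single component nearest the centre", {
  m <- matrix(FALSE, 30, 30)
  m[12:21, 12:21] <- TRUE            # 100-pixel blob at the centre
  m[2, 2] <- m[29, 3] <- m[3, 28] <- TRUE  # three specks
  out <- refine_initial_mask(m)
  expect_false(any(out[cbind(c(2, 29, 3), c(2, 3, 28))]))  # specks gone
  expect_equal(sum(out), 100)
  expect_true(all(which(out) %in% which(m)))

  # two equal blobs: the one at the ROI centre is retained
  m2 <- matrix(FALSE, 30, 30)
  m2[13:18, 13:18] <- TRUE
  m2[2:7, 22:27] <- TRUE
  out2 <- refine_initial_mask(m2)
  expect_true(out2[15, 15] && !out2[4, 24])
  expect_error(refine_initial_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("opening leaves a solid disk essentially unchanged", {
  d <- disk_mask(40, 10)
  out <- refine_initial_mask(d)
  expect_gte(sum(out & d) / sum(out | d), 0.98)
})

test_that("geodesic distance matches a Dijkstra oracle on an L-shaped region", {
  region <- matrix(FALSE, 12, 12)
  region[2:10, 2:4] <- TRUE
  region[8:10, 2:10] <- TRUE
  src <- matrix(FALSE, 12, 12); src[2, 2] <- TRUE
  g <- ggoseg:::cpp_geodesic(region, src)
  # Dijkstra on the 8-connected grid restricted to the region
  idx <- which(region)
  dist <- setNames(rep(Inf, length(idx)), idx)
  dist[as.character(which(src))] <- 0
  unvisited <- idx
  while (length(unvisited) > 0) {
    i <- unvisited[which.min(dist[as.character(unvisited)])]
    unvisited <- setdiff(unvisited, i)
    nb <- ggoseg:::neighbour_pairs(i, c(12L, 12L))
    for (k in seq_len(nrow(nb))) {
      j <- nb[k, "to"]
      if (!region[j]) next
      step <- if (abs((i - 1) %% 12 - (j - 1) %% 12) == 1 &&
                  abs((i - 1) %/% 12 - (j - 1) %/% 12) == 1) sqrt(2) else 1
      nd <- dist[as.character(i)] + step
      if (nd < dist[as.character(j)]) dist[as.character(j)] <- nd
    }
  }
  expect_equal(unname(g[idx]), unname(dist[as.character(idx)]), tolerance = 1e-12)
  expect_true(all(is.na(g[!region])))
})

test_that("geodesic_core extracts a central band and handles degenerate regions", {
  d <- disk_mask(31, 10)
  gc <- geodesic_core(d, T = 2)
  expect_true(all(gc$core[!d] == FALSE))      # core inside O
  ctr_dist <- sqrt((row(d) - 16)^2 + (col(d) - 16)^2)
  expect_true(all(ctr_dist[gc$core] <= 3.6))  # disk-like core near the centre
  expect_gte(sum(gc$core), 1)
  expect_equal(gc$M, max(gc$distance, na.rm = TRUE))

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_warning(gc1 <- geodesic_core(one, T = 2), "thin")
  expect_identical(gc1$core, one)

  # T >= M: the whole disk is the band
  gcall <- geodesic_core(d, T = 99)
  expect_identical(gcall$core, d)
  expect_error(geodesic_core(matrix(FALSE, 4, 4)), "non-empty")
})

test_that("local_similarity follows the product form and is symmetric", {
  f <- fake_field(intensity = matrix(100, 5, 5),
                  gabor = matrix(0, 5, 5))
  expect_equal(local_similarity(c(1, 1), c(1, 2), f), 0)
  # texture-diff norm 2, intensity diff 0 -> S = 4 * e^0
  f2 <- fake_field(intensity = matrix(100, 5, 5),
                   glcm_contrast = matrix(rep(c(0, 2), length.out = 25), 5))
  i <- c(1, 1); j <- c(1, 2)
  td <- (f2$glcm_contrast[1, 1] - f2$glcm_contrast[1, 2])^2
  expect_equal(local_similarity(i, j, f2), td * exp(0))
  expect_equal(td, 4)
  # symmetry for random fields
  set.seed(31)
  fr <- fake_field(intensity = matrix(runif(25, 0, 255), 5),
                   glcm_contrast = matrix(runif(25), 5),
                   gabor = matrix(runif(25), 5))
  for (k in 1:5) {
    i <- c(sample(0:3, 1), sample(0:3, 1))
    j <- i + sample(list(c(0, 1), c(1, 0), c(1, 1)), 1)[[1]]
    expect_equal(local_similarity(i, j, fr), local_similarity(j, i, fr))
  }
  expect_error(local_similarity(c(0, 0), c(0, 2), fr), "adjacent")
})

test_that("similarity exponent is clipped to avoid overflow", {
  f <- fake_field(intensity = matrix(c(0, 255), 2, 2),
                  glcm_contrast = matrix(c(0, 1), 2, 2))
  s <- local_similarity(c(0, 0), c(1, 0), f)
  expect_true(is.finite(s))
  expect_equal(s, 1 * exp(50))
})

test_that("nodule growth: kappa = 0 adds nothing; homogeneous disk fills", {
  n <- 40
  img <- matrix(60, n, n); img[disk_mask(n, 10)] <- 180
  sl <- ct_slice(img)
  f <- build_feature_field(sl)
  O <- disk_mask(n, 10)
  core <- geodesic_core(O, 2)$core
  expect_identical(grow_nodule_seeds(O, core, f, kappa = 0), core)
  grown <- grow_nodule_seeds(O, core, f, kappa = 10)
  expect_true(all(grown[core]))               # superset of the core
  # contained in a modest dilation of O
  big <- disk_mask(n, 14)
  expect_true(all(big[grown]))
  # interior well covered
  expect_gte(sum(grown & disk_mask(n, 8)) / sum(disk_mask(n, 8)), 0.9)
  expect_error(grow_nodule_seeds(O, matrix(FALSE, n, n), f), "core")
})

test_that("nodule growth crosses into a second similar lobe", {
  n <- 40
  img <- matrix(60, n, n)
  d <- disk_mask(n, 11)
  img[d & col(img) <= 20] <- 180
  img[d & col(img) > 20] <- 181      # second plateau within kappa-similarity
  f <- build_feature_field(ct_slice(img))
  core <- matrix(FALSE, n, n); core[19:22, 12:15] <- TRUE  # inside left lobe
  grown <- grow_nodule_seeds(d, core, f, kappa = 10)
  expect_gte(sum(grown[d & col(img) > 22]), 20)  # seeds appear in the right lobe
})

test_that("background growth stays outside O and grows with T1", {
  ph <- make_phantom(phantom_spec(size = 96, radius = 14, noise = 0, seed = 5))
  sl <- coherence_filter(normalize_intensity(ph$image$pixels))
  f <- build_feature_field(sl)
  O <- refine_initial_mask(adaptive_threshold_mask(sl))
  core <- geodesic_core(O, 2)$core
  counts <- sapply(c(20, 60, 100), function(t1)
    sum(grow_background_seeds(O, core, f, T1 = t1)))
  expect_true(all(diff(counts) >= 0))          # non-decreasing in T1
  vb <- grow_background_seeds(O, core, f, T1 = 100)
  expect_false(any(vb & O))                    # all outside O
  # eta = Inf admits nothing before the fallback
  expect_equal(sum(grow_background_seeds(O, core, f, eta = Inf, fallback = FALSE)), 0)
  expect_warning(ring <- grow_background_seeds(O, core, f, eta = Inf),
                 "fallback|border")
  expect_true(any(ring))
  expect_false(any(ring & O))
  # optional cap on the seed count
  capped <- grow_background_seeds(O, core, f, T1 = 100, max_seeds = 50)
  expect_lte(sum(capped), 50)
})

test_that("acquire_seeds yields disjoint, pure seed sets on a clean phantom", {
  ph <- make_phantom(phantom_spec(noise = 0, seed = 9))
  sl <- coherence_filter(normalize_intensity(ph$image$pixels))
  f <- build_feature_field(sl)
  seeds <- acquire_seeds(sl, f)
  expect_s3_class(seeds, "seed_set")
  expect_false(any(seeds$nodule & seeds$background))
  expect_true(all(seeds$core[seeds$core] & seeds$O[seeds$core]))  # core in O
  expect_true(all(seeds$nodule[seeds$core]))                     # V_F >= core
  expect_identical(seeds$b == 1, seeds$nodule)
  expect_identical(seeds$b == -1, seeds$background)
  # >= 95% purity on the clean phantom
  expect_gte(mean(ph$truth[seeds$nodule]), 0.95)
  expect_gte(mean(!ph$truth[seeds$background]), 0.95)
})

test_that("seed acquisition is deterministic", {
  ph <- make_phantom(phantom_spec(noise = 8, seed = 14))
  sl <- coherence_filter(normalize_intensity(ph$image$pixels))
  f <- build_feature_field(sl)
  s1 <- acquire_seeds(sl, f)
  s2 <- acquire_seeds(sl, f)
  expect_identical(s1$nodule, s2$nodule)
  expect_identical(s1$background, s2$background)
})
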