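test_that("homography application covers identity, translation, projection", {
  p <- c(3.5, -2, 7)
  expect_equal(apply_homography(identity_homography(), p), p)
  expect_equal(apply_homography(translation_homography(c(1, -2, 0.5)), p),
               p + c(1, -2, 0.5))
  # projective scaling: last row (0,0,0,2) halves all coordinates
  H <- diag(4); H[4, 4] <- 2
  expect_equal(apply_homography(H, p), p / 2)
  # degenerate projection
  Hd <- diag(4); Hd[4, ] <- c(0, 0, 0, 1e-12)
  expect_error(apply_homography(Hd, p), "degenerate")
  expect_error(homography(matrix(0, 4, 4)), "h44|H\\[4,4\\]|matrix")
})

test_that("atlas sampling is trilinear with a configurable outside value", {
  a <- array(0.5, c(4, 4, 4))
  a[2, 3, 2] <- 0.9
  atlas <- prob_atlas(a)
  # exact lattice node (0-based coordinate (1,2,1))
  expect_equal(sample_atlas(atlas, c(1, 2, 1)), 0.9)
  # midpoint between nodes valued 0.2 and 0.6
  b <- array(0.2, c(3, 3, 3)); b[2, , ] <- 0.6
  expect_equal(sample_atlas(prob_atlas(b), c(0.5, 1, 1)), 0.4)
  # outside the lattice
  expect_equal(sample_atlas(atlas, c(-50, 0, 0)), 0)
  expect_equal(sample_atlas(atlas, c(100, 100, 100), outside = 0.25), 0.25)
})

test_that("fidelity energy matches its closed form and a naive double loop", {
  const <- prob_atlas(array(0.5, c(10, 10, 10)))
  s <- array(0L, c(8, 8, 8))
  s[2:3, 2, 2] <- 1L       # 2 organ seeds
  s[6:8, 6, 6] <- 2L       # 3 background seeds
  seeds <- seed_image(s, alpha = 1)
  expect_equal(fidelity_energy(const, seeds, identity_homography()),
               0.5 * (1 * 3 - 2))
  seeds2 <- seed_image(s, alpha = 0.4)
  expect_equal(fidelity_energy(const, seeds2, identity_homography()),
               0.5 * (0.4 * 3 - 2))
  # naive recomputation voxel by voxel on a random atlas and transform
  set.seed(7)
  atlas <- prob_atlas(array(runif(6 * 6 * 6), c(6, 6, 6)))
  H <- diag(4); H[1:3, 4] <- c(0.3, -0.2, 0.1); H[1, 2] <- 0.05
  h <- homography(H)
  naive <- 0
  num <- seed_numeric(seeds)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (num[i, j, k] == 0) next
    X <- apply_homography(h, c(i, j, k) - 1)
    naive <- naive + sample_atlas(atlas, X) * num[i, j, k]
  }
  expect_equal(fidelity_energy(atlas, seeds, h), naive, tolerance = 1e-12)
  expect_error(fidelity_energy(atlas, seed_image(array(0L, c(2, 2, 2))),
                               identity_homography()))
})

test_that("a zero-gradient start is recognized as a fixed point", {
  # constant atlas, seeds strictly interior: the energy is locally flat and
  # the fit must stop immediately, unchanged
  const <- prob_atlas(array(0.5, c(8, 8, 8)))
  s <- array(0L, c(6, 6, 6)); s[3, 3, 3] <- 1L; s[5, 5, 5] <- 2L
  seeds <- seed_image(s)
  fit <- fit_homography(const, seeds, init = identity_homography(),
                        mode = "projective")
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2)
  expect_equal(fit$homography$H, diag(4), tolerance = 1e-9)
})

test_that("accepted energy trajectory is non-increasing", {
  set.seed(13)
  mask <- label_mask(atlascut:::ellipsoid_mask(c(24, 24, 24), c(11, 12, 11),
                                               c(7, 6, 5)))
  atlas <- prob_atlas(sigmoid_probability(signed_distance(mask), 1))
  seeds <- dense_oracle_seeds(mask)
  fit <- fit_homography(atlas, seeds, init = translation_homography(c(3, -2, 2)),
                        mode = "projective")
  expect_true(all(diff(fit$trajectory) <= 0))
  expect_lt(fit$energy, fit$trajectory[1])
})

test_that("translation-constrained fit recovers a known displacement", {
  set.seed(17)
  sh <- c(28, 28, 28)
  mask <- label_mask(atlascut:::ellipsoid_mask(sh, c(13, 14, 13), c(8, 6, 5)))
  t_true <- c(3, -2, 2)
  am <- array(as.integer(shift_array(mask$data, t_true)), sh)
  atlas <- prob_atlas(sigmoid_probability(signed_distance(label_mask(am)), 1))
  seeds <- dense_oracle_seeds(mask)
  fit <- fit_homography(atlas, seeds, mode = "translation")
  expect_lt(fit$energy, fit$trajectory[1])
  expect_lt(max(abs(fit$homography$H[1:3, 4] - t_true)), 0.5)
  # grid-search oracle confirms the energy minimum sits at the recovery
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  E_grid <- apply(offsets, 1, function(d)
    fidelity_energy(atlas, seeds, translation_homography(t_true + d)))
  expect_lte(fit$energy, min(E_grid) + 1e-6)
})

test_that("warping the atlas onto a grid matches pointwise sampling", {
  set.seed(23)
  atlas <- prob_atlas(array(runif(8 * 8 * 8), c(8, 8, 8)))
  # identity on the lattice shape reproduces the atlas
  w <- warp_atlas_to_image(atlas, identity_homography(), c(8, 8, 8))
  expect_equal(w, atlas$data, tolerance = 1e-12)
  # +1 translation in x shifts the sampled field by -1 (interior)
  w2 <- warp_atlas_to_image(atlas, translation_homography(c(1, 0, 0)),
                            c(8, 8, 8))
  expect_equal(w2[1:7, , ], atlas$data[2:8, , ], tolerance = 1e-12)
  # arbitrary homography: spot-check random voxels against the composition
  H <- diag(4); H[1:3, 4] <- c(0.4, -0.3, 0.2); H[2, 1] <- 0.03
  H[4, 1] <- 1e-3
  h <- homography(H)
  w3 <- warp_atlas_to_image(atlas, h, c(6, 7, 5))
  for (i in 1:10) {
    p <- c(sample(0:5, 1), sample(0:6, 1), sample(0:4, 1))
    expect_equal(w3[p[1] + 1, p[2] + 1, p[3] + 1],
                 sample_atlas(atlas, apply_homography(h, p)),
                 tolerance = 1e-12)
  }
})

test_that("after fitting, the warped prior separates organ from background seeds", {
  set.seed(29)
  cohort <- make_cohort(4, confounded_phantom_spec(c(36, 36, 24), rng_seed = 5))
  atlas <- build_atlas(lapply(cohort[-1], `[[`, "mask"),
                       atlas_config(lattice = c(24, 24, 12), margin = 0.25))
  case <- cohort[[1]]
  seeds <- simulate_seeds(case$mask, rng_seed = 9)
  fit <- fit_homography(atlas, seeds, mode = "projective",
                        opts = fit_options(max_iters = 200))
  prior <- warp_atlas_to_image(atlas, fit$homography, dim(case$volume$data))
  sc <- seed_coords(seeds)
  organ_mean <- mean(prior[sc$organ + 1])
  bg_mean <- mean(prior[sc$background + 1])
  expect_gt(organ_mean, bg_mean)
  expect_gt(organ_mean, 0.5)
})
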