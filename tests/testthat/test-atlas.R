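test_that("bounding box is the tightest half-open index box", {
  m <- array(0L, c(10, 8, 7))
  m[4, 5, 6] <- 1L # 0-based (3, 4, 5)
  bb <- bounding_box(label_mask(m))
  expect_identical(bb$lo, c(3L, 4L, 5L))
  expect_identical(bb$hi, c(4L, 5L, 6L))
  m[1, 1, 1] <- 1L
  m[10, 1, 1] <- 1L
  bb2 <- bounding_box(label_mask(m))
  expect_identical(bb2$lo, c(0L, 0L, 0L))
  expect_identical(bb2$hi[1], 10L)
  full <- label_mask(array(1L, c(4, 3, 2)))
  # all-foreground: box equals the volume extents
  bbf <- bounding_box(full)
  expect_identical(bbf$lo, c(0L, 0L, 0L))
  expect_identical(bbf$hi, c(4L, 3L, 2L))
  expect_error(bounding_box(label_mask(array(0L, c(2, 2, 2)))), "foreground")
})

test_that("resampling maps the box onto the lattice, binarily", {
  cfg <- atlas_config(lattice = c(8, 8, 8))
  # identity resample: box already of lattice shape
  set.seed(5)
  m <- random_mask(c(8, 8, 8))
  m$data[1, 1, 1] <- 1L; m$data[8, 8, 8] <- 1L # pin box to full volume
  res <- resample_to_lattice(m, list(lo = c(0L, 0L, 0L), hi = c(8L, 8L, 8L)),
                             cfg)
  expect_identical(res$data, m$data)
  # half-size solid cube maps to roughly half the lattice per axis
  cube <- array(0L, c(12, 12, 12))
  cube[1:6, 1:6, 1:6] <- 1L
  res2 <- resample_to_lattice(label_mask(cube),
                              list(lo = c(0L, 0L, 0L), hi = c(12L, 12L, 12L)),
                              cfg)
  per_axis <- apply(res2$data, 1, max)
  expect_true(all(abs(sum(per_axis) - 4) <= 1)) # ~half of 8, 1-voxel tolerance
  expect_true(all(res2$data %in% c(0L, 1L)))
  # degenerate box
  expect_error(resample_to_lattice(m, list(lo = c(0L, 0L, 0L),
                                           hi = c(0L, 8L, 8L)), cfg),
               "degenerate")
})

test_that("nearest-neighbour resampling agrees with an independent oracle", {
  cfg <- atlas_config(lattice = c(6, 5, 4))
  set.seed(11)
  for (i in 1:5) {
    m <- random_mask(c(9, 7, 8))
    bb <- bounding_box(m)
    got <- resample_to_lattice(m, bb, cfg)
    want <- brute_resample(m$data, bb$lo, bb$hi, cfg$lattice)
    expect_identical(got$data, want)
  }
})

test_that("signed distance matches brute force and flips with the mask", {
  set.seed(21)
  for (i in 1:8) {
    m <- random_mask(c(5, 5, 5))
    d <- signed_distance(m)
    expect_equal(d, brute_signed_distance(m$data), tolerance = 1e-12)
    comp <- label_mask(1L - m$data)
    expect_equal(signed_distance(comp), -d, tolerance = 1e-12)
  }
  # adjacent fg/bg voxels both sit at |d| = 1
  m <- array(0L, c(4, 4, 4)); m[1:2, , ] <- 1L
  d <- signed_distance(label_mask(m))
  expect_equal(d[2, 1, 1], 1)
  expect_equal(d[3, 1, 1], -1)
  # centre of a ball is about one radius inside
  ball <- array(0L, c(21, 21, 21))
  ctr <- which(array(TRUE, c(21, 21, 21)), arr.ind = TRUE)
  ball[matrix(ctr[rowSums((ctr - 11)^2) <= 64, ], ncol = 3)] <- 1L
  d <- signed_distance(label_mask(ball))
  expect_gt(d[11, 11, 11], 7)
  expect_lt(d[11, 11, 11], 9.5)
  expect_error(signed_distance(label_mask(array(1L, c(3, 3, 3)))), "both")
})

test_that("sigmoid probability has midpoint 0.5, symmetric tails", {
  d <- seq(-20, 20, by = 0.25)
  for (gain in c(0.3, 1, 4)) {
    p <- sigmoid_probability(d, gain)
    expect_equal(sigmoid_probability(0, gain), 0.5)
    expect_equal(p + sigmoid_probability(-d, gain), rep(1, length(d)))
  }
  # strictly inside (0,1) at any finite distance small enough not to
  # underflow double precision
  p <- sigmoid_probability(seq(-8, 8, by = 0.25), 4)
  expect_true(all(p > 0 & p < 1))
  expect_equal(sigmoid_probability(1e4, 1), 1) # float saturation far out
  expect_error(sigmoid_probability(d, -1), "positive")
})

test_that("larger gain sharpens each case's probability map", {
  set.seed(31)
  m <- random_mask(c(6, 6, 6))
  d <- signed_distance(m)
  p1 <- sigmoid_probability(d, 0.5)
  p2 <- sigmoid_probability(d, 2)
  expect_true(all(p2[d > 0] >= p1[d > 0]))
  expect_true(all(p2[d < 0] <= p1[d < 0]))
})

test_that("atlas is the voxelwise mean of per-case sigmoid maps", {
  cfg <- atlas_config(lattice = c(8, 8, 6), gain = 1.3)
  set.seed(41)
  masks <- lapply(1:4, function(i) random_mask(c(9, 8, 7)))
  atlas <- build_atlas(masks, cfg)
  # independent second path: explicit per-case maps averaged by Reduce
  maps <- lapply(masks, function(m) {
    res <- brute_resample(m$data, bounding_box(m)$lo, bounding_box(m)$hi,
                          cfg$lattice)
    sigmoid_probability(brute_signed_distance(res), cfg$gain)
  })
  want <- Reduce(`+`, maps) / length(maps)
  expect_equal(atlas$data, want, tolerance = 1e-12)
  # single case: atlas equals that case's sigmoid map; duplicates: idempotent
  a1 <- build_atlas(masks[1], cfg)
  expect_equal(a1$data, maps[[1]], tolerance = 1e-12)
  a2 <- build_atlas(list(masks[[1]], masks[[1]]), cfg)
  expect_equal(a2$data, a1$data, tolerance = 1e-12)
  expect_true(all(atlas$data > 0 & atlas$data < 1))
  expect_error(build_atlas(list(), cfg), "at least one")
})
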