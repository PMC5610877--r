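test_that("boundary weight follows the Gaussian-contrast form", {
  expect_equal(boundary_weight(5, 5, 1), 1)
  expect_equal(boundary_weight(0, 1, 1, sigma = 1 / sqrt(2)), exp(-1))
  expect_equal(boundary_weight(0, 1, 2, sigma = 1 / sqrt(2)), exp(-1) / 2)
  expect_lt(boundary_weight(0, 100, 1, sigma = 1), 1e-100)
  expect_error(boundary_weight(1, 2, 0), "dist")
  expect_error(boundary_weight(1, 2, 1, sigma = -1), "sigma")
})

test_that("min-cut labeling matches exhaustive enumeration on tiny volumes", {
  set.seed(77)
  cfg_pool <- list(graph_cut_config(lam = 1), graph_cut_config(lam = 0.3),
                   graph_cut_config(lam = 2, connectivity = 26),
                   graph_cut_config(lam = 1, sigma = 0.2))
  for (trial in 1:25) {
    dims <- c(sample(2:4, 1), sample(2:2, 1), sample(1:2, 1))
    n <- prod(dims)
    vol <- volume3d(array(runif(n, 0, 100), dims))
    terms <- list(r_pc = array(runif(n, 0, 5), dims),
                  r_bg = array(runif(n, 0, 5), dims))
    organ_idx <- sample(n, 1)
    bg_idx <- sample(setdiff(seq_len(n), organ_idx), 1)
    s <- array(0L, dims); s[organ_idx] <- 1L; s[bg_idx] <- 2L
    seeds <- seed_image(s)
    cfg <- cfg_pool[[1 + trial %% length(cfg_pool)]]
    cut <- build_and_cut(vol, seeds, terms, cfg)
    got <- labeling_energy(vol, cut, terms, cfg)
    want <- enum_min_energy(vol, terms, cfg, organ_idx, bg_idx)
    expect_equal(got, want, tolerance = 1e-9)
    # the reported cut value is the attained energy
    expect_equal(attr(cut, "cut_value"), got, tolerance = 1e-9)
    # hard constraints hold
    expect_equal(cut$data[organ_idx], 1L)
    expect_equal(cut$data[bg_idx], 0L)
  }
})

test_that("the flow value agrees with an independent max-flow solver", {
  skip_if_not_installed("igraph")
  set.seed(83)
  for (trial in 1:10) {
    dims <- c(3, 3, 2)
    n <- prod(dims)
    nb <- atlascut:::neighbour_pairs(dims, 6L)
    w <- runif(length(nb$p), 0, 2)
    cs <- runif(n, 0, 2)
    ct <- runif(n, 0, 2)
    mf <- atlascut:::bk_mincut_cpp(nb$p, nb$q, w, cs, ct)
    src <- n + 1L; snk <- n + 2L
    edges <- rbind(cbind(nb$p, nb$q), cbind(rep(src, n), 1:n),
                   cbind(1:n, rep(snk, n)))
    g <- igraph::make_graph(t(edges), n = n + 2L, directed = FALSE)
    want <- igraph::max_flow(g, src, snk, capacity = c(w, ct, cs))$value
    expect_equal(mf$flow, want, tolerance = 1e-9)
  }
})

test_that("seed hard constraints survive any configuration", {
  case <- tiny_case(c(8, 8, 5))
  # adversarial data terms pushing every voxel the wrong way
  n <- prod(dim(case$volume$data))
  terms <- list(r_pc = array(10, dim(case$volume$data)),
                r_bg = array(0.01, dim(case$volume$data)))
  for (cfg in list(graph_cut_config(lam = 0), graph_cut_config(lam = 50),
                   graph_cut_config(connectivity = 26))) {
    cut <- build_and_cut(case$volume, case$seeds, terms, cfg)
    expect_true(all(cut$data[case$seeds$data == 1L] == 1L))
    expect_true(all(cut$data[case$seeds$data == 2L] == 0L))
  }
})

test_that("large lambda recovers the per-voxel data-term argmin", {
  case <- tiny_case(c(8, 8, 5))
  model <- fit_histograms(case$volume, case$seeds, n_bins = 16)
  terms <- data_term(model, case$volume)
  cut <- build_and_cut(case$volume, case$seeds, terms,
                       graph_cut_config(lam = 1e4))
  want <- array(as.integer(terms$r_pc < terms$r_bg), dim(case$volume$data))
  want[case$seeds$data == 1L] <- 1L
  want[case$seeds$data == 2L] <- 0L
  disagree <- mean(cut$data != want)
  expect_lt(disagree, 0.01)
})

test_that("small lambda yields the boundary-dominated coherent solution", {
  # sharp two-block volume: with tiny lambda the cut follows the contrast edge
  case <- tiny_case(c(10, 8, 6), bright = 100, dark = 0, sd = 0.5, seed = 4)
  seg <- segment_volume(case$volume, case$seeds,
                        cfg = graph_cut_config(lam = 0.05))
  expect_gt(jaccard(seg, case$mask), 0.9)
})

test_that("segmentation pipeline validates inputs", {
  case <- tiny_case()
  bad_terms <- list(r_pc = array(Inf, dim(case$volume$data)),
                    r_bg = array(1, dim(case$volume$data)))
  expect_error(build_and_cut(case$volume, case$seeds, bad_terms), "finite")
  wrong <- list(r_pc = array(1, c(2, 2, 2)), r_bg = array(1, c(2, 2, 2)))
  expect_error(build_and_cut(case$volume, case$seeds, wrong), "shape")
  expect_error(graph_cut_config(connectivity = 8), "connectivity")
  expect_error(graph_cut_config(lam = -1), "lam")
})

test_that("a constant 0.5 prior reproduces the conventional cut exactly", {
  set.seed(91)
  for (i in 1:3) {
    ph <- make_phantom(phantom_spec(shape = c(24, 24, 16),
                                    semiaxes = c(6, 5, 4),
                                    rng_seed = 100 + i))
    seeds <- simulate_seeds(ph$mask, n_organ_strokes = 3, n_bg_strokes = 5,
                            stroke_radius = 1.5, bg_band_width = 6,
                            rng_seed = 40 + i)
    cgc <- segment_volume(ph$volume, seeds)
    half <- segment_volume(ph$volume, seeds,
                           prior = array(0.5, dim(ph$volume$data)))
    expect_identical(cgc$data, half$data)
  }
})
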