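# Shared fixtures and independent oracles. Every oracle here is a second code
# path (brute force / enumeration / direct formula), deliberately naive, so
# that agreement with the package implementation is informative.

# Brute-force signed distance: for every voxel, the exact Euclidean distance
# to the nearest voxel of the opposite class, positive inside.
brute_signed_distance <- function(mask_arr) {
  fg <- which(mask_arr == 1, arr.ind = TRUE)
  bg <- which(mask_arr == 0, arr.ind = TRUE)
  idx <- which(array(TRUE, dim(mask_arr)), arr.ind = TRUE)
  out <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (mask_arr[p[1], p[2], p[3]] == 1) {
      out[i] <- sqrt(min(colSums((t(bg) - p)^2)))
    } else {
      out[i] <- -sqrt(min(colSums((t(fg) - p)^2)))
    }
  }
  array(out, dim(mask_arr))
}

# Independent nearest-neighbour resampler: lattice voxel i samples the source
# voxel whose cell contains the lattice voxel centre under the box -> lattice
# affine map, written as an explicit triple loop.
brute_resample <- function(mask_arr, lo, hi, lattice) {
  out <- array(0L, lattice)
  ext <- hi - lo
  for (k in seq_len(lattice[3])) for (j in seq_len(lattice[2]))
    for (i in seq_len(lattice[1])) {
      src <- c(lo[1] + floor((i - 0.5) * ext[1] / lattice[1]),
               lo[2] + floor((j - 0.5) * ext[2] / lattice[2]),
               lo[3] + floor((k - 0.5) * ext[3] / lattice[3]))
      src <- pmin(pmax(src, lo), hi - 1) + 1 # to 1-based
      out[i, j, k] <- mask_arr[src[1], src[2], src[3]]
    }
  out
}

# Exhaustive minimum of the segmentation energy over all labelings consistent
# with the seeds, computed from first principles (normalized intensities,
# explicit Gaussian boundary weights).
enum_min_energy <- function(vol, terms, cfg, organ_idx, bg_idx) {
  n <- length(vol$data)
  stopifnot(n <= 16)
  labs <- as.matrix(expand.grid(rep(list(0:1), n)))
  keep <- rep(TRUE, nrow(labs))
  for (i in organ_idx) keep <- keep & labs[, i] == 1
  for (i in bg_idx) keep <- keep & labs[, i] == 0
  labs <- labs[keep, , drop = FALSE]
  v <- as.vector(vol$data)
  if (cfg$normalize) {
    r <- range(v)
    v <- if (r[1] == r[2]) rep(0, n) else (v - r[1]) / (r[2] - r[1])
  }
  nb <- atlascut:::neighbour_pairs(dim(vol$data), cfg$connectivity)
  w <- exp(-(v[nb$p] - v[nb$q])^2 / (2 * cfg$sigma^2)) / nb$dist
  E <- labs %*% as.vector(terms$r_pc) * cfg$lam +
    (1 - labs) %*% as.vector(terms$r_bg) * cfg$lam
  for (e in seq_along(nb$p))
    E <- E + w[e] * (labs[, nb$p[e]] != labs[, nb$q[e]])
  min(E)
}

# Dense "oracle" seeds: the whole eroded interior as organ seeds and a full
# shell outside the dilated mask as background seeds (maximally informative,
# symmetric annotation).
dense_oracle_seeds <- function(mask, margin = 2, band = 2) {
  fg <- mask$data == 1
  dims <- dim(mask$data)
  d_bg <- sqrt(atlascut:::edt_sq_cpp(as.vector(!fg), dims))
  d_fg <- sqrt(atlascut:::edt_sq_cpp(as.vector(fg), dims))
  s <- array(0L, dims)
  s[fg & array(d_bg > margin, dims)] <- 1L
  s[!fg & array(d_fg > margin & d_fg <= margin + band, dims)] <- 2L
  seed_image(s)
}

# Integer-shift a 3D array with clamped (replicated) borders.
shift_array <- function(a, t) {
  d <- dim(a)
  xs <- pmin(pmax(seq_len(d[1]) - t[1], 1), d[1])
  ys <- pmin(pmax(seq_len(d[2]) - t[2], 1), d[2])
  zs <- pmin(pmax(seq_len(d[3]) - t[3], 1), d[3])
  array(a[xs, ys, zs], d)
}

# Random connected-ish blob mask with at least one fg and one bg voxel.
random_mask <- function(dims, p = 0.35) {
  m <- array(as.integer(stats::runif(prod(dims)) < p), dims)
  m[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- 1L
  m[1, 1, 1] <- 0L
  label_mask(m)
}

# Small two-class test volume with a central bright block and one organ +
# one background seed, for quick graph-cut tests.
tiny_case <- function(dims = c(6, 6, 4), bright = 100, dark = 20, sd = 1,
                      seed = 1) {
  set.seed(seed)
  vol <- array(dark + stats::rnorm(prod(dims), 0, sd), dims)
  m <- array(0L, dims)
  ctr <- pmax(2, floor(dims / 3))
  hi <- pmin(dims - 1, ctr + floor(dims / 3))
  m[ctr[1]:hi[1], ctr[2]:hi[2], ctr[3]:hi[3]] <- 1L
  vol[m == 1] <- bright + stats::rnorm(sum(m), 0, sd)
  s <- array(0L, dims)
  s[ctr[1] + 1, ctr[2] + 1, ctr[3]] <- 1L
  s[1, 1, 1] <- 2L
  list(volume = volume3d(vol), mask = label_mask(m), seeds = seed_image(s))
}
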