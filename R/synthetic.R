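# Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Phantom specification
#'
#' Describes one synthetic test case: a smoothly deformed ellipsoidal "organ"
#' over a flat background, optional distractor blobs (other structures that
#' share the organ's intensity distribution, as neighbouring organs do in
#' CT), and additive Gaussian noise. Everything is deterministic given
#' `rng_seed`.
#'
#' @param shape volume dimensions (voxels).
#' @param centre organ centre (0-based voxel coordinates).
#' @param semiaxes ellipsoid half-axes (voxels).
#' @param deform_amp amplitude of the low-frequency sinusoidal radial
#'   deformation, as a fraction of the local radius (0 = exact ellipsoid).
#' @param deform_freq angular frequency of the deformation.
#' @param organ_intensity,background_intensity length-2 `(mean, sd)` of the
#'   per-voxel intensities (arbitrary CT-like units).
#' @param distractors list of distractor blobs, each a list with `centre`,
#'   `semiaxes` and optionally `intensity` (defaults to the organ's, the
#'   confounding case).
#' @param noise_sd global additive Gaussian noise sd.
#' @param rng_seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(36, 36, 24),
                         centre = (shape - 1) / 2,
                         semiaxes = c(9, 7, 5),
                         deform_amp = 0.12,
                         deform_freq = 2,
                         organ_intensity = c(100, 5),
                         background_intensity = c(40, 5),
                         distractors = list(),
                         noise_sd = 2,
                         rng_seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(centre) == 3L, length(semiaxes) == 3L,
            all(semiaxes > 0), deform_amp >= 0, noise_sd >= 0)
  # organ (with maximal deformation) must fit with a >= 2-voxel margin
  reach <- semiaxes * (1 + deform_amp)
  if (any(centre - reach < 2) || any(centre + reach > shape - 3))
    stop("organ does not fit inside the volume with a 2-voxel margin",
         call. = FALSE)
  structure(list(shape = shape, centre = as.numeric(centre),
                 semiaxes = as.numeric(semiaxes), deform_amp = deform_amp,
                 deform_freq = deform_freq,
                 organ_intensity = organ_intensity,
                 background_intensity = background_intensity,
                 distractors = distractors, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Deformed-ellipsoid membership: normalized radius against a radius threshold
# modulated by low-frequency spherical harmonics-like sinusoids with random
# phases.
ellipsoid_mask <- function(shape, centre, semiaxes, amp = 0, freq = 2,
                           phases = c(0, 0)) {
  grids <- lapply(1:3, function(a) (seq_len(shape[a]) - 1 - centre[a]) / semiaxes[a])
  ux <- array(grids[[1]], dim = shape)
  uy <- aperm(array(grids[[2]], dim = shape[c(2, 1, 3)]), c(2, 1, 3))
  uz <- aperm(array(grids[[3]], dim = shape[c(3, 2, 1)]), c(3, 2, 1))
  rho <- sqrt(ux^2 + uy^2 + uz^2)
  if (amp > 0) {
    theta <- atan2(uy, ux)
    phi <- atan2(uz, sqrt(ux^2 + uy^2))
    thresh <- 1 + amp * sin(freq * theta + phases[1]) * cos(freq * phi + phases[2])
  } else {
    thresh <- 1
  }
  rho <= thresh
}

#' Generate one phantom volume and its ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume3d()]) and `mask` (the ground-truth
#'   [label_mask()]; distractors are present in the volume but not the mask).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$rng_seed, {
    phases <- stats::runif(2, 0, 2 * pi)
    organ <- ellipsoid_mask(spec$shape, spec$centre, spec$semiaxes,
                            spec$deform_amp, spec$deform_freq, phases)
    n <- prod(spec$shape)
    vol <- array(spec$background_intensity[1] +
                   stats::rnorm(n, 0, spec$background_intensity[2]),
                 dim = spec$shape)
    for (d in spec$distractors) {
      dm <- ellipsoid_mask(spec$shape, d$centre, d$semiaxes)
      di <- d$intensity %||% spec$organ_intensity
      vol[dm] <- di[1] + stats::rnorm(sum(dm), 0, di[2])
    }
    vol[organ] <- spec$organ_intensity[1] +
      stats::rnorm(sum(organ), 0, spec$organ_intensity[2])
    if (spec$noise_sd > 0) vol <- vol + stats::rnorm(n, 0, spec$noise_sd)
    list(volume = volume3d(vol), mask = label_mask(organ))
  })
}

#' Generate a cohort of phantoms with inter-case variability
#'
#' Emulates inter-patient variability for atlas building: each case jitters
#' the organ's pose and half-axes (and any distractor's pose) around the base
#' specification, and draws fresh deformation phases and noise. Deterministic
#' given the base spec's `rng_seed`.
#'
#' @param n number of cases (>= 2).
#' @param base_spec a [phantom_spec()].
#' @param pose_jitter sd of the centre displacement (voxels).
#' @param shape_jitter sd of the log half-axis scaling (0.08 means roughly
#'   +/- 8% axis variation).
#' @return list of `n` elements, each a list with `volume`, `mask`, `spec`.
#' @export
make_cohort <- function(n, base_spec, pose_jitter = 1.5, shape_jitter = 0.06) {
  stopifnot(n >= 2, inherits(base_spec, "phantom_spec"))
  frozen <- pose_jitter == 0 && shape_jitter == 0
  specs <- local_seed(base_spec$rng_seed, {
    lapply(seq_len(n), function(i) {
      if (frozen) return(base_spec)
      s <- base_spec
      s$centre <- s$centre + stats::rnorm(3, 0, pose_jitter)
      s$semiaxes <- s$semiaxes * exp(stats::rnorm(3, 0, shape_jitter))
      s$distractors <- lapply(s$distractors, function(d) {
        d$centre <- d$centre + stats::rnorm(3, 0, pose_jitter)
        d
      })
      s$rng_seed <- base_spec$rng_seed + i * 1009L
      # keep the jittered organ inside the volume: clamp the centre into the
      # valid range (the per-case shape jitter is small enough that the range
      # stays nonempty for any reasonable base spec)
      reach <- s$semiaxes * (1 + s$deform_amp)
      s$centre <- pmin(pmax(s$centre, 2 + reach + 0.01),
                       s$shape - 3 - reach - 0.01)
      phantom_spec(shape = s$shape, centre = s$centre, semiaxes = s$semiaxes,
                   deform_amp = s$deform_amp, deform_freq = s$deform_freq,
                   organ_intensity = s$organ_intensity,
                   background_intensity = s$background_intensity,
                   distractors = s$distractors, noise_sd = s$noise_sd,
                   rng_seed = s$rng_seed)
    })
  })
  lapply(specs, function(s) c(make_phantom(s), list(spec = s)))
}

#' Simulate seed strokes from ground truth
#'
#' Emulates an expert's scribbles: organ strokes are small balls sampled
#' strictly inside the eroded truth mask; background strokes are sampled in a
#' band around (but strictly outside) the dilated mask, where a user marking
#' the organ's surroundings would scribble. Seeds therefore never contradict
#' the ground truth.
#'
#' @param truth ground-truth [label_mask()] with nonempty foreground.
#' @param n_organ_strokes,n_bg_strokes stroke counts (0 allowed).
#' @param stroke_radius ball radius of each stroke (voxels).
#' @param margin erosion/dilation depth separating seeds from the true
#'   boundary (voxels, default 2).
#' @param bg_band_width how far beyond the dilated mask background strokes may
#'   reach (voxels, default 10).
#' @param alpha background coefficient passed to [seed_image()].
#' @param rng_seed integer RNG seed.
#' @return a [seed_image()].
#' @export
simulate_seeds <- function(truth, n_organ_strokes = 6, n_bg_strokes = 10,
                           stroke_radius = 2, margin = 2, bg_band_width = 10,
                           alpha = 1, rng_seed = 1L) {
  stopifnot(inherits(truth, "label_mask"))
  fg <- truth$data == 1
  if (!any(fg)) stop("truth mask is empty", call. = FALSE)
  dims <- dim(truth$data)
  d_to_bg <- sqrt(edt_sq_cpp(as.vector(!fg), dims)) # distance into the organ
  d_to_fg <- sqrt(edt_sq_cpp(as.vector(fg), dims))  # distance away from it
  organ_ok <- fg & array(d_to_bg > margin, dims)
  bg_ok <- !fg & array(d_to_fg > margin & d_to_fg <= margin + bg_band_width, dims)
  if (n_organ_strokes > 0 && !any(organ_ok))
    stop("mask too thin to erode by the stroke margin", call. = FALSE)
  if (n_bg_strokes > 0 && !any(bg_ok))
    stop("no background voxels available in the stroke band", call. = FALSE)

  seeds <- array(SEED_NONE, dim = dims)
  place <- function(seeds, ok, n_strokes, code) {
    cand <- which(ok, arr.ind = TRUE)
    for (s in seq_len(n_strokes)) {
      ctr <- cand[sample.int(nrow(cand), 1), ]
      ball <- ball_indices(ctr, stroke_radius, dims)
      ball <- ball[ok[ball]] # clip the stroke to the safe region
      seeds[ball] <- code
    }
    seeds
  }
  local_seed(rng_seed, {
    seeds <- place(seeds, organ_ok, n_organ_strokes, SEED_ORGAN)
    seeds <- place(seeds, bg_ok, n_bg_strokes, SEED_BACKGROUND)
  })
  seed_image(seeds, alpha = alpha, spacing = truth$spacing,
             origin = truth$origin)
}

# Linear indices of the ball of given radius around a (1-based) centre.
ball_indices <- function(centre, radius, dims) {
  r <- ceiling(radius)
  rng <- lapply(1:3, function(a)
    max(1, centre[a] - r):min(dims[a], centre[a] + r))
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  keep <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2 <=
    radius^2
  g <- g[keep, , drop = FALSE]
  g$x + (g$y - 1) * dims[1] + (g$z - 1) * dims[1] * dims[2]
}

#' Default confounded phantom specification
#'
#' The standard study phantom: one deformed ellipsoidal organ plus two
#' distractor blobs drawn from the same intensity distribution as the organ,
#' placed away from it, against a darker background. The intensity overlap
#' makes a purely intensity-driven cut leak into the distractors, while an
#' atlas prior fitted to the organ excludes them.
#'
#' @param shape volume dimensions.
#' @param rng_seed integer RNG seed.
#' @return a [phantom_spec()].
#' @export
confounded_phantom_spec <- function(shape = c(40, 40, 26), rng_seed = 1L) {
  phantom_spec(
    shape = shape,
    centre = c(0.38, 0.42, 0.5) * (shape - 1),
    semiaxes = c(0.24, 0.19, 0.17) * shape,
    deform_amp = 0.12,
    deform_freq = 2,
    organ_intensity = c(100, 5),
    background_intensity = c(40, 5),
    distractors = list(
      list(centre = c(0.85, 0.82, 0.30) * (shape - 1),
           semiaxes = c(0.11, 0.10, 0.12) * shape),
      list(centre = c(0.84, 0.18, 0.70) * (shape - 1),
           semiaxes = c(0.10, 0.11, 0.10) * shape)),
    noise_sd = 2,
    rng_seed = rng_seed)
}
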