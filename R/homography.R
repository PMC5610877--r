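#' 3D homography (4x4 projective transform)
#'
#' Maps test-image voxel coordinates into atlas lattice coordinates:
#' `(X', Y', Z', W')^T = H (x, y, z, 1)^T`, followed by division by `W'`.
#' The gauge freedom (H and cH define the same map) is removed by fixing
#' `h44 = 1`; the remaining 15 entries are the free parameters of the
#' projective fit, with translation-only (3 dof) and affine (12 dof)
#' constrained modes available.
#'
#' @param H 4x4 numeric matrix with `H[4,4] == 1` and nonzero determinant.
#' @return an object of class `homography`.
#' @export
homography <- function(H) {
  H <- as.matrix(H)
  if (!all(dim(H) == c(4, 4)) || any(!is.finite(H)))
    stop("H must be a finite 4x4 matrix", call. = FALSE)
  if (abs(H[4, 4] - 1) > 1e-12)
    stop("H[4,4] must equal 1 (gauge fixing)", call. = FALSE)
  if (abs(det(H)) < 1e-12)
    stop("H is (near-)singular", call. = FALSE)
  structure(list(H = H), class = "homography")
}

#' @rdname homography
#' @export
identity_homography <- function() homography(diag(4))

#' @rdname homography
#' @param t numeric length-3 translation (voxels).
#' @export
translation_homography <- function(t) {
  H <- diag(4)
  H[1:3, 4] <- as.numeric(t)
  homography(H)
}

#' Apply a homography to 3D points
#'
#' @param h a [homography()] (or a plain 4x4 matrix, not gauge-checked, for
#'   internal use in tests).
#' @param points numeric length-3 vector or n x 3 matrix of (x, y, z)
#'   coordinates.
#' @param eps projections with `|W'| <= eps` are degenerate.
#' @return transformed coordinates, same shape as `points`.
#' @export
apply_homography <- function(h, points, eps = 1e-9) {
  H <- if (inherits(h, "homography")) h$H else as.matrix(h)
  single <- is.null(dim(points))
  pts <- if (single) matrix(points, nrow = 1) else as.matrix(points)
  P <- cbind(pts, 1) %*% t(H)
  W <- P[, 4]
  if (any(abs(W) <= eps))
    stop("degenerate projection: |W'| <= ", eps, " at ",
         sum(abs(W) <= eps), " point(s)", call. = FALSE)
  out <- P[, 1:3, drop = FALSE] / W
  if (single) as.numeric(out) else out
}

#' Sample the atlas at continuous coordinates
#'
#' Trilinear interpolation on the atlas lattice; 0-based coordinates, so the
#' value at integer coordinate (i, j, k) is the stored value of that lattice
#' node. Coordinates outside the lattice return `outside` (default 0:
#' "certainly not organ", so transforms that throw organ seeds off the atlas
#' are penalized rather than rewarded).
#'
#' @param atlas a [prob_atlas()].
#' @param coords numeric length-3 vector or n x 3 matrix.
#' @param outside value returned outside the lattice support.
#' @return numeric vector of interpolated probabilities.
#' @export
sample_atlas <- function(atlas, coords, outside = 0) {
  stopifnot(inherits(atlas, "prob_atlas"))
  pts <- if (is.null(dim(coords))) matrix(coords, nrow = 1) else as.matrix(coords)
  trilinear_cpp(as.numeric(atlas$data), dim(atlas$data), pts, outside)
}

#' Atlas-to-seed fidelity energy
#'
#' Sum over seed voxels of the atlas probability at the transformed position,
#' weighted by the signed seed value (-1 for organ seeds, +alpha for
#' background seeds). Minimizing drives the warped atlas towards 1 on organ
#' seeds and 0 on background seeds. Unlabeled voxels have weight 0 and are
#' skipped.
#'
#' @param atlas a [prob_atlas()].
#' @param seeds a [seed_image()] with both seed classes nonempty.
#' @param h a [homography()].
#' @param outside atlas value assumed outside the lattice.
#' @return scalar energy (lower is better; negative when well fitted).
#' @export
fidelity_energy <- function(atlas, seeds, h, outside = 0) {
  validate_seeds(seeds)
  sc <- seed_coords(seeds)
  pts <- rbind(sc$organ, sc$background)
  w <- c(rep(-1, nrow(sc$organ)), rep(seeds$alpha, nrow(sc$background)))
  vals <- sample_atlas(atlas, apply_homography(h, pts), outside = outside)
  sum(vals * w)
}

#' Optimizer settings for the homography fit
#'
#' @param max_iters maximum steepest-descent iterations.
#' @param tol stop when the energy decrease over an accepted step falls below
#'   `tol * (1 + |E|)`.
#' @param step0 initial step length in preconditioned parameter space.
#' @param fd_step relative central finite-difference step per parameter.
#' @param min_step line search gives up when the step underflows this value.
#' @return list of class `fit_options`.
#' @export
fit_options <- function(max_iters = 500, tol = 1e-6, step0 = 1,
                        fd_step = 1e-4, min_step = 1e-12) {
  structure(list(max_iters = as.integer(max_iters), tol = tol, step0 = step0,
                 fd_step = fd_step, min_step = min_step),
            class = "fit_options")
}

# Free entries of H per mode, as (row, col) pairs. h44 is gauge-fixed.
free_entries <- function(mode) {
  switch(mode,
    translation = cbind(1:3, 4L),
    affine = as.matrix(expand.grid(row = 1:3, col = 1:4)),
    projective = {
      g <- as.matrix(expand.grid(row = 1:4, col = 1:4))
      g[!(g[, 1] == 4 & g[, 2] == 4), , drop = FALSE]
    },
    stop("unknown mode: ", mode, call. = FALSE))
}

# Per-entry parameter scales: a unit preconditioned step moves transformed
# coordinates by about one voxel regardless of which entry moves. L is the
# magnitude of the input (image) coordinates, A that of the atlas lattice.
entry_scales <- function(entries, L, A) {
  s <- numeric(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    r <- entries[i, 1]; cc <- entries[i, 2]
    s[i] <- if (r <= 3 && cc == 4) 1        # translation
    else if (r <= 3) 1 / L                  # linear part
    else if (cc == 4) 1 / A                 # projective offset (h4c, c=4 fixed)
    else 1 / (L * A)                        # projective row
  }
  s
}

#' Initial homography from the seed geometry
#'
#' `init_homography()` builds a diagonal affine map sending the organ-seed
#' bounding box (expanded by `margin` on each side) onto the atlas lattice:
#' the box centre goes to the lattice centre and the box spans the lattice.
#' The expansion compensates for seed strokes covering only part of the
#' organ. `init_translation()` builds a pure translation aligning the
#' organ-seed centroid with the atlas's probability-weighted centre of mass —
#' the natural starting point for the translation-constrained fit, which
#' cannot correct a scale mismatch anyway.
#'
#' @param atlas a [prob_atlas()].
#' @param seeds a [seed_image()] with at least one organ seed.
#' @param margin fractional half-extent expansion (default 0.5).
#' @return a [homography()].
#' @export
init_homography <- function(atlas, seeds, margin = 0.5) {
  stopifnot(inherits(atlas, "prob_atlas"))
  sc <- seed_coords(seeds)
  if (nrow(sc$organ) == 0L)
    stop("need at least one organ seed to initialize", call. = FALSE)
  lo <- apply(sc$organ, 2, min)
  hi <- apply(sc$organ, 2, max)
  centre <- (lo + hi) / 2
  half <- pmax((hi - lo) / 2 * (1 + margin), 2)
  S <- dim(atlas$data)
  scale <- (S - 1) / (2 * half)
  H <- diag(4)
  H[cbind(1:3, 1:3)] <- scale
  H[1:3, 4] <- (S - 1) / 2 - scale * centre
  homography(H)
}

#' @rdname init_homography
#' @export
init_translation <- function(atlas, seeds) {
  stopifnot(inherits(atlas, "prob_atlas"))
  sc <- seed_coords(seeds)
  if (nrow(sc$organ) == 0L)
    stop("need at least one organ seed to initialize", call. = FALSE)
  S <- dim(atlas$data)
  idx <- which(array(TRUE, S), arr.ind = TRUE) - 1
  w <- as.vector(atlas$data)
  com <- colSums(idx * w) / sum(w)
  translation_homography(com - colMeans(sc$organ))
}

#' Fit the atlas to seed voxels by steepest descent
#'
#' Minimizes the fidelity energy over the free entries of the homography
#' (3, 12 or 15 depending on `mode`) by preconditioned steepest descent with
#' central finite-difference gradients and a backtracking (step-halving,
#' simple-decrease) line search. The accepted-energy trajectory is
#' non-increasing by construction.
#'
#' @param atlas a [prob_atlas()].
#' @param seeds a [seed_image()] with both classes nonempty.
#' @param init initial [homography()]; defaults to [init_homography()], or
#'   [init_translation()] in translation mode.
#' @param mode `"projective"` (default, 15 dof), `"affine"` (12 dof) or
#'   `"translation"` (3 dof, the parallel-translation-only configuration).
#' @param opts a [fit_options()].
#' @param outside atlas value assumed outside the lattice.
#' @return list of class `fit_result` with fields `homography`, `energy`,
#'   `trajectory` (accepted energies, starting at the init energy),
#'   `converged`, `iterations`, `mode`.
#' @export
fit_homography <- function(atlas, seeds, init = NULL,
                           mode = c("projective", "affine", "translation"),
                           opts = fit_options(), outside = 0) {
  mode <- match.arg(mode)
  validate_seeds(seeds)
  if (is.null(init))
    init <- if (mode == "translation") init_translation(atlas, seeds)
            else init_homography(atlas, seeds)
  stopifnot(inherits(init, "homography"))

  sc <- seed_coords(seeds)
  pts <- rbind(sc$organ, sc$background)
  w <- c(rep(-1, nrow(sc$organ)), rep(seeds$alpha, nrow(sc$background)))
  hom_pts <- cbind(pts, 1)
  adata <- as.numeric(atlas$data)
  adim <- dim(atlas$data)

  energy_of <- function(H) {
    P <- hom_pts %*% t(H)
    W <- P[, 4]
    if (any(abs(W) <= 1e-9) || any(!is.finite(W))) return(Inf)
    sum(trilinear_cpp(adata, adim, P[, 1:3, drop = FALSE] / W, outside) * w)
  }

  entries <- free_entries(mode)
  L <- max(1, max(abs(pts)))
  A <- max(1, max(adim) - 1)
  s <- entry_scales(entries, L, A)

  H <- init$H
  E <- energy_of(H)
  if (!is.finite(E))
    stop("non-finite fidelity energy at the initial homography", call. = FALSE)
  traj <- E
  step <- opts$step0
  converged <- FALSE
  iters <- 0L

  for (it in seq_len(opts$max_iters)) {
    iters <- it
    # central finite-difference gradient over the free entries
    g <- numeric(nrow(entries))
    for (i in seq_len(nrow(entries))) {
      d <- opts$fd_step * s[i]
      Hp <- H; Hp[entries[i, 1], entries[i, 2]] <- Hp[entries[i, 1], entries[i, 2]] + d
      Hm <- H; Hm[entries[i, 1], entries[i, 2]] <- Hm[entries[i, 1], entries[i, 2]] - d
      ep <- energy_of(Hp); em <- energy_of(Hm)
      g[i] <- if (is.finite(ep) && is.finite(em)) (ep - em) / (2 * d) else 0
    }
    dirn <- -g * s^2 # preconditioned descent direction
    gnorm <- sqrt(sum((g * s)^2))
    if (gnorm < 1e-14) { converged <- TRUE; break }

    accepted <- FALSE
    st <- step
    while (st >= opts$min_step) {
      Hc <- H
      Hc[entries] <- Hc[entries] + st * dirn
      Ec <- energy_of(Hc)
      if (is.finite(Ec) && Ec < E) {
        H <- Hc
        dE <- E - Ec
        E <- Ec
        traj <- c(traj, E)
        accepted <- TRUE
        step <- st * 2 # optimistic growth for the next iteration
        if (dE < opts$tol * (1 + abs(E))) converged <- TRUE
        break
      }
      st <- st / 2
    }
    if (!accepted || converged) {
      if (!accepted) converged <- TRUE # no descent direction left at min step
      break
    }
  }

  structure(list(homography = homography(H), energy = E, trajectory = traj,
                 converged = converged, iterations = iters, mode = mode),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mode %s, E = %.6g after %d iterations (%s)\n",
              x$mode, x$energy, x$iterations,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Warp the atlas onto a test-image grid
#'
#' Evaluates the fitted prior `A*(x, y, z) = A(H (x, y, z))` at every voxel of
#' the test volume, by trilinear sampling; voxels mapping outside the lattice
#' take `outside`.
#'
#' @param atlas a [prob_atlas()].
#' @param h a [homography()].
#' @param shape integer length-3 test-volume shape.
#' @param outside value assumed outside the lattice.
#' @param eps degeneracy threshold on `|W'|`.
#' @return 3D array of prior probabilities with dimensions `shape`.
#' @export
warp_atlas_to_image <- function(atlas, h, shape, outside = 0, eps = 1e-9) {
  stopifnot(inherits(atlas, "prob_atlas"), inherits(h, "homography"))
  shape <- as.integer(shape)
  coords <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1L,
                                  y = seq_len(shape[2]) - 1L,
                                  z = seq_len(shape[3]) - 1L))
  X <- apply_homography(h, coords, eps = eps)
  array(sample_atlas(atlas, X, outside = outside), dim = shape)
}
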