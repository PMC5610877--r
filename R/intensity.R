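#' Seed-region intensity histograms
#'
#' Estimates the class-conditional intensity likelihoods Pr(v | organ) and
#' Pr(v | background) as normalized histograms of the voxel values under the
#' organ and background seeds, on a common equal-width binning spanning the
#' test volume's intensity range. Every bin mass is floored at `floor` and the
#' histograms renormalized, so the negative-log data terms stay finite.
#'
#' @param vol a [volume3d()].
#' @param seeds a [seed_image()] with both classes nonempty.
#' @param n_bins number of equal-width bins (default 64).
#' @param floor small positive mass floor (default 1e-6).
#' @return object of class `intensity_model` with fields `bin_edges`, `p_pc`,
#'   `p_bg`, `floor`.
#' @export
fit_histograms <- function(vol, seeds, n_bins = 64, floor = 1e-6) {
  stopifnot(inherits(vol, "volume3d"))
  validate_seeds(seeds)
  if (!identical(dim(vol$data), dim(seeds$data)))
    stop("volume and seed image shapes differ", call. = FALSE)
  rng <- range(vol$data)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) # constant volume: one wide bin range
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  class_hist <- function(values) {
    idx <- bin_index(values, edges)
    p <- tabulate(idx, nbins = n_bins) / length(values)
    p <- pmax(p, floor)
    p / sum(p)
  }
  m <- structure(list(
    bin_edges = edges,
    p_pc = class_hist(vol$data[seeds$data == SEED_ORGAN]),
    p_bg = class_hist(vol$data[seeds$data == SEED_BACKGROUND]),
    floor = floor), class = "intensity_model")
  m
}

# Bin index with clamping: values at/below the first edge fall in bin 1,
# at/above the last edge in bin n.
bin_index <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}

#' Per-class likelihood of each voxel's intensity
#'
#' @param model an `intensity_model`.
#' @param values numeric vector/array of intensities.
#' @return list with numeric vectors `pc` and `bg` of bin masses.
#' @export
intensity_likelihood <- function(model, values) {
  stopifnot(inherits(model, "intensity_model"))
  idx <- bin_index(as.vector(values), model$bin_edges)
  list(pc = model$p_pc[idx], bg = model$p_bg[idx])
}

#' Negative-log data terms, optionally atlas-weighted
#'
#' Without a prior, the per-voxel label costs are the plain negative log
#' likelihoods `R_PC = -log Pr(v | organ)`, `R_BG = -log Pr(v | background)`.
#' With a fitted atlas prior `A*`, the likelihoods are replaced by the
#' (unnormalized) posteriors `Pr(v | organ) A*` and
#' `Pr(v | background) (1 - A*)`; `eps` inside the log guards prior values
#' saturated to exactly 0 or 1.
#'
#' @param model an `intensity_model` from [fit_histograms()].
#' @param vol the test [volume3d()].
#' @param prior optional 3D array of prior probabilities (same shape as the
#'   volume, values in \[0, 1\]).
#' @param eps guard added inside the prior-weighted logs (default 1e-6).
#' @return list with 3D arrays `r_pc` and `r_bg` (finite, nonnegative up to
#'   the eps guard).
#' @export
data_term <- function(model, vol, prior = NULL, eps = 1e-6) {
  stopifnot(inherits(model, "intensity_model"), inherits(vol, "volume3d"))
  lik <- intensity_likelihood(model, vol$data)
  dims <- dim(vol$data)
  if (is.null(prior)) {
    r_pc <- -log(lik$pc)
    r_bg <- -log(lik$bg)
  } else {
    prior <- as.array(prior)
    if (!identical(dim(prior), dims))
      stop("prior shape differs from volume shape", call. = FALSE)
    if (any(prior < 0 | prior > 1))
      stop("prior values must lie in [0, 1]", call. = FALSE)
    a <- as.vector(prior)
    r_pc <- -log(lik$pc * a + eps)
    r_bg <- -log(lik$bg * (1 - a) + eps)
  }
  list(r_pc = array(r_pc, dim = dims), r_bg = array(r_bg, dim = dims))
}

#' Serialize an intensity model to JSON
#'
#' @param model an `intensity_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_intensity_model <- function(model, path) {
  stopifnot(inherits(model, "intensity_model"))
  jsonlite::write_json(list(bin_edges = model$bin_edges, p_pc = model$p_pc,
                            p_bg = model$p_bg, floor = model$floor),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
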