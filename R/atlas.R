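#' Atlas construction settings
#'
#' The probabilistic atlas lives on a fixed lattice: every training mask is
#' cropped to its organ bounding box, resampled to the lattice, converted to a
#' signed Euclidean distance map and squashed through a sigmoid; the atlas is
#' the voxelwise mean of the per-case sigmoid maps.
#'
#' @param lattice integer length-3 `(S_x, S_y, S_z)`, lattice extents in
#'   voxels (each >= 2). Default 64 x 64 x 32, an elongated box matching the
#'   roughly prone-ellipsoid aspect of abdominal organs.
#' @param gain sigmoid gain (per voxel of signed distance, > 0). Larger values
#'   sharpen each case's probability map towards a binary mask; 1.0 leaves a
#'   boundary band a few voxels wide at intermediate probability.
#' @param margin optional fractional margin added around the bounding box on
#'   every axis before resampling (default 0: the tight box), so the lattice
#'   faces are not clamped near probability 0.5.
#' @param interp resampling rule for binary masks: `"nearest"` (exactly
#'   binary, the default) or `"linear"` (trilinear then re-threshold at 0.5).
#' @return an object of class `atlas_config`.
#' @export
atlas_config <- function(lattice = c(64, 64, 32), gain = 1.0, margin = 0,
                         interp = c("nearest", "linear")) {
  lattice <- as.integer(lattice)
  if (length(lattice) != 3L || any(lattice < 2L))
    stop("lattice must be three integers, each >= 2", call. = FALSE)
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("gain must be a single positive number", call. = FALSE)
  if (!is.numeric(margin) || margin < 0)
    stop("margin must be >= 0", call. = FALSE)
  structure(list(lattice = lattice, gain = gain, margin = margin,
                 interp = match.arg(interp)),
            class = "atlas_config")
}

#' Tight bounding box of a mask's foreground
#'
#' @param mask a [label_mask()] with at least one foreground voxel.
#' @return list with integer vectors `lo` and `hi`: half-open 0-based index
#'   ranges `[lo, hi)` per axis.
#' @export
bounding_box <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  idx <- which(mask$data == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("mask has no foreground voxels", call. = FALSE)
  lo <- apply(idx, 2, min) - 1L
  hi <- apply(idx, 2, max) # 1-based max == 0-based max + 1 (half-open)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

expand_box <- function(box, margin, shape) {
  if (margin <= 0) return(box)
  ext <- box$hi - box$lo
  pad <- pmax(0L, as.integer(round(ext * margin)))
  list(lo = pmax(0L, box$lo - pad),
       hi = pmin(as.integer(shape), box$hi + pad))
}

#' Resample a mask's bounding box onto the atlas lattice
#'
#' Maps the half-open box `[lo, hi)` onto the full lattice. With
#' `interp = "nearest"` each lattice voxel takes the value of the source voxel
#' whose cell contains the lattice voxel's centre (output exactly binary);
#' with `"linear"` the mask is trilinearly interpolated and re-binarized at
#' 0.5.
#'
#' @param mask a [label_mask()].
#' @param box half-open index box as returned by [bounding_box()].
#' @param cfg an [atlas_config()].
#' @return a [label_mask()] of the lattice shape.
#' @export
resample_to_lattice <- function(mask, box, cfg) {
  stopifnot(inherits(mask, "label_mask"), inherits(cfg, "atlas_config"))
  ext <- box$hi - box$lo
  if (any(ext <= 0L))
    stop("degenerate bounding box (zero extent on some axis)", call. = FALSE)
  S <- cfg$lattice
  if (cfg$interp == "nearest") {
    # lattice voxel i (0-based) samples source voxel lo + floor((i + 0.5) * ext / S)
    src_idx <- lapply(1:3, function(a) {
      i <- seq_len(S[a]) - 1L
      pmin(box$hi[a] - 1L, box$lo[a] + as.integer(floor((i + 0.5) * ext[a] / S[a]))) + 1L
    })
    out <- mask$data[src_idx[[1]], src_idx[[2]], src_idx[[3]], drop = FALSE]
  } else {
    # continuous coordinate of lattice voxel centre in source voxel units
    grids <- lapply(1:3, function(a) {
      i <- seq_len(S[a]) - 1L
      box$lo[a] + (i + 0.5) * ext[a] / S[a] - 0.5
    })
    coords <- as.matrix(expand.grid(x = grids[[1]], y = grids[[2]], z = grids[[3]]))
    vals <- trilinear_cpp(as.numeric(mask$data), dim(mask$data), coords, 0)
    out <- array(as.integer(vals >= 0.5), dim = S)
  }
  label_mask(array(as.integer(out), dim = S))
}

#' Signed Euclidean distance transform of a binary mask
#'
#' For every voxel, the Euclidean distance (in voxel units) to the nearest
#' voxel of the opposite class: positive inside the organ, negative outside.
#' Computed with an exact separable squared-distance transform.
#'
#' @param mask a [label_mask()] containing both foreground and background.
#' @return 3D numeric array of signed distances.
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  fg <- mask$data == 1
  if (all(fg) || !any(fg))
    stop("signed distance needs both foreground and background voxels",
         call. = FALSE)
  dims <- dim(mask$data)
  d_to_fg <- sqrt(edt_sq_cpp(as.vector(fg), dims))   # distance to nearest organ voxel
  d_to_bg <- sqrt(edt_sq_cpp(as.vector(!fg), dims))  # distance to nearest background voxel
  d <- ifelse(as.vector(fg), d_to_bg, -d_to_fg)
  array(d, dim = dims)
}

#' Sigmoid conversion of signed distance to probability
#'
#' `1 / (1 + exp(-gain * d))`: 0.5 on the boundary (d = 0), approaching 1
#' deep inside the organ and 0 far outside.
#'
#' @param d numeric array (or vector) of signed distances, positive inside.
#' @param gain positive sigmoid gain.
#' @return array of the same shape with values in (0, 1) (saturating to 0/1
#'   only by floating-point underflow at large `|d|`).
#' @export
sigmoid_probability <- function(d, gain) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("gain must be a single positive number", call. = FALSE)
  1 / (1 + exp(-gain * d))
}

#' Build a probabilistic atlas from training masks
#'
#' Each training mask is cropped to its (optionally margin-expanded) organ
#' bounding box, resampled to the lattice, converted to a signed distance map
#' and squashed through the sigmoid; the atlas is the voxelwise arithmetic
#' mean over cases.
#'
#' @param masks list of [label_mask()] objects, each with nonempty foreground.
#' @param cfg an [atlas_config()].
#' @return a [prob_atlas()] of the lattice shape.
#' @export
build_atlas <- function(masks, cfg = atlas_config()) {
  stopifnot(inherits(cfg, "atlas_config"))
  if (!is.list(masks) || length(masks) == 0L)
    stop("need at least one training mask", call. = FALSE)
  S <- cfg$lattice
  acc <- array(0, dim = S)
  for (m in masks) {
    stopifnot(inherits(m, "label_mask"))
    box <- expand_box(bounding_box(m), cfg$margin, dim(m$data))
    res <- resample_to_lattice(m, box, cfg)
    acc <- acc + sigmoid_probability(signed_distance(res), cfg$gain)
  }
  prob_atlas(acc / length(masks))
}
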