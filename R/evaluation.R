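#' Jaccard index between two masks
#'
#' `|E intersect G| / |E union G|` over voxels: 1 for identical nonempty
#' masks, 0 for disjoint nonempty masks. Two empty masks are defined to agree
#' perfectly (JI = 1); an empty vs a nonempty mask scores 0.
#'
#' @param e,g [label_mask()] objects of equal shape.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(e, g) {
  stopifnot(inherits(e, "label_mask"), inherits(g, "label_mask"))
  if (!identical(dim(e$data), dim(g$data)))
    stop("mask shapes differ", call. = FALSE)
  ee <- e$data == 1
  gg <- g$data == 1
  uni <- sum(ee | gg)
  if (uni == 0L) return(1)
  sum(ee & gg) / uni
}

#' Leave-one-out comparison of conventional vs atlas-weighted graph cut
#'
#' For each case in the cohort, the probabilistic atlas is built from all
#' other cases' ground-truth masks, fitted to the test case's seeds, and the
#' case is segmented twice with identical seeds: the conventional graph cut
#' (CGC, intensity data term only) and the atlas-weighted graph cut (AGC,
#' data term weighted by the fitted prior). Both are scored against the
#' ground truth with the Jaccard index.
#'
#' @param cohort list of cases; each case is a list with `volume`
#'   (a [volume3d()]), `mask` (ground-truth [label_mask()]) and optionally
#'   `seeds` (a [seed_image()]; simulated from the truth when absent).
#' @param atlas_cfg an [atlas_config()].
#' @param gc_cfg a [graph_cut_config()].
#' @param fit_mode homography mode for the atlas fit (see [fit_homography()]).
#' @param fit_opts a [fit_options()].
#' @param seed_args arguments for [simulate_seeds()] when a case carries no
#'   seeds (list; `rng_seed` is offset per case).
#' @param n_bins,floor,eps intensity-model settings.
#' @return data.frame of class `loo_result` with columns `case_id`, `ji_cgc`,
#'   `ji_agc`.
#' @export
leave_one_out <- function(cohort, atlas_cfg = atlas_config(),
                          gc_cfg = graph_cut_config(),
                          fit_mode = "projective", fit_opts = fit_options(),
                          seed_args = list(), n_bins = 64, floor = 1e-6,
                          eps = 1e-6) {
  if (!is.list(cohort) || length(cohort) < 2L)
    stop("cohort must contain at least two cases", call. = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    case <- cohort[[i]]
    seeds <- case$seeds
    if (is.null(seeds)) {
      sa <- seed_args
      sa$truth <- case$mask
      sa$rng_seed <- (sa$rng_seed %||% 1L) + i * 101L
      seeds <- do.call(simulate_seeds, sa)
    }
    atlas <- build_atlas(lapply(cohort[-i], `[[`, "mask"), atlas_cfg)
    fit <- fit_homography(atlas, seeds, mode = fit_mode, opts = fit_opts)
    prior <- warp_atlas_to_image(atlas, fit$homography, dim(case$volume$data))
    cgc <- segment_volume(case$volume, seeds, prior = NULL, cfg = gc_cfg,
                          n_bins = n_bins, floor = floor, eps = eps)
    agc <- segment_volume(case$volume, seeds, prior = prior, cfg = gc_cfg,
                          n_bins = n_bins, floor = floor, eps = eps)
    data.frame(case_id = i,
               ji_cgc = jaccard(cgc, case$mask),
               ji_agc = jaccard(agc, case$mask))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loo_result", class(out))
  out
}

#' @export
print.loo_result <- function(x, ...) {
  NextMethod()
  cat(sprintf("mean JI: CGC %.3f, AGC %.3f (n = %d)\n",
              mean(x$ji_cgc), mean(x$ji_agc), nrow(x)))
  invisible(x)
}

#' Corrective seed proposal from segmentation errors
#'
#' Simulates the expert-in-the-loop correction step: for each error type
#' (false negatives and false positives vs the ground truth), place one small
#' spherical stroke on the largest connected error component, centred at the
#' component voxel nearest its centroid. Proposed organ seeds lie in
#' false-negative regions (so inside the truth) and background seeds in
#' false-positive regions (outside the truth); existing seed voxels are never
#' relabelled.
#'
#' @param truth ground-truth [label_mask()].
#' @param seg current segmentation [label_mask()].
#' @param seeds current [seed_image()].
#' @param stroke_radius stroke ball radius (voxels).
#' @return updated [seed_image()] (identical to `seeds` when the segmentation
#'   is perfect).
#' @export
propose_corrective_seeds <- function(truth, seg, seeds, stroke_radius = 1.5) {
  stopifnot(inherits(truth, "label_mask"), inherits(seg, "label_mask"),
            inherits(seeds, "seed_image"))
  dims <- dim(truth$data)
  new_seeds <- seeds$data
  add_stroke <- function(err, code) {
    if (!any(err)) return(invisible(NULL))
    lab <- array(label_components_cpp(as.vector(err), dims, 6L), dims)
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    comp <- which(lab == big, arr.ind = TRUE)
    ctr <- colMeans(comp)
    nearest <- comp[which.min(colSums((t(comp) - ctr)^2)), ]
    ball <- ball_indices(nearest, stroke_radius, dims)
    ball <- ball[err[ball]] # clip the stroke to the error component's class
    if (any(new_seeds[ball] != SEED_NONE & new_seeds[ball] != code))
      stop("corrective stroke would contradict an existing seed", call. = FALSE)
    new_seeds[ball] <<- code
    invisible(NULL)
  }
  fn <- truth$data == 1 & seg$data == 0
  fp <- seg$data == 1 & truth$data == 0
  add_stroke(fn, SEED_ORGAN)
  add_stroke(fp, SEED_BACKGROUND)
  seed_image(new_seeds, alpha = seeds$alpha, spacing = seeds$spacing,
             origin = seeds$origin)
}

#' Iterative seed refinement against ground truth
#'
#' Runs the interactive protocol with a deterministic corrective oracle
#' standing in for the expert: segment, compare to the ground truth, add
#' corrective seed strokes on the largest error components, re-fit the atlas
#' (when one is supplied) and re-segment. Seeds are only ever added, so every
#' round's hard constraints contain the previous round's. The loop stops when
#' a round proposes no new seeds (the segmentation is perfect on the error
#' components reachable by strokes) or after `max_rounds`.
#'
#' @param vol the test [volume3d()].
#' @param truth ground-truth [label_mask()].
#' @param seeds initial [seed_image()].
#' @param atlas optional [prob_atlas()]; when supplied the prior is re-fitted
#'   to the current seeds each round (AGC), otherwise the plain CGC runs.
#' @param gc_cfg a [graph_cut_config()].
#' @param fit_mode,fit_opts homography fit settings (AGC only).
#' @param max_rounds round budget.
#' @param stroke_radius corrective stroke radius.
#' @param n_bins,floor,eps intensity-model settings.
#' @return list of class `refine_result`: `iterations` (data.frame with
#'   columns `round`, `n_seeds`, `ji`), `ji` (final), `mask` (final
#'   segmentation), `seeds` (final seed image), `converged` (TRUE when the
#'   loop stopped because no further correction was proposed).
#' @export
iterative_refinement <- function(vol, truth, seeds, atlas = NULL,
                                 gc_cfg = graph_cut_config(),
                                 fit_mode = "projective",
                                 fit_opts = fit_options(), max_rounds = 5,
                                 stroke_radius = 1.5, n_bins = 64,
                                 floor = 1e-6, eps = 1e-6) {
  stopifnot(inherits(vol, "volume3d"), inherits(truth, "label_mask"))
  validate_seeds(seeds)
  rows <- list()
  converged <- FALSE
  seg <- NULL
  for (round in seq_len(max_rounds)) {
    prior <- NULL
    if (!is.null(atlas)) {
      fit <- fit_homography(atlas, seeds, mode = fit_mode, opts = fit_opts)
      prior <- warp_atlas_to_image(atlas, fit$homography, dim(vol$data))
    }
    seg <- segment_volume(vol, seeds, prior = prior, cfg = gc_cfg,
                          n_bins = n_bins, floor = floor, eps = eps)
    rows[[round]] <- data.frame(round = round,
                                n_seeds = sum(seeds$data != SEED_NONE),
                                ji = jaccard(seg, truth))
    updated <- propose_corrective_seeds(truth, seg, seeds, stroke_radius)
    if (identical(updated$data, seeds$data)) {
      converged <- TRUE
      break
    }
    if (round == max_rounds) break # budget exhausted; keep the seeds used
    seeds <- updated
  }
  it <- do.call(rbind, rows)
  structure(list(iterations = it, ji = it$ji[nrow(it)], mask = seg,
                 seeds = seeds, converged = converged),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> %d round(s), final JI %.3f (%s)\n",
              nrow(x$iterations), x$ji,
              if (x$converged) "converged" else "round budget reached"))
  invisible(x)
}

#' Write leave-one-out results to CSV
#'
#' @param results a `loo_result` data.frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
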