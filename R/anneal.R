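#' Parameters of one simulated-annealing stage
#'
#' @param iterations number of single-node proposals.
#' @param node_counts (gz, gy, gx) node counts for the stage.
#' @param resolution_um isotropic image resolution the stage runs at; stages
#'   never upsample past the native spacing of the inputs.
#' @param t0 initial temperature.
#' @param t_final final temperature (default t0/30, reached at the last
#'   iteration by geometric decay).
#' @param initial_step_fraction initial proposal sigma as a fraction of the
#'   stage's minimum node spacing (default 0.2).
#' @return a `bw_stage` parameter list.
#' @export
stage_params <- function(iterations, node_counts, resolution_um, t0,
                         t_final = t0 / 30, initial_step_fraction = 0.2) {
  stopifnot(iterations >= 1, t0 > 0, t_final > 0)
  structure(list(iterations = as.integer(iterations),
                 node_counts = as.integer(node_counts),
                 resolution_um = resolution_um, t0 = t0, t_final = t_final,
                 initial_step_fraction = initial_step_fraction),
            class = "bw_stage")
}

#' Default 4-stage coarse-to-fine schedule
#'
#' 2000 iterations per stage; node counts 2x2x2, 5x3x2, 9x5x3, 9x9x5
#' (assigned as (y, x, z) to put the densest node rows on the longest brain
#' axes, i.e. (z, y, x) counts (2,2,2), (2,5,3), (3,9,5), (5,9,9)); stage
#' resolutions 96, 96, 96, 48 um; initial temperatures 1e-3, 1e-3, 1e-4,
#' 1e-5, each decaying to 1/30 of its initial value.
#'
#' @param iteration_factor multiplies the per-stage iteration counts
#'   (whole-brain alignment conventionally uses 2).
#' @return list of `bw_stage` objects.
#' @export
default_schedule <- function(iteration_factor = 1) {
  its <- as.integer(2000 * iteration_factor)
  list(
    stage_params(its, c(2, 2, 2), 96, 1e-3),
    stage_params(its, c(2, 5, 3), 96, 1e-3),
    stage_params(its, c(3, 9, 5), 96, 1e-4),
    stage_params(its, c(5, 9, 9), 48, 1e-5))
}

#' Whole-brain schedule: doubled iterations
#'
#' Whole brains (rather than hemispheres) are aligned with twice the usual
#' number of iterations; pair it with a low energy weight (lambda = 1e-5)
#' when alignment matters more than feature preservation.
#'
#' @return list of `bw_stage` objects.
#' @export
whole_brain_schedule <- function() default_schedule(iteration_factor = 2)

#' Reduced schedule for small phantom studies
#'
#' Three coarse-to-fine stages at 192 um, ending on the full 9x9x5 node
#' grid with a cold final stage, for desk-scale synthetic series where
#' per-sample deformations are smooth and bounded; used by the
#' temporal-staging simulations to keep many-pair studies in the minutes
#' range.
#'
#' @return list of `bw_stage` objects.
#' @export
reduced_schedule <- function() {
  list(
    stage_params(400, c(2, 2, 2), 192, 1e-3),
    stage_params(500, c(2, 5, 3), 192, 1e-4),
    stage_params(900, c(5, 9, 9), 192, 1e-5))
}

#' Simulated-annealing acceptance probability
#'
#' p = min(exp(dE / temperature), 1), where dE is the objective change
#' (positive = improvement; improvements are always accepted). A
#' non-positive temperature degenerates to the greedy rule: accept iff
#' dE > 0.
#'
#' @param dE objective change, new minus old.
#' @param temperature annealing temperature.
#' @return acceptance probability (vectorized).
#' @export
acceptance_probability <- function(dE, temperature) {
  if (any(temperature <= 0))
    return(as.numeric(dE > 0))
  pmin(exp(dE / temperature), 1)
}

#' Attention weights over grid nodes
#'
#' Probability of selecting each node for a proposal, proportional to the L1
#' difference between the warped source and the target within the grid cells
#' adjacent to the node (plus a 1e-12 floor), normalized to sum 1. Mismatch
#' concentrates proposals where alignment is poor.
#'
#' @param source_warped,target filtered volumes of identical shape.
#' @param g a `bw_grid`.
#' @param eps floor added to every node weight (default 1e-12).
#' @return numeric array of node weights, dim = node_counts, summing to 1.
#' @export
node_attention_weights <- function(source_warped, target, g, eps = 1e-12) {
  a <- if (is.list(source_warped)) source_warped$data else source_warped
  b <- if (is.list(target)) target$data else target
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  cl1 <- cpp_cell_l1(a, b, g$volume_shape, g$node_counts)
  nc <- g$node_counts
  w <- array(eps, nc)
  dcell <- dim(cl1)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    # cell (cz,cy,cx) is incident to node (cz+dz, cy+dy, cx+dx)
    w[(1:dcell[1]) + dz, (1:dcell[2]) + dy, (1:dcell[3]) + dx] <-
      w[(1:dcell[1]) + dz, (1:dcell[2]) + dy, (1:dcell[3]) + dx] + cl1
  }
  w / sum(w)
}

#' Run one annealing stage
#'
#' Performs `params$iterations` single-node proposals on images already
#' resampled to the stage resolution: a node is selected by attention (or
#' uniformly), a zero-mean Gaussian 3-vector displacement with the current
#' sigma is proposed, and accepted with probability min(exp(dObj/t), 1).
#' Sigma divides by 0.99 on success, multiplies by 0.99 on failure, clamped
#' to [0.01, 1] times the minimum node spacing; temperature decays
#' geometrically from t0 to t_final across the stage. Only grid cells
#' adjacent to the displaced node are re-warped per iteration; cached
#' statistics are refreshed by a full recomputation every `recompute_every`
#' iterations and at the stage end (the residual is reported as `drift`).
#'
#' @param source,target filtered volumes at the stage resolution.
#' @param g starting `bw_grid` (already refined to the stage node counts).
#' @param params a `bw_stage`.
#' @param lambda deformation-energy weight.
#' @param sigma0 initial proposal sigma in voxels (default:
#'   `initial_step_fraction` of the minimum node spacing).
#' @param greedy zero-temperature mode: accept only improvements.
#' @param attention use mismatch-gated node selection (default TRUE).
#' @param recompute_every full cache refresh period (default 200).
#' @return list: `grid`, `trace` (data.frame), `sigma`, `similarity`,
#'   `energy`, `objective`, `drift`.
#' @export
anneal_stage <- function(source, target, g, params, lambda = 1 / 1000,
                         sigma0 = NULL, greedy = FALSE, attention = TRUE,
                         recompute_every = 200L) {
  sv <- if (is.list(source)) source$data else source
  tv <- if (is.list(target)) target$data else target
  if (!identical(dim(sv), dim(tv))) stop("shape mismatch")
  if (!identical(dim(sv), as.integer(g$volume_shape)))
    stop("grid does not span the images")
  sp <- grid_spacing(g)
  if (is.null(sigma0)) sigma0 <- params$initial_step_fraction * min(sp)
  res <- cpp_sa_stage(sv, tv, g$volume_shape, g$displacements,
                      g$node_counts, lambda, params$t0,
                      params$t_final / params$t0, params$iterations, sigma0,
                      0.01 * min(sp), 1.0 * min(sp), greedy, attention,
                      as.integer(recompute_every))
  g$displacements <- res$disp
  list(grid = g, trace = res$trace, sigma = res$sigma,
       similarity = res$similarity, energy = res$energy,
       objective = res$objective, drift = res$drift)
}

#' Register one filtered volume onto another
#'
#' Runs the full coarse-to-fine schedule: at each stage both images are
#' downsampled to the stage resolution (block averaging; never upsampled
#' past their native spacing), the grid is refined to the stage node counts
#' with interpolated displacements, and an annealing stage is run. The
#' returned grid is expressed in full-resolution voxel units, ready for
#' [warp_volume()] on the native images. Deterministic given `seed`: node
#' choice, proposal components and the acceptance draw consume R's RNG
#' stream in that fixed order each iteration.
#'
#' @param source,target filtered volumes at a common native resolution.
#' @param schedule list of `bw_stage` objects (default [default_schedule()]).
#' @param lambda deformation-energy weight (default 1/1000).
#' @param seed integer RNG seed.
#' @param greedy,attention optimizer ablations (see [anneal_stage()]).
#' @param temperature0 optional vector overriding each stage's t0 (final
#'   temperatures keep the t0/30 ratio).
#' @return list: `grid` (full-resolution `bw_grid`), `trace` (data.frame
#'   with a `stage` column), `similarity`, `energy`, `objective`.
#' @export
register_pair <- function(source, target, schedule = default_schedule(),
                          lambda = 1 / 1000, seed = 1L, greedy = FALSE,
                          attention = TRUE, temperature0 = NULL) {
  if (length(schedule) == 0) stop("empty schedule")
  if (!identical(dim(source$data), dim(target$data)))
    stop("source and target must share shape")
  native <- rep(source$spacing_um, length.out = 3)
  if (max(native) - min(native) > 1e-9)
    stop("inputs must be isotropic; run load_and_standardize() first")
  native <- native[1]

  with_seed(seed, {
    g <- NULL
    f_prev <- NA_real_
    traces <- list()
    last <- NULL
    for (k in seq_along(schedule)) {
      par <- schedule[[k]]
      if (!is.null(temperature0)) {
        par$t0 <- temperature0[min(k, length(temperature0))]
        par$t_final <- par$t0 / 30
      }
      eff <- max(par$resolution_um, native) # clamp: never upsample
      f <- eff / native
      s_k <- resample_volume(source, eff)
      t_k <- resample_volume(target, eff)
      dims <- dim(s_k$data)
      if (is.null(g)) {
        g <- create_grid(dims, par$node_counts, eff)
      } else {
        # carry displacements across the resolution change, then refine
        g$displacements <- g$displacements * (f_prev / f)
        g$volume_shape <- as.integer(dims)
        g$spacing_um <- eff
        g <- refine_grid(g, par$node_counts)
      }
      st <- anneal_stage(s_k, t_k, g, par, lambda = lambda,
                         greedy = greedy, attention = attention)
      g <- st$grid
      tr <- st$trace
      tr$stage <- k
      traces[[k]] <- tr
      last <- st
      f_prev <- f
    }
    # express the final grid in native voxel units
    g$displacements <- g$displacements * f_prev
    g$volume_shape <- as.integer(dim(source$data))
    g$spacing_um <- native
    list(grid = g, trace = do.call(rbind, traces),
         similarity = last$similarity, energy = last$energy,
         objective = last$objective)
  })
}
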