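#' Mirror a volume across the left-right axis
#'
#' Index reversal along X; the side label flips. Applying it twice is the
#' identity.
#'
#' @param v a `bw_volume`.
#' @return the mirrored volume.
#' @export
mirror_volume <- function(v) {
  nx <- dim(v$data)[3]
  out <- v$data[, , nx:1, drop = FALSE]
  flip <- c(whole = "whole", left = "right", right = "left")
  as_volume(out, v, side = unname(flip[v$side]))
}

pad_x_even <- function(v) {
  d <- dim(v$data)
  if (d[3] %% 2 == 0) return(v)
  # symmetric zero padding: one plane appended so the mid-plane stays put
  out <- array(0, d + c(0, 0, 1))
  out[, , seq_len(d[3])] <- v$data
  as_volume(out, v)
}

#' Symmetrize a brain and split it into hemispheres
#'
#' Registers the brain's filtered image to its mirror image, yielding a
#' transformation T; warps the original by T/2 (every node displacement
#' halved), which places the anatomical symmetry plane at the volume
#' mid-plane; pads X to even length if needed; splits at the mid-plane; and
#' stores the left half mirrored into right-hemisphere coordinates so all
#' downstream registration operates in a single frame.
#'
#' @param v a `bw_volume` (side "whole").
#' @param schedule annealing schedule for the mirror registration.
#' @param seed RNG seed.
#' @param threshold,log_radius preprocessing parameters.
#' @param lambda deformation-energy weight.
#' @param min_objective symmetrization fails (error) if the mirror
#'   registration's final objective falls below this floor.
#' @return list of class `bw_hemipair`: `right`, `left_mirrored` (volumes),
#'   `right_filtered`, `left_mirrored_filtered`, `symmetrizing_grid` (the
#'   T/2 grid), `sample_id`.
#' @export
symmetrize_and_split <- function(v, schedule = default_schedule(), seed = 1L,
                                 threshold = 0.01, log_radius = 5,
                                 lambda = 1 / 1000, min_objective = 0.2) {
  f <- preprocess_volume(v, threshold, log_radius)
  fm <- mirror_volume(f)
  reg <- register_pair(f, fm, schedule = schedule, lambda = lambda,
                       seed = seed)
  if (reg$objective < min_objective)
    stop(sprintf("symmetrization failed for %s: objective %.3f < %.3f",
                 v$sample_id, reg$objective, min_objective))
  half <- reg$grid
  half$displacements <- half$displacements / 2
  v_sym <- pad_x_even(warp_volume(v, half))
  f_sym <- pad_x_even(warp_volume(f, half))
  nx <- dim(v_sym$data)[3]
  lhs <- seq_len(nx / 2)
  rhs <- seq(nx / 2 + 1, nx)
  take <- function(vol, idx, side, mirror) {
    h <- as_volume(vol$data[, , idx, drop = FALSE], vol, side = side)
    if (mirror) h$data <- h$data[, , rev(seq_along(idx)), drop = FALSE]
    h
  }
  # right hemisphere: keep orientation, midline at x = 1
  right <- take(v_sym, rhs, "right", mirror = FALSE)
  right_f <- take(f_sym, rhs, "right", mirror = FALSE)
  # left hemisphere mirrored into right-hemisphere coordinates
  left <- take(v_sym, lhs, "left", mirror = TRUE)
  left_f <- take(f_sym, lhs, "left", mirror = TRUE)
  structure(list(right = right, left_mirrored = left,
                 right_filtered = right_f, left_mirrored_filtered = left_f,
                 symmetrizing_grid = half, sample_id = v$sample_id),
            class = "bw_hemipair")
}
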