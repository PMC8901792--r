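#' Specification of a developing-brain phantom
#'
#' Phantoms emulate the statistical structure of whole-mount perinatal brain
#' stacks that the registration pipeline assumes: a growing, bilaterally
#' symmetric ellipsoidal sample with bright internal structures whose
#' intensities change linearly with developmental age — a shell-like region
#' ("cerebellum", intensity rising) and a tube-like midline region ("RMS",
#' intensity falling). Axes: Z dorsoventral (shortest), Y rostrocaudal
#' (longest), X left-right (the mirror axis).
#'
#' @param shape voxel extents (nz, ny, nx), default 64^3.
#' @param spacing_um nominal voxel spacing, default 96.
#' @param semiaxes0 ellipsoid semi-axes at age 0, voxels (z, y, x).
#' @param growth semi-axis growth per day, voxels (z, y, x).
#' @param base_intensity interior tissue intensity.
#' @param shell_center (z, y, x) offset of the shell center from the volume
#'   center, voxels; x must be 0 for bilateral symmetry.
#' @param shell_radius0,shell_growth,shell_thickness shell mid-radius at age
#'   0, radius growth per day, and half-thickness (voxels).
#' @param shell_intensity0,shell_slope shell intensity at age 0 and change
#'   per day (positive: proliferation rises).
#' @param tube_radius tube radius (voxels); the tube runs along Y on the
#'   midline.
#' @param tube_y y-range of the tube relative to the center, voxels.
#' @param tube_intensity0,tube_slope tube intensity at age 0 and change per
#'   day (negative: proliferation falls); floored at 0.05.
#' @param asymmetry_amp left-right asymmetry: x-shift of the shell center,
#'   voxels (default 0.5).
#' @param noise_sd additive Gaussian noise inside the sample, as a fraction
#'   of the dynamic range (default 0.02); background receives a tenth of it;
#'   clipped at 0.
#' @param shell_sites,tube_sites number of candidate labeled-cell sites in
#'   the shell and tube regions. Each site is a fixed anatomical position
#'   (identical across samples from the same spec, mirrored across the
#'   midline) with a site-specific age threshold: shell sites switch ON as
#'   age passes the threshold (proliferation appearing), tube sites switch
#'   OFF (proliferation fading). Labeled cells are what the imaging signal
#'   measures, and a coarse deformation grid cannot create or remove them,
#'   so this layer carries the developmental-age signal through
#'   registration.
#' @param site_radius,site_intensity Gaussian radius (voxels) and amplitude
#'   of one labeled-cell bump.
#' @param site_age_range age range (days) over which site thresholds are
#'   uniformly spread.
#' @param site_seed RNG seed for the site table (part of the spec: the same
#'   spec always yields the same anatomy).
#' @return list of class `bw_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing_um = 96,
                         semiaxes0 = c(10, 16, 13),
                         growth = c(0.8, 1.2, 1.0), base_intensity = 0.3,
                         shell_center = c(0, -10, 0), shell_radius0 = 5,
                         shell_growth = 0.5, shell_thickness = 1.6,
                         shell_intensity0 = 0.5, shell_slope = 0.1,
                         tube_radius = 2.2, tube_y = c(-2, 12),
                         tube_intensity0 = 0.9, tube_slope = -0.12,
                         asymmetry_amp = 0.5, noise_sd = 0.02,
                         shell_sites = 150L, tube_sites = 40L,
                         site_radius = 1.2, site_intensity = 1.2,
                         site_age_range = c(0, 6), site_seed = 20220307L) {
  spec <- as.list(environment())
  spec$sites <- make_site_table(spec)
  structure(spec, class = "bw_phantom_spec")
}

# fixed table of labeled-cell sites: positions (relative to the volume
# center, mirrored in x so the anatomy is bilaterally symmetric), region,
# and the age threshold at which each site switches
make_site_table <- function(spec) {
  with_seed(spec$site_seed, {
    ref_age <- mean(spec$site_age_range)
    rs <- spec$shell_radius0 + spec$shell_growth * ref_age
    n_sh <- spec$shell_sites
    # shell sites: random directions at the reference shell radius
    u <- matrix(rnorm(3 * n_sh), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- rs + runif(n_sh, -1, 1) * spec$shell_thickness
    sh <- sweep(u * r, 2, spec$shell_center, "+")
    # tube sites: along the midline tube
    n_tb <- spec$tube_sites
    tb <- cbind(runif(n_tb, -1, 1) * spec$tube_radius * 0.7,
                runif(n_tb, spec$tube_y[1], spec$tube_y[2]),
                runif(n_tb, -1, 1) * spec$tube_radius * 0.7)
    pos <- rbind(sh, tb)
    pos[, 3] <- abs(pos[, 3]) # right half; mirrored when rendered
    region <- rep(c("shell", "tube"), c(n_sh, n_tb))
    thr <- runif(n_sh + n_tb, spec$site_age_range[1], spec$site_age_range[2])
    data.frame(z = pos[, 1], y = pos[, 2], x = pos[, 3], region = region,
               threshold = thr, stringsAsFactors = FALSE)
  })
}

# add a Gaussian bump at a (z, y, x) position relative to the volume center
add_bump <- function(a, ctr, p, radius, amp) {
  d <- dim(a)
  R <- ceiling(3 * radius)
  c0 <- ctr + p # 1-based center
  lo <- pmax(1, floor(c0 - R))
  hi <- pmin(d, ceiling(c0 + R))
  if (any(lo > hi)) return(a)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  r2 <- outer(outer((zi - c0[1])^2, (yi - c0[2])^2, "+"), (xi - c0[3])^2,
              "+")
  a[zi, yi, xi] <- a[zi, yi, xi] + amp * exp(-r2 / (2 * radius^2))
  a
}

#' Generate a phantom volume at a given developmental age
#'
#' Deterministic given (spec, age, seed); bilaterally symmetric up to the
#' spec's asymmetry amplitude and noise. Region label masks (the ground
#' truth for dynamics checks) are returned alongside the volume.
#'
#' @param spec a `bw_phantom_spec`.
#' @param age developmental age in days.
#' @param seed RNG seed for the noise draw.
#' @param sample_id,side,recorded_age_days metadata for the volume (recorded
#'   age defaults to `age`).
#' @return list: `volume` (a `bw_volume`), `labels` (list of logical arrays
#'   interior/shell/tube, pairwise disjoint).
#' @export
make_phantom <- function(spec, age, seed = 1L, sample_id = "phantom",
                         side = "whole", recorded_age_days = age) {
  d <- spec$shape
  if (any(spec$semiaxes0 + spec$growth * age >= (d - 2) / 2))
    stop("phantom regions exceed the volume at this age")
  ctr <- (d + 1) / 2 # symmetric under index reversal
  zc <- seq_len(d[1]) - ctr[1]
  yc <- seq_len(d[2]) - ctr[2]
  xc <- seq_len(d[3]) - ctr[3]
  ax <- spec$semiaxes0 + spec$growth * age
  Z <- array(zc, d)
  Y <- aperm(array(yc, d[c(2, 1, 3)]), c(2, 1, 3))
  X <- aperm(array(xc, d[c(3, 2, 1)]), c(3, 2, 1))
  inside <- (Z / ax[1])^2 + (Y / ax[2])^2 + (X / ax[3])^2 <= 1

  sc <- spec$shell_center
  rs <- spec$shell_radius0 + spec$shell_growth * age
  r_shell <- sqrt((Z - sc[1])^2 + (Y - sc[2])^2 +
                    (X - sc[3] - spec$asymmetry_amp)^2)
  shell <- abs(r_shell - rs) <= spec$shell_thickness & inside
  r_tube <- sqrt((Z - 0)^2 + (X + spec$asymmetry_amp / 2)^2)
  tube <- r_tube <= spec$tube_radius & Y >= spec$tube_y[1] &
    Y <= spec$tube_y[2] & inside & !shell

  shell_i <- max(spec$shell_intensity0 + spec$shell_slope * age, 0.05)
  tube_i <- max(spec$tube_intensity0 + spec$tube_slope * age, 0.05)
  a <- array(0, d)
  a[inside] <- spec$base_intensity
  a[shell] <- spec$base_intensity + shell_i
  a[tube] <- spec$base_intensity + tube_i

  # labeled-cell layer: shell sites switch on with age, tube sites off
  st <- spec$sites
  if (!is.null(st) && nrow(st)) {
    on <- ifelse(st$region == "shell", age >= st$threshold,
                 age <= st$threshold)
    for (i in which(on)) {
      sft <- spec$asymmetry_amp / 2
      a <- add_bump(a, ctr, c(st$z[i], st$y[i], st$x[i] + sft),
                    spec$site_radius, spec$site_intensity)
      a <- add_bump(a, ctr, c(st$z[i], st$y[i], -st$x[i] + sft),
                    spec$site_radius, spec$site_intensity)
    }
    a[!inside] <- 0 # cells live inside the sample
  }

  if (spec$noise_sd > 0) {
    rng <- max(a)
    a <- with_seed(seed, {
      nin <- array(rnorm(prod(d), 0, spec$noise_sd * rng), d)
      nout <- array(rnorm(prod(d), 0, 0.1 * spec$noise_sd * rng), d)
      a + ifelse(inside, nin, nout)
    })
    a[a < 0] <- 0
  }
  v <- volume(a, spacing_um = spec$spacing_um, sample_id = sample_id,
              side = side, recorded_age_days = recorded_age_days)
  list(volume = v,
       labels = list(interior = inside & !shell & !tube, shell = shell,
                     tube = tube))
}

#' Warp a volume by a random smooth ground-truth deformation
#'
#' Draws node displacements uniformly in +/- `max_disp_fraction` of the
#' per-axis cell size on a regular grid and returns the warped volume
#' together with the generating grid (the ground truth for recovery
#' experiments).
#'
#' @param v a `bw_volume`.
#' @param max_disp_fraction displacement bound as a fraction of cell size,
#'   in (0, 0.5] (default 0.2).
#' @param node_counts grid node counts (default c(3, 4, 4)).
#' @param seed RNG seed.
#' @return list: `volume` (warped), `grid` (the generating `bw_grid`).
#' @export
apply_ground_truth_deformation <- function(v, max_disp_fraction = 0.2,
                                           node_counts = c(3, 4, 4),
                                           seed = 1L) {
  stopifnot(max_disp_fraction >= 0, max_disp_fraction <= 0.5)
  if (max_disp_fraction == 0) { # degenerate: identity
    g <- create_grid(dim(v$data), node_counts, v$spacing_um)
    return(list(volume = v, grid = g))
  }
  g <- create_grid(dim(v$data), node_counts, v$spacing_um)
  cell <- grid_spacing(g)
  nn <- prod(g$node_counts)
  g$displacements <- with_seed(seed, {
    array(c(runif(nn, -1, 1) * max_disp_fraction * cell[1],
            runif(nn, -1, 1) * max_disp_fraction * cell[2],
            runif(nn, -1, 1) * max_disp_fraction * cell[3]),
          c(g$node_counts, 3))
  })
  list(volume = warp_volume(v, g), grid = g)
}

#' Generate a jittered developmental series with ground truth
#'
#' Each sample's true developmental age is its recorded age plus a uniform
#' jitter in +/- `age_jitter` days (the mismatch between birth date and
#' brain development that temporal staging should recover); morphology is
#' generated at the true age, and each sample additionally receives a
#' random smooth anatomical deformation bounded by `max_disp_fraction` of
#' the jitter-grid cell size.
#'
#' @param spec a `bw_phantom_spec`.
#' @param recorded_ages recorded ages (days), >= 2 values.
#' @param per_age samples per recorded age (default 1).
#' @param age_jitter uniform jitter half-width in days (default 0.5).
#' @param max_disp_fraction anatomical jitter bound (default 0.2).
#' @param jitter_nodes node counts of the anatomical jitter grid. The
#'   default (5, 8, 8) keeps same-age samples closer to each other than to
#'   neighbouring age groups (correlation-distance within a group roughly a
#'   tenth of the full developmental range), the regime age-block distance
#'   matrices of perinatal series show.
#' @param seed RNG seed.
#' @param side side label given to the samples (default "right": the series
#'   emulates a set of co-oriented hemisphere frames).
#' @param hemisphere_pairs if TRUE, `per_age` counts hemispheres (must be
#'   even) and samples come in left/right pairs: both hemispheres of a
#'   brain share its true developmental age and its anatomical jitter
#'   deformation (a rigid-brain assumption) but have independent voxel
#'   noise, mirroring how hemisphere splitting doubles a real sample set.
#' @return list: `samples` (a `bw_samples` set with raw volumes attached as
#'   `$raw`), `truth` (data.frame: key, recorded, true age), `grids` (the
#'   per-sample jitter grids).
#' @export
make_series <- function(spec, recorded_ages, per_age = 1, age_jitter = 0.5,
                        max_disp_fraction = 0.2, jitter_nodes = c(5, 8, 8),
                        seed = 1L, side = "right",
                        hemisphere_pairs = FALSE) {
  stopifnot(length(recorded_ages) >= 2)
  if (hemisphere_pairs && per_age %% 2 != 0)
    stop("hemisphere_pairs needs an even per_age")
  n_units <- if (hemisphere_pairs) per_age / 2 else per_age
  plan <- expand.grid(rep = seq_len(n_units), age = recorded_ages)
  n <- nrow(plan)
  draws <- with_seed(seed, {
    list(jit = runif(n, -age_jitter, age_jitter),
         seeds = sample.int(.Machine$integer.max / 2, 3 * n))
  })
  vols <- list()
  grids <- list()
  truth <- NULL
  for (i in seq_len(n)) {
    rec <- plan$age[i]
    tru <- rec + draws$jit[i]
    id <- sprintf("p%03.0f_%02d", rec * 10, plan$rep[i])
    sides <- if (hemisphere_pairs) c("right", "left") else side
    jg <- NULL
    for (s in seq_along(sides)) {
      ph <- make_phantom(spec, tru,
                         seed = draws$seeds[(s - 1) * n + i],
                         sample_id = id, side = sides[s],
                         recorded_age_days = rec)
      if (is.null(jg))
        jg <- apply_ground_truth_deformation(ph$volume, max_disp_fraction,
                                             jitter_nodes,
                                             seed = draws$seeds[2 * n + i]
                                             )$grid
      key <- paste(id, sides[s], sep = "_")
      vols[[key]] <- warp_volume(ph$volume, jg)
      grids[[key]] <- jg
      truth <- rbind(truth, data.frame(
        key = key, sample_id = id, recorded_age_days = rec,
        true_age_days = tru, stringsAsFactors = FALSE))
    }
  }
  samples <- hemisphere_set(unname(vols))
  for (k in seq_along(samples)) samples[[k]]$raw <- vols[[k]]
  list(samples = samples, truth = truth, grids = grids)
}

#' Composition residual between an estimated and a true deformation
#'
#' Registering (warped, original) estimates the inverse of the generating
#' field, so recovery is scored as the RMS over foreground voxels of
#' f_est(x) + f_true(x + f_est(x)) — zero iff the estimated warp exactly
#' undoes the ground truth. Background voxels carry no image evidence and
#' are excluded.
#'
#' @param g_est estimated `bw_grid` (maps warped back onto the original).
#' @param g_true generating `bw_grid` (used to create the warped volume).
#' @param mask logical/0-1 array of foreground voxels of the original.
#' @return RMS residual in voxels.
#' @export
field_recovery_error <- function(g_est, g_true, mask) {
  f_est <- displacement_field(g_est)
  d <- dim(mask)
  idx <- which(mask > 0, arr.ind = TRUE) - 1
  fe <- cbind(f_est[, , , 1][mask > 0], f_est[, , , 2][mask > 0],
              f_est[, , , 3][mask > 0])
  pts <- idx + fe
  ft <- cpp_field_at_points(pts, g_true$volume_shape,
                            g_true$displacements, g_true$node_counts)
  resid <- fe + ft
  sqrt(mean(rowSums(resid^2)))
}
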