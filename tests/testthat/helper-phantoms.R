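# Shared fixtures and independent oracles, all generated in code.

# small solid ellipsoid phantom (no equalization quirks), optionally with an
# interior blob; returns a raw bw_volume
ellipsoid_volume <- function(d = c(32, 32, 32), semi = c(11, 13, 13),
                             center_shift = c(0, 0, 0), base = 0.3,
                             blob_off = NULL, blob_r = 3, blob_int = 1,
                             spacing_um = 96) {
  ctr <- (d + 1) / 2 + center_shift
  zc <- array(seq_len(d[1]), d) - ctr[1]
  yc <- aperm(array(seq_len(d[2]), d[c(2, 1, 3)]), c(2, 1, 3)) - ctr[2]
  xc <- aperm(array(seq_len(d[3]), d[c(3, 2, 1)]), c(3, 2, 1)) - ctr[3]
  a <- array(0, d)
  inside <- (zc / semi[1])^2 + (yc / semi[2])^2 + (xc / semi[3])^2 <= 1
  a[inside] <- base
  if (!is.null(blob_off)) {
    b <- (zc - blob_off[1])^2 + (yc - blob_off[2])^2 +
      (xc - blob_off[3])^2 <= blob_r^2
    a[b & inside] <- blob_int
  }
  volume(a, spacing_um = spacing_um, sample_id = "ellipsoid")
}

# adversarial pair for optimizer ablations: identical outer masks up to a
# global shift, with an interior blob that must travel across a uniform
# region (a similarity plateau sloped only by the deformation energy) to
# reach its counterpart
two_optimum_pair <- function() {
  d <- rep(40L, 3)
  ctr <- (d + 1) / 2
  zc <- array(seq_len(d[1]), d) - ctr[1]
  yc <- aperm(array(seq_len(d[2]), d[c(2, 1, 3)]), c(2, 1, 3)) - ctr[2]
  xc <- aperm(array(seq_len(d[3]), d[c(3, 2, 1)]), c(3, 2, 1)) - ctr[3]
  img <- function(off, s) {
    inside <- (zc / 16)^2 + ((yc - s) / 17)^2 + ((xc - s) / 17)^2 <= 1
    b <- (zc^2 + (yc - s)^2 + (xc - s - off)^2) <= 3^2
    a <- array(0, d)
    a[inside] <- 0.3
    a[b] <- 1.0
    volume(a, 96)
  }
  list(src = preprocess_volume(img(4, 2), log_radius = 2.5,
                               equalize = FALSE),
       tgt = preprocess_volume(img(-4, 0), log_radius = 2.5,
                               equalize = FALSE))
}

# schedule used with two_optimum_pair(): hot middle stage so the optimizer
# can diffuse across the plateau, cold last stage to settle
ablation_schedule <- function() {
  list(stage_params(500, c(2, 2, 2), 96, 1e-3),
       stage_params(2500, c(4, 5, 5), 96, 1e-3),
       stage_params(500, c(4, 5, 5), 96, 1e-5))
}

# schedule for the regularization contrast: noise-mismatched same-age
# phantoms and a long cold stage where the energy term biases acceptance
quench_schedule <- function() {
  list(stage_params(300, c(2, 2, 2), 192, 1e-3),
       stage_params(1200, c(3, 4, 4), 192, 1e-4),
       stage_params(3000, c(3, 5, 5), 192, 1e-6))
}

# short schedule for smoke-scale registrations in module tests
tiny_schedule <- function(iters = c(300, 400)) {
  list(stage_params(iters[1], c(2, 2, 2), 192, 1e-3),
       stage_params(iters[2], c(2, 5, 3), 192, 1e-4))
}

# ---- independent oracles ----------------------------------------------------

# brute-force tetrahedral volume-change energy (mirrors the documented
# 5-tetrahedra alternating-parity decomposition, implemented independently
# in R from first principles)
tetra_energy_oracle <- function(g) {
  nc <- g$node_counts
  vs <- g$volume_shape
  h <- (vs - 1) / (nc - 1)
  D <- g$displacements
  vol <- function(P) {
    a <- P[2, ] - P[1, ]; b <- P[3, ] - P[1, ]; c <- P[4, ] - P[1, ]
    (a[1] * (b[2] * c[3] - b[3] * c[2]) -
       a[2] * (b[1] * c[3] - b[3] * c[1]) +
       a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
  }
  corn <- expand.grid(dz = 0:1, dy = 0:1, dx = 0:1)
  code <- corn$dz * 4 + corn$dy * 2 + corn$dx
  pc <- (corn$dz + corn$dy + corn$dx) %% 2
  e <- 0
  for (cz in 0:(nc[1] - 2)) for (cy in 0:(nc[2] - 2))
    for (cx in 0:(nc[3] - 2)) {
      par <- (cz + cy + cx) %% 2
      centpar <- if (par == 0) 1 else 0
      getP <- function(i, disp) {
        p <- c((cz + corn$dz[i]) * h[1], (cy + corn$dy[i]) * h[2],
               (cx + corn$dx[i]) * h[3])
        if (disp)
          p <- p + D[cz + corn$dz[i] + 1, cy + corn$dy[i] + 1,
                     cx + corn$dx[i] + 1, ]
        p
      }
      cen <- which(pc == centpar)[order(code[pc == centpar])]
      tets <- list(cen)
      for (i in which(pc != centpar)) {
        nb <- sapply(c(4, 2, 1),
                     function(m) which(code == bitwXor(code[i], m)))
        tets[[length(tets) + 1]] <- c(i, nb)
      }
      for (t in tets) {
        Pd <- do.call(rbind, lapply(t, getP, disp = TRUE))
        Pr <- do.call(rbind, lapply(t, getP, disp = FALSE))
        e <- e + abs(vol(Pd) - vol(Pr))
      }
    }
  e / prod(vs - 1)
}

# closed-form trilinear interpolation of node displacements at a point
# (z, y, x in 0-based voxel coordinates)
trilinear_field_oracle <- function(g, p) {
  nc <- g$node_counts
  h <- (g$volume_shape - 1) / (nc - 1)
  u <- p / h
  c0 <- pmin(pmax(floor(u), 0), nc - 2)
  t <- pmin(pmax(u - c0, 0), 1)
  out <- c(0, 0, 0)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a) t[1] else 1 - t[1]) * (if (b) t[2] else 1 - t[2]) *
      (if (cc) t[3] else 1 - t[3])
    out <- out + w * g$displacements[c0[1] + a + 1, c0[2] + b + 1,
                                     c0[3] + cc + 1, ]
  }
  out
}

# random small grid with random displacements
random_grid <- function(max_nodes = 5, vshape = NULL, scale = 1.5,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- sample(2:max_nodes, 3, replace = TRUE)
  if (is.null(vshape)) vshape <- sample(8:20, 3, replace = TRUE)
  g <- create_grid(vshape, nc)
  g$displacements <- array(rnorm(prod(nc) * 3, 0, scale), c(nc, 3))
  g
}
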