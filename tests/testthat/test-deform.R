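test_that("grid creation places nodes at corners with the documented spacing", {
  g <- create_grid(c(96, 96, 96), c(2, 2, 2))
  expect_equal(prod(g$node_counts), 8)
  expect_true(all(g$displacements == 0))
  expect_equal(prod(create_grid(c(64, 64, 64), c(9, 9, 5))$node_counts),
               405) # the ~400-node working grid
  g2 <- create_grid(c(20, 30, 40), c(5, 3, 2))
  expect_equal(brainwarp:::grid_spacing(g2), c(19 / 4, 29 / 2, 39 / 1))
  expect_error(create_grid(c(10, 10, 10), c(1, 2, 2)), "node_counts")
})

test_that("refinement preserves the field at old nodes and interpolates new ones", {
  g <- create_grid(c(9, 9, 9), c(2, 2, 2))
  expect_identical(refine_grid(g, c(2, 2, 2)), g)
  g$displacements[2, 1, 1, ] <- c(4, 0, 0) # one endpoint along z
  g3 <- refine_grid(g, c(3, 2, 2))
  expect_equal(g3$displacements[2, 1, 1, ], c(2, 0, 0)) # midpoint
  expect_equal(g3$displacements[1, 1, 1, ], c(0, 0, 0))
  expect_equal(g3$displacements[3, 1, 1, ], c(4, 0, 0))
  expect_error(refine_grid(g3, c(2, 2, 2)), "reduce")
  # the 4-stage coarse-to-fine sequence is nested and runs cleanly
  set.seed(4)
  gg <- create_grid(c(33, 33, 33), c(2, 2, 2))
  gg$displacements[] <- rnorm(length(gg$displacements))
  for (nc in list(c(2, 5, 3), c(3, 9, 5), c(5, 9, 9))) {
    old <- gg
    gg <- refine_grid(gg, nc)
    # old nodes are a subset of new nodes: field preserved exactly there
    f_old <- displacement_field(old)
    f_new <- displacement_field(gg)
    for (iz in seq_len(old$node_counts[1])) {
      z <- brainwarp:::node_positions(old, 1)[iz] + 1
      expect_equal(f_new[z, 1, 1, ], f_old[z, 1, 1, ], tolerance = 1e-12)
    }
  }
})

test_that("displacement field is exact at nodes and trilinear in between", {
  set.seed(5)
  g <- random_grid(4, vshape = c(15, 13, 17))
  f <- displacement_field(g)
  # constant field
  gc <- create_grid(c(10, 10, 10), c(3, 3, 3))
  gc$displacements[, , , 1] <- 2; gc$displacements[, , , 3] <- -1
  fc <- displacement_field(gc)
  expect_lt(max(abs(fc[, , , 1] - 2)), 1e-12)
  expect_true(all(fc[, , , 2] == 0))
  expect_lt(max(abs(fc[, , , 3] + 1)), 1e-12)
  # node exactness
  for (iz in 1:g$node_counts[1]) for (iy in 1:g$node_counts[2])
    for (ix in 1:g$node_counts[3]) {
      p <- c(brainwarp:::node_positions(g, 1)[iz],
             brainwarp:::node_positions(g, 2)[iy],
             brainwarp:::node_positions(g, 3)[ix])
      if (all(abs(p - round(p)) < 1e-9))
        expect_equal(f[p[1] + 1, p[2] + 1, p[3] + 1, ],
                     g$displacements[iz, iy, ix, ], tolerance = 1e-12)
    }
  # closed-form trilinear oracle at random interior points
  pts <- cbind(runif(200, 0, g$volume_shape[1] - 1),
               runif(200, 0, g$volume_shape[2] - 1),
               runif(200, 0, g$volume_shape[3] - 1))
  got <- brainwarp:::cpp_field_at_points(pts, g$volume_shape,
                                         g$displacements, g$node_counts)
  want <- t(apply(pts, 1, function(p) trilinear_field_oracle(g, p)))
  expect_lt(max(abs(got - want)), 1e-12)
  # edge midpoint between two nodes
  ge <- create_grid(c(11, 11, 11), c(2, 2, 2))
  ge$displacements[1, 1, 1, ] <- c(1, 0, 0)
  fe <- displacement_field(ge)
  expect_equal(fe[6, 1, 1, ], c(0.5, 0, 0))
})

test_that("warping matches an index-shift oracle and handles boundaries", {
  v <- ellipsoid_volume(d = c(20, 20, 20), semi = c(7, 8, 6))
  g <- create_grid(dim(v$data), c(2, 2, 2))
  expect_equal(warp_volume(v, g)$data, v$data)       # identity
  g$displacements[, , , 3] <- 2                      # read from x + 2
  w <- warp_volume(v, g)$data
  oracle <- array(0, dim(v$data))
  oracle[, , 1:18] <- v$data[, , 3:20]
  expect_equal(w, oracle)
  g$displacements[, , , 3] <- 100                    # fully outside
  expect_true(all(warp_volume(v, g)$data == 0))
})

test_that("inverse warp of a small smooth deformation restores the input", {
  v <- make_phantom(phantom_spec(noise_sd = 0), 2, seed = 1)$volume
  gt <- apply_ground_truth_deformation(v, 0.05, c(3, 4, 4), seed = 2)
  gneg <- gt$grid
  gneg$displacements <- -gneg$displacements
  back <- warp_volume(warp_volume(v, gt$grid), gneg)
  mask <- v$data > 0
  err <- mean(abs(back$data[mask] - v$data[mask])) / diff(range(v$data))
  expect_lt(err, 0.05)
})

test_that("deformation energy matches the brute-force tetra oracle", {
  g <- create_grid(c(11, 11, 11), c(2, 2, 2))
  expect_equal(deformation_energy(g), 0)
  g$displacements[, , , 2] <- 3.7                 # pure translation
  expect_equal(deformation_energy(g), 0, tolerance = 1e-12)
  gs <- create_grid(c(11, 11, 11), c(2, 2, 2))
  gs$displacements[, , 2, 3] <- 10                # double the x extent
  expect_equal(deformation_energy(gs), 1, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    g <- random_grid(5)
    expect_equal(deformation_energy(g), tetra_energy_oracle(g),
                 tolerance = 1e-9)
  }
})

test_that("tetra decomposition: rest volumes sum to the cell volume", {
  g <- create_grid(c(13, 9, 17), c(4, 3, 5))
  expect_equal(deformation_energy(g), 0)
  # doubling all displacements along z doubles every tetra volume: energy 1
  g$displacements[, , , 1] <- rep(brainwarp:::node_positions(g, 1),
                                  prod(g$node_counts[2:3]))
  expect_equal(deformation_energy(g), 1, tolerance = 1e-9)
})

test_that("pearson similarity follows the direct covariance formula", {
  a <- array(c(0, 1, 2, 0, 1, 2, 0, 1), c(2, 2, 2))
  b <- array(c(0, 2, 1, 0, 2, 1, 0, 2), c(2, 2, 2))
  expect_equal(pearson_similarity(a, b),
               cov(as.vector(a), as.vector(b)) / (sd(a) * sd(b)))
  expect_equal(pearson_similarity(array(c(0, 1, 2), c(3, 1, 1))[, , 1,
                                                                drop = FALSE],
               array(c(0, 2, 1), c(3, 1, 1))[, , 1, drop = FALSE]), 0.5)
  v <- ellipsoid_volume()
  expect_equal(pearson_similarity(v, v), 1)
  anti <- as_volume(max(v$data) - v$data, v)
  expect_equal(pearson_similarity(v, anti), -1)
  expect_error(pearson_similarity(v, as_volume(array(1, dim(v$data)), v)),
               "constant")
})

test_that("objective equals similarity minus lambda times energy", {
  v <- ellipsoid_volume()
  f <- preprocess_volume(v, equalize = FALSE)
  g <- random_grid(3, vshape = dim(v$data), scale = 0.5, seed = 7)
  g$volume_shape <- dim(v$data)
  expect_equal(registration_objective(f, f, g, lambda = 1 / 1000),
               pearson_similarity(warp_volume(f, g), f) -
                 deformation_energy(g) / 1000)
  gid <- create_grid(dim(v$data), c(2, 2, 2))
  expect_equal(registration_objective(f, f, gid, lambda = 0), 1)
})

test_that("grid JSON serialization round-trips bit-exactly", {
  g <- random_grid(4, seed = 8)
  g$spacing_um <- 96
  js <- grid_to_json(g)
  g2 <- grid_from_json(js)
  expect_identical(g2$displacements, g$displacements)
  expect_identical(g2$node_counts, g$node_counts)
  expect_identical(g2$volume_shape, g$volume_shape)
  path <- file.path(tempdir(), "grid.json")
  grid_to_json(g, path)
  expect_identical(grid_from_json(path)$displacements, g$displacements)
  unlink(path)
})
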