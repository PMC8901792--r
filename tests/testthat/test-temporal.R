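mini_sample <- function(id, side, age, seed = 1, spec = phantom_spec()) {
  f <- preprocess_volume(make_phantom(spec, age, seed = seed)$volume)
  f$sample_id <- id; f$side <- side; f$recorded_age_days <- age
  f
}

test_that("alignment plans chain references by age and cover every hemisphere", {
  spec <- phantom_spec(shape = c(16, 16, 16), semiaxes0 = c(4, 5, 5),
                       growth = c(0.2, 0.2, 0.2), shell_sites = 0L,
                       tube_sites = 0L, shell_center = c(0, -2, 0),
                       shell_radius0 = 2, tube_y = c(0, 2),
                       noise_sd = 0)
  s <- hemisphere_set(list(
    mini_sample("a", "right", 0, spec = spec),
    mini_sample("b", "right", 1, spec = spec),
    mini_sample("c", "right", 1, spec = spec)))
  plan <- build_alignment_plan(s, seed = 1)
  expect_identical(plan$root, "a_right")
  expect_equal(nrow(plan$edges), 2)  # (groups-1) + (rights - groups)
  chain <- plan$edges[plan$edges$type == "chain", ]
  expect_identical(chain$target, "a_right")
  ig <- plan$edges[plan$edges$type == "in_group", ]
  expect_identical(ig$target, chain$source) # non-reference -> reference
  expect_setequal(c("a_right", chain$source, ig$source), names(s))
  # single group: only in-group edges
  s1 <- hemisphere_set(list(mini_sample("a", "right", 2, spec = spec),
                            mini_sample("b", "right", 2, spec = spec)))
  p1 <- build_alignment_plan(s1, seed = 2)
  expect_true(all(p1$edges$type == "in_group"))
  # edge count formula on a larger set
  s2 <- hemisphere_set(lapply(1:6, function(i)
    mini_sample(paste0("s", i), "right", c(0, 0, 1, 1, 1, 2)[i],
                seed = i, spec = spec)))
  p2 <- build_alignment_plan(s2, seed = 3)
  expect_equal(nrow(p2$edges), (3 - 1) + (6 - 3))
  # determinism of the seeded reference draw
  expect_identical(build_alignment_plan(s2, seed = 3)$references,
                   p2$references)
  expect_error(build_alignment_plan(hemisphere_set(list(
    mini_sample("a", "left", 0, spec = spec))), 1), "right")
})

test_that("running a plan on identical phantoms aligns everything", {
  spec <- phantom_spec(noise_sd = 0, asymmetry_amp = 0)
  base <- make_phantom(spec, 2, seed = 1)$volume
  mk <- function(id, age) {
    f <- preprocess_volume(base)
    f$sample_id <- id; f$side <- "right"; f$recorded_age_days <- age
    f
  }
  s <- hemisphere_set(list(mk("a", 0), mk("b", 1), mk("c", 1)))
  plan <- build_alignment_plan(s, seed = 4)
  reg <- run_plan(s, plan, schedule = tiny_schedule(c(200, 200)), seed = 5)
  expect_length(attr(reg, "failures"), 0)
  D <- pairwise_distances(reg)
  expect_true(all(D[upper.tri(D)] <= 0.01))
})

test_that("left hemispheres inherit their brain's grid bit-identically", {
  spec <- phantom_spec(noise_sd = 0.01)
  r1 <- mini_sample("b1", "right", 0, seed = 1, spec = spec)
  l1 <- mini_sample("b1", "left", 0, seed = 1, spec = spec)
  r2 <- mini_sample("b2", "right", 1, seed = 2, spec = spec)
  l2 <- mini_sample("b2", "left", 1, seed = 2, spec = spec)
  s <- hemisphere_set(list(r1, l1, r2, l2))
  plan <- build_alignment_plan(s, seed = 6)
  reg <- run_plan(s, plan, schedule = tiny_schedule(c(150, 150)), seed = 7)
  expect_identical(reg$b2_left$grid$displacements,
                   reg$b2_right$grid$displacements)
})

test_that("distance matrices follow the 1 - Pearson definition", {
  spec <- phantom_spec()
  s <- hemisphere_set(list(mini_sample("a", "right", 0, 1, spec),
                           mini_sample("b", "right", 1, 2, spec),
                           mini_sample("c", "right", 2, 3, spec)))
  D <- pairwise_distances(s, 96)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 2))
  f <- function(i) resample_volume(s[[i]]$filtered, 96)
  expect_equal(D[1, 2], 1 - pearson_similarity(f(1), f(2)),
               tolerance = 1e-12)
  expect_equal(D[2, 3], 1 - pearson_similarity(f(2), f(3)),
               tolerance = 1e-12)
  # identical and anti-correlated images
  a <- s[["a_right"]]$filtered
  ss <- hemisphere_set(list(a, local({
    b <- as_volume(max(a$data) - a$data, a); b$sample_id <- "anti"; b
  })))
  D2 <- pairwise_distances(ss, 96)
  expect_equal(D2[1, 2], 2, tolerance = 1e-12)
})

test_that("classical MDS recovers exact and synthetic geometries", {
  # collinear 3-point configuration
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  e <- suppressWarnings(cmds_embed(d, k = 2)) # k exceeds the embeddable rank
  expect_equal(abs(e$points[, 1]), c(1, 0, 1), tolerance = 1e-12)
  expect_equal(e$points[1, 1], -e$points[3, 1], tolerance = 1e-12)
  expect_equal(e$variance_explained[1], 1, tolerance = 1e-12)
  # all-zero distances
  z <- suppressWarnings(cmds_embed(matrix(0, 4, 4), k = 2))
  expect_true(all(abs(z$points) < 1e-12))
  # Gram reconstruction of a random 3-D point cloud
  set.seed(13)
  X <- matrix(rnorm(30), ncol = 3)
  DX <- as.matrix(dist(X))
  eX <- cmds_embed(DX, k = 3)
  expect_equal(as.matrix(dist(eX$points)), DX, tolerance = 1e-8,
               ignore_attr = TRUE)
  # agreement with the standard cmdscale implementation
  ref <- cmdscale(DX, k = 3)
  for (j in 1:3)
    expect_equal(abs(eX$points[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  # noiseless 1-D growth line
  pos <- seq(0, 5, length.out = 12)
  DL <- abs(outer(pos, pos, "-"))
  eL <- suppressWarnings(cmds_embed(DL, k = 2, ages = pos))
  expect_gte(abs(cor(eL$points[, 1], pos)), 0.99)
  expect_gte(cor(eL$points[, 1], pos), 0) # sign convention
})

test_that("age adjustment matches closed-form OLS and its invariances", {
  # exact hand-computed case
  ages <- c(0, 0, 1, 1)
  cmds1 <- c(0, 0.2, 0.8, 1.0)
  at <- adjust_ages(cmds1, ages)
  expect_equal(at$slope, 0.8 / 0.68, tolerance = 1e-12)
  expect_equal(at$table$adjusted_age_days,
               c(-0.088, 0.147, 0.853, 1.088), tolerance = 1e-2)
  # perfect affine relation reproduces the recorded ages
  cm <- (ages - 3) / 2
  expect_equal(adjust_ages(cm, ages)$table$adjusted_age_days, ages,
               tolerance = 1e-12)
  # invariance to the global sign of cmds1
  expect_equal(adjust_ages(-cmds1, ages)$table$adjusted_age_days,
               at$table$adjusted_age_days, tolerance = 1e-12)
  # hemisphere synchrony bookkeeping
  at2 <- adjust_ages(c(0.1, 0.12, 0.9, 0.95), c(0, 0, 1, 1),
                     sample_ids = c("b1", "b1", "b2", "b2"),
                     sides = c("left", "right", "left", "right"))
  expect_equal(at2$table$synchrony_days[1], at2$table$synchrony_days[2])
  expect_true(all(is.finite(at2$table$synchrony_days)))
  expect_error(adjust_ages(rep(1, 4), c(0, 0, 1, 1)), "degenerate")
  expect_error(adjust_ages(c(1, 2), c(0, 1)), "3 samples")
})

test_that("hemisphere pairs of symmetric brains stay synchronous", {
  spec <- phantom_spec(asymmetry_amp = 0, noise_sd = 0.01)
  mk2 <- function(id, age, seed) {
    r <- mini_sample(id, "right", age, seed, spec)
    l <- r; l$side <- "left"
    list(r, l)
  }
  s <- hemisphere_set(c(mk2("b1", 0, 1), mk2("b2", 1, 2), mk2("b3", 2, 3)))
  D <- pairwise_distances(s, 96)
  tab <- brainwarp:::sample_table(s)
  emb <- suppressWarnings(cmds_embed(D, k = 2,
                                     ages = tab$recorded_age_days))
  at <- adjust_ages(emb, tab$recorded_age_days, tab$sample_id, tab$side)
  expect_lt(max(at$table$synchrony_days, na.rm = TRUE), 0.1)
})
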