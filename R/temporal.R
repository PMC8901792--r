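#' Assemble a hemisphere sample set
#'
#' A sample set is a list of hemisphere records, each holding the sample id,
#' side, recorded postnatal age and the filtered feature volume. Hemisphere
#' pairs from [symmetrize_and_split()] contribute one right and one
#' left-mirrored record per brain.
#'
#' @param ... `bw_hemipair` objects and/or filtered `bw_volume`s (whose
#'   metadata supply id, side and age; volumes are treated as
#'   right-hemisphere frames).
#' @return list of class `bw_samples`.
#' @export
hemisphere_set <- function(...) {
  items <- list(...)
  if (length(items) == 1 && is.list(items[[1]]) &&
      !inherits(items[[1]], c("bw_hemipair", "bw_volume")))
    items <- items[[1]]
  recs <- list()
  for (it in items) {
    if (inherits(it, "bw_hemipair")) {
      recs[[length(recs) + 1]] <- list(
        sample_id = it$sample_id, side = "right",
        recorded_age_days = it$right$recorded_age_days,
        filtered = it$right_filtered)
      recs[[length(recs) + 1]] <- list(
        sample_id = it$sample_id, side = "left",
        recorded_age_days = it$left_mirrored$recorded_age_days,
        filtered = it$left_mirrored_filtered)
    } else if (inherits(it, "bw_volume")) {
      recs[[length(recs) + 1]] <- list(
        sample_id = it$sample_id, side = it$side,
        recorded_age_days = it$recorded_age_days, filtered = it)
    } else stop("unsupported sample type")
  }
  ids <- vapply(recs, function(r) paste(r$sample_id, r$side, sep = "_"),
                character(1))
  if (anyDuplicated(ids))
    stop("each brain may contribute at most one left and one right ",
         "hemisphere")
  names(recs) <- ids
  structure(recs, class = "bw_samples")
}

sample_table <- function(s) {
  data.frame(
    key = names(s),
    sample_id = vapply(s, function(r) r$sample_id, character(1)),
    side = vapply(s, function(r) r$side, character(1)),
    recorded_age_days = vapply(s, function(r) r$recorded_age_days,
                               numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the order-aware alignment plan
#'
#' Groups right hemispheres by recorded age, randomly selects one reference
#' per group (seeded; ties in the chain order are broken lexicographically
#' by sample id), chains the references in ascending age (each reference
#' registers to the previous, already-transformed reference), and registers
#' every non-reference right hemisphere to the transformed reference of its
#' own age group. The plan is a forest reaching every right hemisphere.
#'
#' @param s a `bw_samples` set (>= 1 right hemisphere per age group).
#' @param seed RNG seed for the reference draws.
#' @return list of class `bw_plan`: `references` (key per age group, in
#'   ascending age), `edges` (data.frame: source key, target key, type
#'   "chain"/"in_group"), `root`, `seed`.
#' @export
build_alignment_plan <- function(s, seed = 1L) {
  tab <- sample_table(s)
  rights <- tab[tab$side == "right", ]
  if (nrow(rights) == 0) stop("plan error: no right hemispheres")
  ages <- sort(unique(rights$recorded_age_days))
  refs <- character(length(ages))
  with_seed(seed, {
    for (i in seq_along(ages)) {
      grp <- rights$key[rights$recorded_age_days == ages[i]]
      grp <- sort(grp) # deterministic order before the seeded draw
      refs[i] <- grp[[sample.int(length(grp), 1)]]
    }
  })
  edges <- data.frame(source = character(0), target = character(0),
                      type = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(ages)) {
    if (i > 1)
      edges <- rbind(edges, data.frame(source = refs[i],
                                       target = refs[i - 1],
                                       type = "chain"))
    grp <- sort(rights$key[rights$recorded_age_days == ages[i]])
    for (k in setdiff(grp, refs[i]))
      edges <- rbind(edges, data.frame(source = k, target = refs[i],
                                       type = "in_group"))
  }
  structure(list(references = refs, ages = ages, edges = edges,
                 root = refs[1], seed = seed),
            class = "bw_plan")
}

#' Execute an alignment plan
#'
#' Registers right hemispheres along the plan edges. Because every target is
#' already in the common (root-reference) frame when its edge runs, each
#' hemisphere ends up with a single deformation grid mapping it from its
#' own frame into the common frame. Left(-mirrored) hemispheres receive
#' their brain's right-hemisphere grid unchanged (copy semantics in the
#' shared right-hemisphere coordinate frame). A failed edge is recorded and
#' the plan continues on other branches.
#'
#' @param s a `bw_samples` set.
#' @param plan a `bw_plan` from [build_alignment_plan()].
#' @param schedule annealing schedule (default [reduced_schedule()], sized
#'   for phantom series; use [default_schedule()] for full-scale data).
#' @param lambda deformation-energy weight.
#' @param seed RNG seed; edge k runs with seed + k.
#' @return a `bw_samples` set where each record gains `registered` (warped
#'   filtered volume in the common frame), `grid`, and `edge_similarity`;
#'   attribute "failures" lists failed edges.
#' @export
run_plan <- function(s, plan, schedule = reduced_schedule(),
                     lambda = 1 / 1000, seed = 1L) {
  grids <- list()
  registered <- list()
  failures <- character(0)
  root <- plan$root
  registered[[root]] <- s[[root]]$filtered
  grids[[root]] <- create_grid(dim(s[[root]]$filtered$data),
                               c(2, 2, 2),
                               s[[root]]$filtered$spacing_um)
  edges <- plan$edges
  for (k in seq_len(nrow(edges))) {
    src <- edges$source[k]
    tgt <- edges$target[k]
    res <- tryCatch({
      if (is.null(registered[[tgt]]))
        stop("target not yet registered")
      register_pair(s[[src]]$filtered, registered[[tgt]],
                    schedule = schedule, lambda = lambda,
                    seed = seed + k)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s -> %s: %s", src, tgt,
                                      conditionMessage(res)))
      next
    }
    grids[[src]] <- res$grid
    registered[[src]] <- warp_volume(s[[src]]$filtered, res$grid)
    attr(registered[[src]], "edge_similarity") <- res$similarity
  }
  # copy each brain's right-hemisphere transformation to its mirrored left
  tab <- sample_table(s)
  for (i in seq_len(nrow(tab))) {
    key <- tab$key[i]
    if (tab$side[i] != "left") next
    rkey <- paste(tab$sample_id[i], "right", sep = "_")
    if (is.null(grids[[rkey]])) next
    grids[[key]] <- grids[[rkey]]
    registered[[key]] <- warp_volume(s[[key]]$filtered, grids[[rkey]])
  }
  out <- s
  for (key in names(out)) {
    out[[key]]$registered <- registered[[key]]
    out[[key]]$grid <- grids[[key]]
  }
  attr(out, "failures") <- failures
  class(out) <- "bw_samples"
  out
}

#' Pairwise correlation-distance matrix
#'
#' d(i, j) = 1 - Pearson(filtered_i, filtered_j) over all hemispheres in the
#' common frame, computed at a common working resolution (default 96 um).
#' Symmetric with zero diagonal; entries in [0, 2].
#'
#' @param s a registered `bw_samples` set (from [run_plan()]).
#' @param resolution_um working resolution for the comparison.
#' @return symmetric distance matrix with hemisphere keys as dimnames.
#' @export
pairwise_distances <- function(s, resolution_um = 96) {
  keys <- names(s)
  vols <- lapply(s, function(r) {
    v <- r$registered %||% r$filtered
    resample_volume(v, max(resolution_um, rep(v$spacing_um, 3)[1]))
  })
  n <- length(vols)
  D <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- 1 - pearson_similarity(vols[[i]], vols[[j]])
    D[i, j] <- d
    D[j, i] <- d
  }
  D
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances, eigendecomposes, and returns
#' coordinates scaled by the square roots of the positive eigenvalues in
#' descending order. Variance explained is computed over positive
#' eigenvalues only (negative eigenvalues flag non-Euclidean distances and
#' are dropped with a warning). The sign of dimension 1 is chosen so its
#' correlation with `ages` (if supplied) is nonnegative.
#'
#' @param d symmetric distance matrix, zero diagonal.
#' @param k number of dimensions to retain (truncated, with a warning, to
#'   the number of positive eigenvalues).
#' @param ages optional recorded ages fixing the sign of dimension 1.
#' @return list of class `bw_embedding`: `points` (n x k), `eigenvalues`,
#'   `variance_explained`.
#' @export
cmds_embed <- function(d, k = 3L, ages = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (d * d) %*% J
  B <- (B + t(B)) / 2
  ee <- eigen(B, symmetric = TRUE)
  pos <- ee$values > max(ee$values, 0) * 1e-12
  npos <- sum(pos)
  if (any(ee$values < -max(abs(ee$values)) * 1e-8))
    warning("distance matrix is non-Euclidean; negative eigenvalues dropped")
  if (k > npos) {
    if (npos < n - 1) # silent when k simply exceeds the embeddable rank
      warning(sprintf("only %d positive eigenvalues; k truncated", npos))
    k <- max(npos, 0L)
  }
  lam <- ee$values[seq_len(k)]
  pts <- if (k > 0) {
    ee$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(lam), nrow = k)
  } else matrix(0, n, 0)
  if (k > 0 && !is.null(ages) && sd(pts[, 1]) > 0 && sd(ages) > 0 &&
      cor(pts[, 1], ages) < 0)
    pts[, 1] <- -pts[, 1]
  rownames(pts) <- rownames(d)
  ve <- if (npos > 0) pmax(ee$values, 0) / sum(pmax(ee$values, 0)) else
    rep(0, n)
  structure(list(points = pts, eigenvalues = ee$values,
                 variance_explained = ve[seq_len(max(k, 1))]),
            class = "bw_embedding")
}

#' Adjusted developmental ages from the first CMDS coordinate
#'
#' Ordinary least squares of recorded age on the first CMDS coordinate; the
#' fitted values are the adjusted ages. Reports the per-sample adjustment
#' (adjusted minus recorded) and, when both hemispheres of a brain are
#' present, the hemisphere synchrony |adjusted_L - adjusted_R|. The
#' alternative regression direction (cmds1 on age, then inverted) is
#' available for sensitivity checks.
#'
#' @param e a `bw_embedding` (or numeric cmds1 vector).
#' @param recorded_ages numeric recorded ages, one per sample.
#' @param sample_ids,sides optional identifiers enabling the synchrony
#'   report.
#' @param direction "age_on_cmds1" (default) or "cmds1_on_age".
#' @return list of class `bw_ages`: `table` (data.frame with cmds1,
#'   adjusted_age_days, adjustment_days, synchrony_days), `intercept`,
#'   `slope`, `confint` (95% band for the coefficients).
#' @export
adjust_ages <- function(e, recorded_ages, sample_ids = NULL, sides = NULL,
                        direction = c("age_on_cmds1", "cmds1_on_age")) {
  direction <- match.arg(direction)
  cmds1 <- if (inherits(e, "bw_embedding")) e$points[, 1] else as.numeric(e)
  if (length(cmds1) < 3) stop("need at least 3 samples")
  if (sd(cmds1) == 0) stop("degenerate regression: constant cmds1")
  if (direction == "age_on_cmds1") {
    fit <- lm(recorded_ages ~ cmds1)
    adjusted <- as.numeric(fitted(fit))
    a <- coef(fit)[2]
    b <- coef(fit)[1]
  } else {
    fit <- lm(cmds1 ~ recorded_ages)
    a <- 1 / coef(fit)[2]
    b <- -coef(fit)[1] / coef(fit)[2]
    adjusted <- a * cmds1 + b
  }
  n <- length(cmds1)
  ids <- sample_ids %||% names(cmds1) %||% sprintf("s%02d", seq_len(n))
  sds <- sides %||% rep(NA_character_, n)
  tab <- data.frame(sample_id = ids, side = sds,
                    recorded_age_days = recorded_ages, cmds1 = cmds1,
                    adjusted_age_days = adjusted,
                    adjustment_days = adjusted - recorded_ages,
                    synchrony_days = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!all(is.na(sds))) {
    for (id in unique(ids)) {
      sel <- tab$sample_id == id
      if (sum(sel) == 2) {
        sync <- abs(diff(tab$adjusted_age_days[sel]))
        tab$synchrony_days[sel] <- sync
      }
    }
  }
  structure(list(table = tab, slope = unname(a), intercept = unname(b),
                 confint = tryCatch(suppressWarnings(confint(fit)),
                                    error = function(e) NULL)),
            class = "bw_ages")
}

#' Write an age table to CSV
#'
#' Columns: sample_id, side, recorded_age_days, cmds1, adjusted_age_days,
#' adjustment_days, synchrony_days. Numbers are written with full precision
#' so identical runs produce byte-identical files.
#'
#' @param ages a `bw_ages` object.
#' @param path output CSV path.
#' @export
write_age_table <- function(ages, path) {
  tab <- ages$table
  num <- vapply(tab, is.numeric, logical(1))
  for (j in which(num)) tab[[j]] <- sprintf("%.12g", tab[[j]])
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
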