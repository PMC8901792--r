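#' Gaussian blending weights over the developmental timeline
#'
#' Each sample contributes to a time point with an unnormalized Gaussian
#' weight peaking at its adjusted age, standard deviation `sigma_days`
#' (default half a day, half the daily sampling interval); at every time
#' point the weights over samples are normalized to sum to one.
#'
#' @param ages adjusted ages (days), one per sample.
#' @param timeline time points (days); default `seq(min(ages), max(ages),
#'   by = dt)`.
#' @param sigma_days Gaussian standard deviation (default 0.5).
#' @param dt timeline step when `timeline` is NULL (default 0.1).
#' @return list of class `bw_weights`: `timeline`, `weights` (samples x
#'   time points, columns summing to 1), `sigma_days`.
#' @export
blend_weights <- function(ages, timeline = NULL, sigma_days = 0.5,
                          dt = 0.1) {
  stopifnot(length(ages) >= 1, sigma_days > 0)
  if (is.null(timeline)) {
    timeline <- if (max(ages) > min(ages))
      seq(min(ages), max(ages), by = dt) else min(ages)
  }
  w <- outer(ages, timeline,
             function(a, t) exp(-(t - a)^2 / (2 * sigma_days^2)))
  w <- sweep(w, 2, colSums(w), "/")
  rownames(w) <- names(ages)
  structure(list(timeline = timeline, weights = w, sigma_days = sigma_days),
            class = "bw_weights")
}

weights_at <- function(wc, t) {
  i <- which.min(abs(wc$timeline - t))
  wc$weights[, i]
}

#' Weighted-average volume at a time point
#'
#' Voxelwise convex combination of registered volumes with the blending
#' weights at time `t` (or an explicit weight vector).
#'
#' @param volumes list of volumes in the common frame, equal shapes.
#' @param w a `bw_weights` object or a numeric weight vector.
#' @param t time point (days), used when `w` is a `bw_weights`.
#' @return a `bw_volume`.
#' @export
average_volume <- function(volumes, w, t = NULL) {
  wv <- if (inherits(w, "bw_weights")) weights_at(w, t) else as.numeric(w)
  if (length(wv) != length(volumes))
    stop("one weight per volume required")
  d <- dim(volumes[[1]]$data)
  for (v in volumes) if (!identical(dim(v$data), d))
    stop("volumes differ in shape")
  acc <- array(0, d)
  for (i in seq_along(volumes)) acc <- acc + wv[i] * volumes[[i]]$data
  as_volume(acc, volumes[[1]], sample_id = "average", side = "right")
}

#' Differential volume between consecutive average images
#'
#' diff = current minus previous; increases render red, decreases blue, both
#' scaled by the 99th percentile of |diff| (clipped to [0, 255]).
#'
#' @param avg_t,avg_prev average volumes of identical shape.
#' @param pct percentile of |diff| used for contrast scaling (default 99).
#' @return list of class `bw_signed`: `signed` (the difference volume),
#'   `rgb` (integer array dim c(dim, 3), 0..255), `scale`.
#' @export
differential_volume <- function(avg_t, avg_prev, pct = 99) {
  if (!identical(dim(avg_t$data), dim(avg_prev$data)))
    stop("shape mismatch")
  dd <- avg_t$data - avg_prev$data
  sc <- quantile(abs(dd), pct / 100, names = FALSE)
  scale_chan <- function(x) {
    if (sc > 0) pmin(pmax(round(255 * x / sc), 0), 255) else x * 0L
  }
  rgb <- array(0L, c(dim(dd), 3))
  rgb[, , , 1] <- scale_chan(pmax(dd, 0))
  rgb[, , , 3] <- scale_chan(pmax(-dd, 0))
  structure(list(signed = as_volume(dd, avg_t, sample_id = "differential"),
                 rgb = rgb, scale = sc),
            class = "bw_signed")
}

#' Linear growth fit of sample sizes
#'
#' Fits foreground bounding-box extents per axis (dorsoventral = Z,
#' rostrocaudal = Y, mediolateral = X) against age by OLS, normalizes to
#' the fitted size at age 0 (birth), and returns per-age scale factors for
#' rendering.
#'
#' @param ages recorded or adjusted ages, >= 2 distinct values.
#' @param masks list of binary mask volumes, one per age entry.
#' @return list of class `bw_sizes`: `fits` (per-axis lm), `table`
#'   (age, per-axis extents and normalized extents), `scale_at` (function
#'   of age returning per-axis scale factors relative to birth), `confint`.
#' @export
size_scaling <- function(ages, masks) {
  if (length(unique(ages)) < 2)
    stop("size fit needs at least 2 distinct ages")
  ext <- t(vapply(masks, function(m) {
    idx <- which(m$data > 0, arr.ind = TRUE)
    apply(idx, 2, function(u) diff(range(u)) + 1)
  }, numeric(3)))
  colnames(ext) <- c("z", "y", "x")
  fits <- lapply(1:3, function(j) lm(ext[, j] ~ ages))
  names(fits) <- colnames(ext)
  at0 <- vapply(fits, function(f) unname(predict(f, list(ages = 0))),
                numeric(1))
  tab <- data.frame(age_days = ages, ext,
                    sweep(ext, 2, at0, "/"))
  names(tab)[5:7] <- paste0("norm_", colnames(ext))
  scale_at <- function(a) {
    vapply(seq_along(fits), function(j)
      unname(predict(fits[[j]], list(ages = a))) / at0[j], numeric(1))
  }
  structure(list(fits = fits, table = tab, scale_at = scale_at,
                 size_at_birth = at0,
                 confint = suppressWarnings(lapply(fits, confint))),
            class = "bw_sizes")
}

#' Red/green overlay of a registered pair
#'
#' Red = contrast-stretched fixed image, green = contrast-stretched moving
#' image; overlap renders yellow.
#'
#' @param fixed,moving volumes of identical shape.
#' @return integer RGB array, dim c(dim, 3), values 0..255.
#' @export
overlay_rgb <- function(fixed, moving) {
  if (!identical(dim(fixed$data), dim(moving$data)))
    stop("shape mismatch")
  stretch <- function(x) {
    r <- range(x)
    if (r[2] > r[1]) as.integer(round(255 * (x - r[1]) / (r[2] - r[1])))
    else array(0L, dim(x))
  }
  rgb <- array(0L, c(dim(fixed$data), 3))
  rgb[, , , 1] <- stretch(fixed$data)
  rgb[, , , 2] <- stretch(moving$data)
  rgb
}

#' Mirror-append a hemisphere into a whole-brain rendering
#'
#' Concatenates the mirrored hemisphere and the hemisphere along X so the
#' result is exactly mid-plane symmetric (the display convention for data
#' registered in a single-hemisphere frame).
#'
#' @param hemi a hemisphere volume with the midline at x = 1.
#' @return a `bw_volume` with even X extent, side "whole".
#' @export
mirror_append <- function(hemi) {
  nx <- dim(hemi$data)[3]
  out <- array(0, dim(hemi$data) + c(0, 0, nx))
  out[, , seq_len(nx)] <- hemi$data[, , nx:1]
  out[, , nx + seq_len(nx)] <- hemi$data
  as_volume(out, hemi, side = "whole")
}

#' Day-to-day variability of an average-image series
#'
#' Mean over consecutive pairs of the chosen norm of voxelwise differences,
#' optionally on volumes downsampled by an integer factor per axis
#' (`downsample = 2` halves each axis, i.e. 1/8 of the voxels).
#'
#' @param series list of average volumes at consecutive days, equal shapes.
#' @param norm "l2" (default) or "l1".
#' @param downsample integer block-averaging factor per axis (default 1).
#' @return nonnegative scalar.
#' @export
day_to_day_variability <- function(series, norm = c("l2", "l1"),
                                   downsample = 1L) {
  norm <- match.arg(norm)
  if (length(series) < 2) stop("need at least 2 consecutive time points")
  arrs <- lapply(series, function(v) {
    a <- if (is.list(v)) v$data else v
    if (downsample > 1) block_mean(a, rep(as.integer(downsample), 3)) else a
  })
  vals <- vapply(seq_len(length(arrs) - 1), function(i) {
    d <- arrs[[i + 1]] - arrs[[i]]
    if (norm == "l2") sqrt(sum(d^2)) else sum(abs(d))
  }, numeric(1))
  mean(vals)
}
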