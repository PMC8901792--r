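#' Per-slice histogram equalization
#'
#' Equalizes each XY-slice independently to compensate for signal attenuation
#' along Z in light-sheet stacks. The mapping is the empirical CDF of the
#' slice's nonzero voxels (exact histogram equalization): each value maps to
#' the fraction of nonzero voxels at or below it, so background stays exactly
#' zero, tied values keep their full cumulative mass, within-slice intensity
#' ranks are preserved exactly, and the output lies in (0, 1]. Run after
#' [suppress_background()] so rank-based equalization cannot amplify faint
#' background noise in slices that contain no sample.
#'
#' @param v a `bw_volume`.
#' @return a `bw_volume` with equalized slices.
#' @export
equalize_slices <- function(v) {
  d <- v$data
  nz <- dim(d)[1]
  for (z in seq_len(nz)) {
    sl <- d[z, , ]
    pos <- sl > 0
    nzv <- sl[pos]
    if (!length(nzv)) next
    sl[pos] <- ecdf(nzv)(nzv)
    d[z, , ] <- sl
  }
  as_volume(d, v)
}

#' Suppress background signal
#'
#' Sets voxels below `frac` of the volume maximum to zero; all other voxels
#' are unchanged. Idempotent.
#'
#' @param v a `bw_volume`.
#' @param frac threshold as a fraction of the maximum intensity (default
#'   0.01).
#' @return a `bw_volume`.
#' @export
suppress_background <- function(v, frac = 0.01) {
  stopifnot(frac >= 0, frac < 1)
  mx <- max(v$data)
  if (mx <= 0) stop("empty sample: volume has no positive signal")
  d <- v$data
  d[d < frac * mx] <- 0
  as_volume(d, v)
}

otsu_threshold <- function(x, bins = 256L) {
  br <- seq(min(x), max(x), length.out = bins + 1L)
  idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, nbins = bins)
  p <- cnt / sum(cnt)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Binarize a volume into a foreground mask
#'
#' Mask is 1 where intensity exceeds `frac` of the maximum (the threshold
#' that separates sample from background in background-suppressed stacks).
#' An Otsu mode selects the threshold from the intensity histogram instead.
#'
#' @param v a `bw_volume` with a positive maximum.
#' @param frac threshold fraction of the maximum (default 0.01).
#' @param method "frac" (default) or "otsu".
#' @return a `bw_volume` of class `bw_volume`/`bw_mask` with values in {0, 1}.
#' @export
binarize <- function(v, frac = 0.01, method = c("frac", "otsu")) {
  method <- match.arg(method)
  mx <- max(v$data)
  if (mx <= 0) stop("empty sample: volume has no positive signal")
  thr <- if (method == "frac") frac * mx else otsu_threshold(as.vector(v$data))
  m <- as_volume(array(as.double(v$data > thr), dim(v$data)), v)
  class(m) <- c("bw_mask", class(m))
  m
}

#' PCA pre-alignment of a binary mask
#'
#' Rotates the foreground voxel cloud so its principal axes map onto the
#' (Z, Y, X) array axes in order of descending eigenvalue. Among the four
#' proper-rotation sign choices, the one maximizing binary overlap
#' correlation with `reference` is chosen; without a reference, signs are
#' chosen so the centroid-to-farthest-point vector points into the positive
#' octant as far as a proper rotation allows. Optionally rescales each axis
#' to the reference's foreground extents.
#'
#' @param m a binary mask volume.
#' @param reference optional binary mask in the target orientation.
#' @param scale_to_reference rescale per-axis foreground extents to the
#'   reference's (default FALSE).
#' @param eig_tol relative eigenvalue-gap tolerance below which the mask is
#'   considered degenerate (default 1e-6).
#' @param allow_degenerate if TRUE, degenerate (near-spherical) masks use the
#'   arbitrary eigenvector basis instead of raising an error.
#' @return list with `transform` (rotation, scale, translation) and
#'   `resampled` (the mask resampled into the aligned frame).
#' @export
pca_prealign <- function(m, reference = NULL, scale_to_reference = FALSE,
                         eig_tol = 1e-6, allow_degenerate = FALSE) {
  coords <- which(m$data > 0, arr.ind = TRUE) # (z, y, x), 1-based
  if (nrow(coords) < 4) stop("mask needs at least 4 foreground voxels")
  coords <- coords - 1
  ctr <- colMeans(coords)
  C <- cov(coords)
  ee <- eigen(C, symmetric = TRUE)
  lam <- ee$values
  if (any(diff(lam) == 0) ||
      min(abs(diff(lam))) / max(lam) < eig_tol) {
    if (!allow_degenerate)
      stop("degenerate principal axes (near-equal eigenvalues); ",
           "no unique orientation")
  }
  V <- ee$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  R0 <- t(V) # rows = principal axes, descending eigenvalue -> (Z, Y, X)

  signs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cand <- lapply(seq_len(4), function(i) diag(signs[i, ]) %*% R0)

  d_out <- if (!is.null(reference)) dim(reference$data) else dim(m$data)
  c_out <- (d_out - 1) / 2

  scl <- c(1, 1, 1)
  if (scale_to_reference) {
    if (is.null(reference)) stop("scale_to_reference needs a reference")
    ext_ref <- apply(which(reference$data > 0, arr.ind = TRUE), 2,
                     function(u) diff(range(u)))
    ext_own <- sqrt(lam) # axis spreads in the principal frame
    ext_own_ref <- sqrt(eigen(cov(which(reference$data > 0,
                                        arr.ind = TRUE)),
                              symmetric = TRUE)$values)
    scl <- ext_own_ref / ext_own
  }

  resample_with <- function(Rc) {
    A <- t(Rc) %*% diag(1 / scl)
    b <- ctr - A %*% c_out
    out <- cpp_affine_sample(m$data, as.integer(dim(m$data)),
                             as.integer(d_out), A, as.numeric(b),
                             nearest = TRUE)
    out
  }

  if (!is.null(reference)) {
    scores <- vapply(cand, function(Rc) {
      out <- resample_with(Rc)
      if (sd(out) == 0 || sd(reference$data) == 0) return(-2)
      cor(as.vector(out), as.vector(reference$data))
    }, numeric(1))
    pick <- which.max(scores) # ties resolve to the earliest (identity-like)
  } else {
    far <- coords[which.max(rowSums(sweep(coords, 2, ctr)^2)), ] - ctr
    sc1 <- vapply(cand, function(Rc) sum(Rc %*% far > 0), numeric(1))
    sc2 <- vapply(cand, function(Rc) sum(Rc %*% far), numeric(1))
    pick <- order(-sc1, -sc2)[1]
  }
  Rc <- cand[[pick]]
  out <- resample_with(Rc)

  res <- as_volume(array(out, d_out), m)
  list(
    transform = list(rotation = Rc, scale = scl,
                     translation = as.numeric(ctr - t(Rc) %*% c_out)),
    resampled = res)
}

#' Laplacian-of-Gaussian contour image
#'
#' Band-pass filters the volume with a Laplacian of Gaussian (sigma =
#' `radius_vox` voxels), computed in the frequency domain with zero padding,
#' and returns the response magnitude rescaled so its mean over nonzero
#' voxels equals 1. The kernel is DC-corrected so constant regions map to
#' exactly zero. The blur radius is chosen large enough to average out
#' individual labelled cells but small enough to preserve region shapes; 5
#' voxels is the working default.
#'
#' @param v a `bw_volume`.
#' @param radius_vox Gaussian sigma in voxels (default 5).
#' @return a `bw_volume` holding the normalized contour image.
#' @export
log_contours <- function(v, radius_vox = 5) {
  stopifnot(radius_vox > 0)
  d <- dim(v$data)
  if (radius_vox > min(d) / 2)
    stop("LoG radius exceeds half the smallest volume dimension")
  if (max(v$data) == min(v$data)) # constant input: Laplacian is zero
    return(as_volume(array(0, dim(v$data)), v))
  K <- log_kernel(radius_vox)
  res <- fft_convolve_same(v$data, K)
  contour <- abs(res)
  mx <- max(contour)
  # constant (or numerically constant) input: the response is round-off only
  if (mx <= 1e-10 * max(abs(v$data), 1))
    return(as_volume(array(0, dim(v$data)), v))
  # clear the FFT round-off floor so "nonzero voxels" means the contour band
  contour[contour < 1e-6 * mx] <- 0
  nzm <- mean(contour[contour > 0])
  if (is.finite(nzm) && nzm > 0) contour <- contour / nzm
  as_volume(contour, v)
}

# sampled 3D LoG kernel, DC-corrected with a Gaussian-weighted term so the
# response to a constant input is exactly zero
log_kernel <- function(sigma) {
  R <- ceiling(4 * sigma)
  g <- seq(-R, R)
  r2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
  G <- exp(-r2 / (2 * sigma^2))
  K <- (r2 / sigma^2 - 3) / sigma^2 * G
  K - sum(K) * G / sum(G)
}

# linear 'same' convolution of a 3D array with a centered odd-sized kernel,
# via zero-padded FFTs
fft_convolve_same <- function(a, K) {
  d <- dim(a)
  R <- (dim(K)[1] - 1) / 2
  P <- d + 2 * R
  A <- array(0, P)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  B <- array(0, P)
  iz <- ((-R:R) %% P[1]) + 1
  iy <- ((-R:R) %% P[2]) + 1
  ix <- ((-R:R) %% P[3]) + 1
  B[iz, iy, ix] <- K
  res <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / prod(P)
  res[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

#' Compose the filtered feature image
#'
#' The feature space for registration: the binary mask plus the normalized
#' contour image (weight 1:1 by default). The mask term carries the overall
#' sample shape for coarse alignment; the contour term sharpens the
#' similarity peak for fine alignment.
#'
#' @param m binary mask volume.
#' @param contours normalized contour volume.
#' @param weight multiplier applied to the contour term (default 1).
#' @return a `bw_volume` of class `bw_filtered`.
#' @export
compose_filtered <- function(m, contours, weight = 1) {
  if (!identical(dim(m$data), dim(contours$data)))
    stop("mask and contour image differ in shape")
  if (!isTRUE(all.equal(rep(m$spacing_um, length.out = 3),
                        rep(contours$spacing_um, length.out = 3))))
    stop("mask and contour image differ in spacing")
  f <- as_volume(m$data + weight * contours$data, m)
  class(f) <- c("bw_filtered", "bw_volume")
  attr(f, "provenance") <- list(mask_id = m$sample_id, weight = weight)
  f
}

#' Full preprocessing chain from raw volume to filtered feature image
#'
#' Suppresses sub-threshold background on the raw intensities, equalizes the
#' surviving signal per XY-slice, binarizes, extracts LoG contours, and
#' returns mask + contours. Background suppression runs first so that
#' rank-based equalization sees sample voxels only.
#'
#' @param v a `bw_volume`.
#' @param threshold background threshold fraction (default 0.01).
#' @param log_radius LoG sigma in voxels (default 5).
#' @param equalize apply per-slice histogram equalization (default TRUE).
#' @return a `bw_filtered` volume.
#' @export
preprocess_volume <- function(v, threshold = 0.01, log_radius = 5,
                              equalize = TRUE) {
  v <- suppress_background(v, threshold)
  if (equalize) v <- equalize_slices(v)
  m <- binarize(v, threshold)
  ct <- log_contours(v, log_radius)
  compose_filtered(m, ct)
}
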