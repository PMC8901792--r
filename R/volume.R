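#' 3D volume container
#'
#' A volume is a 3D numeric array in (Z, Y, X) axis order together with its
#' isotropic voxel spacing in micrometres and sample metadata. All
#' registration code operates on this container.
#'
#' @param data 3D numeric array, dim (nz, ny, nx).
#' @param spacing_um isotropic voxel edge length in micrometres (> 0). A
#'   length-3 vector (z, y, x) is accepted for raw, not-yet-standardized data.
#' @param sample_id character sample identifier.
#' @param side one of "whole", "left", "right".
#' @param recorded_age_days postnatal age recorded for the sample, in days.
#' @return an object of class `bw_volume`.
#' @export
volume <- function(data, spacing_um, sample_id = "sample",
                   side = c("whole", "left", "right"),
                   recorded_age_days = NA_real_) {
  side <- match.arg(side)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have extent >= 2 along every axis")
  if (any(!is.finite(data)))
    stop("volume data must be finite")
  if (any(spacing_um <= 0))
    stop("spacing_um must be positive")
  structure(
    list(data = data, spacing_um = spacing_um, sample_id = sample_id,
         side = side, recorded_age_days = recorded_age_days),
    class = "bw_volume")
}

#' @export
print.bw_volume <- function(x, ...) {
  cat(sprintf("<bw_volume> %s [%s] %s voxels @ %s um, age %s d\n",
              x$sample_id, x$side, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_um, 4), collapse = "/"),
              format(x$recorded_age_days)))
  invisible(x)
}

#' Rebuild a volume around new data, keeping metadata
#'
#' Returns a copy of `like` whose `data` (and any other named fields passed
#' via `...`) are replaced; spacing and sample metadata carry over.
#'
#' @param data replacement 3D array.
#' @param like a `bw_volume` supplying metadata.
#' @param ... further fields to override (e.g. `side`, `spacing_um`).
#' @return a `bw_volume`.
#' @export
as_volume <- function(data, like, ...) {
  v <- like
  v$data <- data
  extra <- list(...)
  for (nm in names(extra)) v[[nm]] <- extra[[nm]]
  v
}

# ---- resampling -------------------------------------------------------------

block_mean <- function(a, f) {
  d <- dim(a)
  nd <- d %/% f
  a <- a[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]),
         drop = FALSE]
  dim(a) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  a <- aperm(a, c(2, 4, 6, 1, 3, 5))
  dim(a) <- c(prod(nd), prod(f))
  array(rowMeans(a), nd)
}

#' Resample a volume to a target isotropic spacing
#'
#' Integer downsampling factors use block averaging (antialiased); fractional
#' factors use trilinear interpolation. Upsampling is refused by
#' [load_and_standardize()]'s callers but supported here via trilinear
#' interpolation.
#'
#' @param v a `bw_volume` (spacing may be per-axis).
#' @param target_spacing_um desired isotropic spacing.
#' @return a `bw_volume` at the target spacing.
#' @export
resample_volume <- function(v, target_spacing_um) {
  sp <- rep(v$spacing_um, length.out = 3) # (z, y, x)
  f <- target_spacing_um / sp
  if (all(abs(f - 1) < 1e-9)) {
    v$spacing_um <- target_spacing_um
    return(v)
  }
  d <- dim(v$data)
  if (all(abs(f - round(f)) < 1e-9) && all(round(f) >= 1)) {
    out <- block_mean(v$data, as.integer(round(f)))
  } else {
    odim <- pmax(2L, as.integer(floor((d - 1) / f) + 1))
    out <- cpp_resample_trilinear(v$data, as.integer(d), odim, f)
  }
  as_volume(out, v, spacing_um = target_spacing_um)
}

# ---- readers / writers ------------------------------------------------------

vol_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.(tif|tiff)$", p)) return("tiff")
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.nrrd$", p)) return("nrrd")
  stop("unsupported volume format: ", path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    kv <- strsplit(ln, ":=?", fixed = FALSE)[[1]]
    hdr[[trimws(tolower(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  type <- hdr$type
  enc <- hdr$encoding %||% "raw"
  what <- switch(type,
    "double" = "double", "float" = "double",
    "short" = "integer", "unsigned short" = "integer", "ushort" = "integer",
    "uchar" = "integer", "unsigned char" = "integer",
    stop("unsupported NRRD type: ", type))
  size <- switch(type, "double" = 8, "float" = 4, "short" = 2,
                 "unsigned short" = 2, "ushort" = 2, 1)
  signed <- !type %in% c("unsigned short", "ushort", "uchar", "unsigned char")
  n <- prod(sizes)
  raw_data <- readBin(con, "raw", n = n * size + 8)
  if (identical(enc, "gzip")) raw_data <- memDecompress(raw_data, "gzip")
  vals <- readBin(raw_data, what, n = n, size = size, signed = signed,
                  endian = "little")
  spacing <- NULL
  if (!is.null(hdr$spacings))
    spacing <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  # NRRD lists the fastest axis first (x, y, z); convert to (z, y, x)
  a <- array(as.double(vals), dim = sizes)
  list(data = aperm(a, c(3, 2, 1)),
       spacing = if (!is.null(spacing)) rev(spacing) else NULL)
}

write_nrrd <- function(v, path) {
  d <- dim(v$data)
  sp <- rep(v$spacing_um, length.out = 3)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "NRRD0004\n",
    "type: double\n",
    "dimension: 3\n",
    sprintf("sizes: %d %d %d\n", d[3], d[2], d[1]),
    sprintf("spacings: %.17g %.17g %.17g\n", sp[3], sp[2], sp[1]),
    "endian: little\n",
    "encoding: raw\n",
    "\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.double(aperm(v$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  invisible(path)
}

#' Read a 3D volume from disk
#'
#' Supported formats: multi-page TIFF (spacing must be supplied), NIfTI
#' (.nii/.nii.gz, spacing read from the header) and NRRD (raw or gzip
#' encoding). Data are returned in (Z, Y, X) axis order.
#'
#' @param path file path.
#' @param spacing_um voxel spacing in micrometres; overrides any header value.
#'   Scalar or (z, y, x) vector.
#' @param ... passed to [volume()] (sample_id, side, recorded_age_days).
#' @return a `bw_volume`.
#' @export
read_volume <- function(path, spacing_um = NULL, ...) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  fmt <- vol_format(path)
  if (fmt == "tiff") {
    sl <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(sl)) sl <- list(sl)
    sl <- lapply(sl, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
    d <- c(length(sl), dim(sl[[1]]))
    a <- array(0, d)
    for (z in seq_along(sl)) a[z, , ] <- sl[[z]]
    sp <- spacing_um
    if (is.null(sp))
      stop("TIFF carries no voxel spacing metadata; supply spacing_um")
  } else if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    a <- aperm(array(as.double(img), dim(img)), c(3, 2, 1))
    sp <- spacing_um %||% rev(RNifti::pixdim(img)[1:3])
  } else {
    nr <- read_nrrd(path)
    a <- nr$data
    sp <- spacing_um %||% nr$spacing
    if (is.null(sp))
      stop("NRRD header carries no spacings; supply spacing_um")
  }
  volume(a, spacing_um = sp, ...)
}

#' Write a 3D volume to disk
#'
#' TIFF output is a 16-bit multi-page stack scaled to the volume maximum
#' (lossy for float data); NIfTI and NRRD store doubles and round-trip
#' exactly.
#'
#' @param v a `bw_volume`.
#' @param path output path; format chosen by extension.
#' @export
write_volume <- function(v, path) {
  fmt <- vol_format(path)
  if (fmt == "tiff") {
    mx <- max(v$data)
    sc <- if (mx > 0) v$data / mx else v$data
    sl <- lapply(seq_len(dim(sc)[1]), function(z) sc[z, , ])
    tiff::writeTIFF(sl, path, bits.per.sample = 16L)
  } else if (fmt == "nifti") {
    sp <- rep(v$spacing_um, length.out = 3)
    img <- RNifti::asNifti(aperm(v$data, c(3, 2, 1)))
    RNifti::pixdim(img) <- rev(sp)
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(v, path)
  }
  invisible(path)
}

#' Load a volume and standardize it to an isotropic working resolution
#'
#' Reads the file, reorders axes to (Z, Y, X) and resamples to the target
#' isotropic spacing (default 12 um, the working resolution used for
#' light-sheet brain stacks). Integer per-axis factors are block-averaged;
#' fractional factors fall back to trilinear interpolation.
#'
#' @inheritParams read_volume
#' @param target_spacing_um isotropic output spacing (default 12).
#' @return a `bw_volume` at `target_spacing_um`.
#' @export
load_and_standardize <- function(path, target_spacing_um = 12,
                                 spacing_um = NULL, ...) {
  v <- read_volume(path, spacing_um = spacing_um, ...)
  resample_volume(v, target_spacing_um)
}
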