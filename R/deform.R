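#' Create a free-form deformation grid
#'
#' Nodes form a regular lattice spanning the full volume extent (corners
#' included), with one 3-vector displacement per node, initialized to zero.
#' The warp between nodes is piecewise trilinear.
#'
#' @param volume_shape integer (nz, ny, nx) voxel extents.
#' @param node_counts integer (gz, gy, gx) node counts, each >= 2.
#' @param spacing_um voxel spacing the grid's voxel units refer to (optional
#'   bookkeeping).
#' @return an object of class `bw_grid`.
#' @export
create_grid <- function(volume_shape, node_counts, spacing_um = NA_real_) {
  volume_shape <- as.integer(volume_shape)
  node_counts <- as.integer(node_counts)
  if (length(volume_shape) != 3 || any(volume_shape < 2))
    stop("volume_shape must be 3 extents, each >= 2")
  if (length(node_counts) != 3 || any(node_counts < 2))
    stop("node_counts must be 3 counts, each >= 2")
  structure(
    list(volume_shape = volume_shape, node_counts = node_counts,
         spacing_um = spacing_um,
         displacements = array(0, c(node_counts, 3))),
    class = "bw_grid")
}

#' @export
print.bw_grid <- function(x, ...) {
  cat(sprintf("<bw_grid> %s nodes on %s voxels, max |disp| %.3g\n",
              paste(x$node_counts, collapse = "x"),
              paste(x$volume_shape, collapse = "x"),
              max(abs(x$displacements))))
  invisible(x)
}

# node spacing in voxels, per axis
grid_spacing <- function(g) (g$volume_shape - 1) / (g$node_counts - 1)

# rest positions of the nodes along one axis (0-based voxel coordinates)
node_positions <- function(g, axis) {
  seq(0, g$volume_shape[axis] - 1, length.out = g$node_counts[axis])
}

#' Refine a deformation grid to a denser node lattice
#'
#' New nodes receive trilinearly interpolated displacements from the old
#' grid, so the displacement field is preserved at all old node positions
#' (exactly, for nested refinements such as the default coarse-to-fine
#' sequence).
#'
#' @param g a `bw_grid`.
#' @param new_counts target node counts, each >= the current count.
#' @return a refined `bw_grid`.
#' @export
refine_grid <- function(g, new_counts) {
  new_counts <- as.integer(new_counts)
  if (any(new_counts < g$node_counts))
    stop("refinement cannot reduce node counts")
  if (all(new_counts == g$node_counts)) return(g)
  g2 <- create_grid(g$volume_shape, new_counts, g$spacing_um)
  pts <- as.matrix(expand.grid(
    z = node_positions(g2, 1), y = node_positions(g2, 2),
    x = node_positions(g2, 3)))
  # expand.grid varies the first column fastest = node linear order
  f <- cpp_field_at_points(pts, g$volume_shape, g$displacements,
                           g$node_counts)
  g2$displacements <- array(f, c(new_counts, 3))
  g2
}

#' Per-voxel displacement field of a grid
#'
#' Trilinear interpolation of the node displacements at every voxel center.
#'
#' @param g a `bw_grid`.
#' @return numeric array, dim (nz, ny, nx, 3), voxel units.
#' @export
displacement_field <- function(g) {
  cpp_displacement_field(g$volume_shape, g$displacements, g$node_counts)
}

#' Warp a volume by a deformation grid
#'
#' Backward mapping: each output voxel x takes the trilinearly interpolated
#' source intensity at x + field(x); samples outside the source extent read
#' zero (volumes are background-suppressed, so outside is empty).
#'
#' @param v a `bw_volume` (or filtered volume).
#' @param g a `bw_grid` spanning `v`'s extent.
#' @return a warped volume of the same class.
#' @export
warp_volume <- function(v, g) {
  if (!identical(dim(v$data), as.integer(g$volume_shape)))
    stop("grid does not span the volume's extent")
  out <- cpp_warp(v$data, g$volume_shape, g$displacements, g$node_counts)
  as_volume(array(out, dim(v$data)), v)
}

#' L1 volume-change deformation energy
#'
#' Each hexahedral grid cell is split into 5 tetrahedra (alternating parity,
#' conforming faces); the energy is the sum over tetrahedra of the absolute
#' change in signed volume between rest and deformed node positions, divided
#' by the total rest volume. Zero iff all tetra volumes are preserved;
#' dimensionless, so the objective's weight transfers across resolutions.
#'
#' @param g a `bw_grid`.
#' @return nonnegative scalar.
#' @export
deformation_energy <- function(g) {
  cpp_deformation_energy(g$volume_shape, g$displacements, g$node_counts)
}

#' Pearson similarity between two images
#'
#' @param a,b volumes (or arrays) of identical shape, both nonconstant.
#' @return correlation in [-1, 1].
#' @export
pearson_similarity <- function(a, b) {
  av <- if (is.list(a)) a$data else a
  bv <- if (is.list(b)) b$data else b
  if (!identical(dim(av), dim(bv))) stop("shape mismatch")
  if (sd(av) == 0 || sd(bv) == 0)
    stop("correlation undefined for a constant image")
  cor(as.vector(av), as.vector(bv))
}

#' Registration objective
#'
#' Pearson correlation of the warped source with the target, minus
#' `lambda` times the deformation energy. The default weight 1/1000
#' balances alignment against feature preservation; benchmark-style
#' whole-brain alignment uses 1/100000.
#'
#' @param source,target filtered volumes of identical shape.
#' @param g a `bw_grid`.
#' @param lambda deformation-energy weight (default 1/1000).
#' @return scalar objective value (maximized by the optimizer).
#' @export
registration_objective <- function(source, target, g, lambda = 1 / 1000) {
  pearson_similarity(warp_volume(source, g), target) -
    lambda * deformation_energy(g)
}

#' Serialize a deformation grid to JSON
#'
#' Displacements are written in (Z, Y, X) node order with full double
#' precision, so `grid_from_json(grid_to_json(g))` is bit-exact.
#'
#' @param g a `bw_grid`.
#' @param path optional file to write to.
#' @return JSON string (invisibly, if `path` is given).
#' @export
grid_to_json <- function(g, path = NULL) {
  obj <- list(node_counts = g$node_counts, volume_shape = g$volume_shape,
              spacing_um = g$spacing_um,
              displacements = as.numeric(g$displacements))
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a deformation grid from JSON
#'
#' @param x JSON string or path to a JSON file written by [grid_to_json()].
#' @return a `bw_grid`.
#' @export
grid_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  g <- create_grid(obj$volume_shape, obj$node_counts,
                   if (length(obj$spacing_um)) obj$spacing_um else NA_real_)
  g$displacements <- array(obj$displacements, c(g$node_counts, 3))
  g
}
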