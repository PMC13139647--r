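#' Voxel grid specification
#'
#' A regular cubic grid: origin, edge length and voxel counts per axis, plus
#' the occupancy threshold (minimum points per voxel for a voxel to count as
#' occupied; the default 1 means any return fills a voxel).
#'
#' @param origin Numeric length-3 (x0, y0, z0), metres.
#' @param edge Voxel edge length in metres; default 0.40.
#' @param dims Integer length-3 (nx, ny, nz) voxel counts.
#' @param min_points Occupancy threshold, points per voxel (default 1).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(origin = c(0, 0, 0), edge = 0.4, dims, min_points = 1L) {
  stopifnot(length(origin) == 3, is.finite(origin), edge > 0,
            length(dims) == 3, all(dims >= 1), min_points >= 1)
  structure(list(origin = as.numeric(origin), edge = edge,
                 dims = as.integer(dims), min_points = as.integer(min_points)),
            class = "grid_spec")
}

#' Derive a grid spec from a subplot footprint and cloud height
#'
#' Horizontal dimensions are `ceiling(footprint / edge)` (edge voxels may
#' overhang the footprint, but the per-layer denominator is then constant at
#' `nx * ny`); the vertical dimension covers the cloud's highest point,
#' `nz = ceiling(max z / edge)`, with z0 at ground (0).
#'
#' @param footprint List with `xlo`, `xhi`, `ylo`, `yhi` as returned by
#'   [subplot_footprint()].
#' @param max_z Height of the highest point (m); must be > 0.
#' @param edge Voxel edge length (m), default 0.40.
#' @param min_points Occupancy threshold (default 1).
#' @return A [grid_spec()].
#' @export
grid_for_footprint <- function(footprint, max_z, edge = 0.4, min_points = 1L) {
  stopifnot(max_z > 0)
  nx <- ceiling((footprint$xhi - footprint$xlo) / edge)
  ny <- ceiling((footprint$yhi - footprint$ylo) / edge)
  nz <- ceiling(max_z / edge)
  grid_spec(origin = c(footprint$xlo, footprint$ylo, 0), edge = edge,
            dims = c(nx, ny, nz), min_points = min_points)
}

#' Voxelise a point cloud
#'
#' Point p maps to cell `(floor((p.x - x0)/e), floor((p.y - y0)/e),
#' floor((p.z - z0)/e))` (0-based in that formula; counts are stored in a
#' 1-based R array). Points outside `[origin, origin + dims * e)` on any axis
#' are dropped and reported in the `out_of_bounds` tally, never an error.
#'
#' @param cloud A [point_cloud()]; may be empty (all-zero grid).
#' @param spec A [grid_spec()].
#' @return A `voxel_grid` list: `spec`, integer `counts` array of dim
#'   (nx, ny, nz), and `out_of_bounds` count.
#' @export
voxelize <- function(cloud, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  d <- spec$dims
  counts <- array(0L, dim = d)
  oob <- 0L
  if (nrow(cloud)) {
    i <- floor((cloud$x - spec$origin[1]) / spec$edge)
    j <- floor((cloud$y - spec$origin[2]) / spec$edge)
    k <- floor((cloud$z - spec$origin[3]) / spec$edge)
    inb <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    oob <- sum(!inb)
    if (any(inb)) {
      lin <- i[inb] + d[1] * (j[inb] + d[2] * k[inb]) + 1
      tab <- tabulate(lin, nbins = prod(d))
      counts <- array(as.integer(tab), dim = d)
    }
  }
  structure(list(spec = spec, counts = counts, out_of_bounds = as.integer(oob)),
            class = "voxel_grid")
}

#' Build a voxel grid directly from a hand-specified occupancy pattern
#'
#' Test and example helper: constructs a `voxel_grid` whose counts array is
#' given explicitly.
#'
#' @param counts Integer array of dim (nx, ny, nz).
#' @param edge Voxel edge length (m).
#' @param origin Grid origin, default (0, 0, 0).
#' @param min_points Occupancy threshold.
#' @return A `voxel_grid`.
#' @export
voxel_grid_from_counts <- function(counts, edge = 0.4, origin = c(0, 0, 0),
                                   min_points = 1L) {
  stopifnot(length(dim(counts)) == 3)
  spec <- grid_spec(origin = origin, edge = edge, dims = dim(counts),
                    min_points = min_points)
  structure(list(spec = spec, counts = array(as.integer(counts), dim(counts)),
                 out_of_bounds = 0L),
            class = "voxel_grid")
}

# Logical occupancy array for a grid.
.occupied <- function(grid) grid$counts >= grid$spec$min_points

#' Total number of occupied voxels
#' @param grid A `voxel_grid`.
#' @return Integer count.
#' @export
occupied_total <- function(grid) sum(.occupied(grid))

#' Per-layer occupancy profile
#'
#' For each horizontal layer k (bottom layer = 1) computes the occupancy
#' fraction `o_k` = occupied voxels in the layer / (nx * ny); the denominator
#' is the constant grid footprint. The layer's vertical extent is
#' `[z0 + (k-1)*e, z0 + k*e)`.
#'
#' @param grid A `voxel_grid`.
#' @return Data frame with columns `layer`, `z_lo`, `z_hi`, `occupied`,
#'   `occupancy` (one row per layer, bottom first).
#' @export
layer_profile <- function(grid) {
  d <- grid$spec$dims
  occ <- apply(.occupied(grid), 3, sum)
  k <- seq_len(d[3])
  data.frame(layer = k,
             z_lo = grid$spec$origin[3] + (k - 1) * grid$spec$edge,
             z_hi = grid$spec$origin[3] + k * grid$spec$edge,
             occupied = as.integer(occ),
             occupancy = occ / (d[1] * d[2]))
}

#' Occupied and total voxel counts within a contiguous layer range
#'
#' The numerator/denominator provider for the space filling index: `total` is
#' (number of layers) * nx * ny and `occupied` counts occupied voxels within
#' those layers.
#'
#' @param grid A `voxel_grid`.
#' @param layers Contiguous 1-based layer indices, non-empty, within
#'   `[1, nz]`.
#' @return List with `occupied` and `total` counts.
#' @export
occupied_in_slab <- function(grid, layers) {
  d <- grid$spec$dims
  if (!length(layers)) stop("empty layer range")
  layers <- as.integer(layers)
  if (any(layers < 1 | layers > d[3])) {
    stop("layer range out of bounds [1, ", d[3], "]")
  }
  occ <- sum(.occupied(grid)[, , layers, drop = FALSE])
  list(occupied = as.integer(occ),
       total = as.integer(length(layers) * d[1] * d[2]))
}

#' Export nonzero voxel counts as a plain table
#'
#' @param grid A `voxel_grid`.
#' @return Data frame of (i, j, k, count) for cells with count > 0, 1-based
#'   indices ordered by k, then j, then i.
#' @export
voxel_table <- function(grid) {
  nz <- which(grid$counts > 0)
  idx <- arrayInd(nz, dim(grid$counts))
  ord <- order(idx[, 3], idx[, 2], idx[, 1])
  data.frame(i = idx[ord, 1], j = idx[ord, 2], k = idx[ord, 3],
             count = grid$counts[nz][ord])
}
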