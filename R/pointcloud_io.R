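#' Construct a point cloud
#'
#' A point cloud is a plain data frame with numeric columns `x`, `y`, `z`
#' (metres) and a `source_id` attribute naming the plot or subplot it came
#' from. Clouds may be empty; downstream functions handle that explicitly.
#'
#' @param x,y,z Numeric coordinate vectors of equal length, metres.
#' @param source_id Plot or subplot label, a single string.
#' @return A `point_cloud` data frame.
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        source_id = "cloud") {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(x) && !all(is.finite(x) & is.finite(y) & is.finite(z))) {
    stop("point cloud coordinates must all be finite")
  }
  cloud <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  attr(cloud, "source_id") <- source_id
  class(cloud) <- c("point_cloud", "data.frame")
  cloud
}

#' Plot geometry
#'
#' Describes one square experimental plot: lower-left corner, side lengths,
#' the edge buffer stripped before analysis, and the implicit 2 x 2 subplot
#' layout of the buffered interior.
#'
#' @param origin Numeric length-2, (x, y) of the plot's lower-left corner (m).
#' @param side_x,side_y Plot side lengths in metres (default 45).
#' @param buffer Edge buffer width in metres removed on all four sides
#'   (default 2).
#' @return A `plot_geometry` list.
#' @export
plot_geometry <- function(origin = c(0, 0), side_x = 45, side_y = 45,
                          buffer = 2) {
  stopifnot(length(origin) == 2, is.finite(origin), side_x > 0, side_y > 0,
            buffer >= 0)
  if (side_x - 2 * buffer <= 0 || side_y - 2 * buffer <= 0) {
    stop("buffer too wide: side - 2*buffer must be positive")
  }
  structure(list(origin = as.numeric(origin), side_x = side_x,
                 side_y = side_y, buffer = buffer),
            class = "plot_geometry")
}

#' Read a point cloud from an ASCII XYZ file
#'
#' One point per line, whitespace- or comma-delimited, at least three numeric
#' columns (x, y, z in metres); extra columns are ignored and point order is
#' preserved. Lines that do not yield three finite numbers raise an error
#' naming the offending line.
#'
#' @param path Path to the file.
#' @param format Only `"xyz"` is supported; binary LAS/LAZ input is out of
#'   scope for this package and should be converted to XYZ upstream.
#' @param source_id Label stored on the returned cloud; defaults to the file
#'   name.
#' @return A [point_cloud()].
#' @export
read_cloud <- function(path, format = "xyz",
                       source_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!identical(format, "xyz")) {
    stop("unknown format '", format, "': only 'xyz' is supported")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(point_cloud(source_id = source_id))
  fields <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  ncol <- lengths(fields)
  bad <- idx[ncol < 3]
  if (length(bad)) {
    stop("malformed row in ", path, ": line ", bad[1],
         " has fewer than 3 columns")
  }
  xyz <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1:3])),
                numeric(3))
  nonnum <- idx[colSums(!is.finite(xyz)) > 0]
  if (length(nonnum)) {
    stop("malformed row in ", path, ": non-numeric coordinate on line ",
         nonnum[1])
  }
  point_cloud(xyz[1, ], xyz[2, ], xyz[3, ], source_id = source_id)
}

#' Write a point cloud as ASCII XYZ
#'
#' @param cloud A [point_cloud()].
#' @param path Output path.
#' @param digits Significant digits written (default 10, enough for mm
#'   precision on kilometre coordinates).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, digits = 10) {
  m <- format(as.matrix(cloud[, c("x", "y", "z")]), digits = digits,
              trim = TRUE, scientific = FALSE)
  writeLines(apply(m, 1, paste, collapse = " "), path)
  invisible(path)
}

# Half-open rectangle membership [lo, hi) on x and y; the shared convention
# for buffer clipping and quadrant assignment so no point is double-counted.
.in_rect <- function(cloud, xlo, xhi, ylo, yhi) {
  cloud$x >= xlo & cloud$x < xhi & cloud$y >= ylo & cloud$y < yhi
}

#' Remove the plot-edge buffer
#'
#' Retains exactly the points whose (x, y) fall in the half-open buffered
#' rectangle `[origin + buffer, origin + side - buffer)`; z is untouched.
#' Idempotent; an empty result is allowed.
#'
#' @param cloud A [point_cloud()].
#' @param geom A [plot_geometry()].
#' @return The clipped [point_cloud()].
#' @export
clip_buffer <- function(cloud, geom) {
  stopifnot(inherits(geom, "plot_geometry"))
  xlo <- geom$origin[1] + geom$buffer
  ylo <- geom$origin[2] + geom$buffer
  xhi <- geom$origin[1] + geom$side_x - geom$buffer
  yhi <- geom$origin[2] + geom$side_y - geom$buffer
  keep <- .in_rect(cloud, xlo, xhi, ylo, yhi)
  out <- cloud[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_id") <- attr(cloud, "source_id")
  class(out) <- class(cloud)
  out
}

#' Split a buffered cloud into four subplot clouds
#'
#' Assigns each point to exactly one quadrant of the buffered interior by
#' half-open x/y midlines (a point exactly on a midline goes to the
#' eastern/northern side). Labels are `SW`, `SE`, `NW`, `NE`.
#'
#' @param cloud A buffer-clipped [point_cloud()].
#' @param geom A [plot_geometry()].
#' @return Named list of four [point_cloud()]s whose sizes sum to the input
#'   size.
#' @export
split_subplots <- function(cloud, geom) {
  stopifnot(inherits(geom, "plot_geometry"))
  xmid <- geom$origin[1] + geom$side_x / 2
  ymid <- geom$origin[2] + geom$side_y / 2
  east <- cloud$x >= xmid
  north <- cloud$y >= ymid
  lab <- ifelse(north, ifelse(east, "NE", "NW"), ifelse(east, "SE", "SW"))
  src <- attr(cloud, "source_id")
  out <- lapply(c(SW = "SW", SE = "SE", NW = "NW", NE = "NE"), function(q) {
    sub <- cloud[lab == q, , drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "source_id") <- paste(src, q, sep = "_")
    class(sub) <- class(cloud)
    sub
  })
  out
}

#' Footprint of one subplot quadrant
#'
#' Returns the half-open (x, y) rectangle of a named quadrant of the buffered
#' interior, used to anchor the voxel grid.
#'
#' @param geom A [plot_geometry()].
#' @param quadrant One of `"SW"`, `"SE"`, `"NW"`, `"NE"`.
#' @return List with `xlo`, `xhi`, `ylo`, `yhi` (m).
#' @export
subplot_footprint <- function(geom, quadrant = c("SW", "SE", "NW", "NE")) {
  quadrant <- match.arg(quadrant)
  xlo <- geom$origin[1] + geom$buffer
  ylo <- geom$origin[2] + geom$buffer
  xhi <- geom$origin[1] + geom$side_x - geom$buffer
  yhi <- geom$origin[2] + geom$side_y - geom$buffer
  xmid <- geom$origin[1] + geom$side_x / 2
  ymid <- geom$origin[2] + geom$side_y / 2
  switch(quadrant,
    SW = list(xlo = xlo, xhi = xmid, ylo = ylo, yhi = ymid),
    SE = list(xlo = xmid, xhi = xhi, ylo = ylo, yhi = ymid),
    NW = list(xlo = xlo, xhi = xmid, ylo = ymid, yhi = yhi),
    NE = list(xlo = xmid, xhi = xhi, ylo = ymid, yhi = yhi))
}

#' Normalise heights to a lowest-point ground model
#'
#' Subtracts, per horizontal grid cell of size `cell`, the minimum z found in
#' that cell. A deliberately simple terrain model: with dense ground returns
#' the residual error is bounded by the terrain relief across one cell.
#' Off by default in the pipeline — synthetic clouds are generated
#' ground-relative and real-data users opt in.
#'
#' @param cloud A non-empty [point_cloud()].
#' @param cell Horizontal cell size in metres (default 1).
#' @return A [point_cloud()] with all z >= 0.
#' @export
normalize_heights <- function(cloud, cell = 1.0) {
  if (!nrow(cloud)) stop("cannot normalise heights of an empty cloud")
  stopifnot(cell > 0)
  ci <- floor(cloud$x / cell)
  cj <- floor(cloud$y / cell)
  key <- paste(ci, cj)
  zmin <- tapply(cloud$z, key, min)
  out <- cloud
  out$z <- cloud$z - as.numeric(zmin[key])
  out
}
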