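#' Canopy space definitions
#'
#' The four vertical delineations of the canopy space used throughout the
#' package, each a slab between an upper and a lower boundary height:
#' \describe{
#'   \item{total}{lowest green branch (LGB) up to the highest canopy top
#'     (H_max).}
#'   \item{top}{two-thirds of H_max up to H_max.}
#'   \item{mid}{one-third of H_max up to the 10 percent occupancy height
#'     (h10).}
#'   \item{main}{LGB up to h10.}
#' }
#' @export
CANOPY_DEFINITIONS <- c("total", "top", "mid", "main")

#' Detect canopy boundary heights from a voxel grid
#'
#' Three per-subplot boundary heights:
#' \itemize{
#'   \item `h_max`: top face of the highest occupied layer (canopy top).
#'   \item `h10`: scanning from the top layer downward, the top face of the
#'     first layer whose occupancy fraction reaches `tau` (default 0.10).
#'     `NA` if no layer reaches `tau` (the mid/main definitions are then
#'     invalid).
#'   \item `lgb`: the lowest green branch. If `lgb_override` is supplied
#'     (e.g. from field measurement) it is used directly; otherwise the
#'     bottom face of the lowest occupied layer whose bottom face lies at or
#'     above `ground_exclusion` (default 0.3 m, screening out ground
#'     returns), or 0 if no such layer exists.
#' }
#'
#' @param grid A `voxel_grid` with at least one occupied voxel.
#' @param tau Occupancy threshold for h10, in (0, 1); comparison is `>= tau`.
#' @param lgb_override Optional externally measured LGB height (m).
#' @param ground_exclusion Ground-exclusion height for the grid-derived LGB
#'   (m, default 0.3).
#' @return A `canopy_bounds` list: `h_max`, `lgb`, `h10` (h10 may be `NA`).
#' @export
detect_bounds <- function(grid, tau = 0.10, lgb_override = NULL,
                          ground_exclusion = 0.3) {
  stopifnot(tau > 0, tau < 1)
  prof <- layer_profile(grid)
  occ_layers <- which(prof$occupied > 0)
  if (!length(occ_layers)) stop("empty canopy: no occupied voxel in grid")
  h_max <- prof$z_hi[max(occ_layers)]
  at_tau <- which(prof$occupancy >= tau)
  h10 <- if (length(at_tau)) prof$z_hi[max(at_tau)] else NA_real_
  if (!is.null(lgb_override)) {
    lgb <- as.numeric(lgb_override)
  } else {
    eligible <- occ_layers[prof$z_lo[occ_layers] >= ground_exclusion]
    lgb <- if (length(eligible)) prof$z_lo[min(eligible)] else 0
  }
  if (lgb < 0 || lgb > h_max) {
    stop("invalid lowest green branch height ", lgb,
         " (must lie in [0, h_max])")
  }
  structure(list(h_max = h_max, lgb = lgb, h10 = h10, tau = tau),
            class = "canopy_bounds")
}

#' Vertical slab for one canopy space definition
#'
#' Maps boundary heights to a `[z_lo, z_hi]` slab:
#' total `[lgb, h_max]`; top `[(2/3) h_max, h_max]`;
#' mid `[(1/3) h_max, h10]`; main `[lgb, h10]`.
#' Degenerate slabs (inverted bounds, or h10 undefined for mid/main) are
#' returned flagged invalid rather than raising, so batch runs complete.
#'
#' @param bounds A `canopy_bounds`.
#' @param definition One of [CANOPY_DEFINITIONS].
#' @return List with `definition`, `z_lo`, `z_hi`, `valid`, `reason`.
#' @export
slab_for_definition <- function(bounds, definition = CANOPY_DEFINITIONS) {
  definition <- match.arg(definition)
  h <- bounds$h_max
  lim <- switch(definition,
    total = c(bounds$lgb, h),
    top   = c(2 / 3 * h, h),
    mid   = c(1 / 3 * h, bounds$h10),
    main  = c(bounds$lgb, bounds$h10))
  if (definition %in% c("mid", "main") && is.na(bounds$h10)) {
    return(list(definition = definition, z_lo = NA_real_, z_hi = NA_real_,
                valid = FALSE, reason = "h10 undefined"))
  }
  if (lim[1] >= lim[2]) {
    return(list(definition = definition, z_lo = lim[1], z_hi = lim[2],
                valid = FALSE, reason = "empty slab"))
  }
  list(definition = definition, z_lo = lim[1], z_hi = lim[2],
       valid = TRUE, reason = "")
}

# Layers whose centre z0 + (k - 1/2)*e falls in the closed slab [z_lo, z_hi].
.slab_layers <- function(spec, z_lo, z_hi) {
  centres <- spec$origin[3] + (seq_len(spec$dims[3]) - 0.5) * spec$edge
  which(centres >= z_lo & centres <= z_hi)
}

#' Canopy space filling index over a vertical slab
#'
#' The fraction of occupied voxels among all voxels of the horizontal layers
#' whose centres fall within the closed slab `[z_lo, z_hi]`. Invalid slabs,
#' or slabs containing no layer centre, yield a flagged invalid record with
#' `csfi = NA` rather than an error.
#'
#' @param grid A `voxel_grid`.
#' @param slab A slab from [slab_for_definition()], or a list with `z_lo`,
#'   `z_hi`.
#' @return A one-row data frame: `definition`, `z_lo`, `z_hi`, `layer_lo`,
#'   `layer_hi`, `occupied`, `total`, `csfi`, `valid`, `reason`.
#' @export
csfi <- function(grid, slab) {
  def <- if (!is.null(slab$definition)) slab$definition else "custom"
  invalid <- function(reason) {
    data.frame(definition = def, z_lo = slab$z_lo, z_hi = slab$z_hi,
               layer_lo = NA_integer_, layer_hi = NA_integer_,
               occupied = NA_integer_, total = NA_integer_, csfi = NA_real_,
               valid = FALSE, reason = reason)
  }
  if (!is.null(slab$valid) && !slab$valid) return(invalid(slab$reason))
  layers <- .slab_layers(grid$spec, slab$z_lo, slab$z_hi)
  if (!length(layers)) return(invalid("no layer centre in slab"))
  ct <- occupied_in_slab(grid, layers)
  data.frame(definition = def, z_lo = slab$z_lo, z_hi = slab$z_hi,
             layer_lo = min(layers), layer_hi = max(layers),
             occupied = ct$occupied, total = ct$total,
             csfi = ct$occupied / ct$total, valid = TRUE, reason = "")
}

#' CSFI under all four canopy space definitions
#'
#' @param grid A `voxel_grid` with at least one occupied voxel.
#' @param tau Occupancy threshold for h10 (default 0.10).
#' @param lgb_override Optional measured LGB height (m).
#' @param ground_exclusion Ground-exclusion height (m) for the grid-derived
#'   LGB.
#' @return Four-row data frame, one row per definition, as in [csfi()].
#' @export
csfi_all_definitions <- function(grid, tau = 0.10, lgb_override = NULL,
                                 ground_exclusion = 0.3) {
  bounds <- detect_bounds(grid, tau = tau, lgb_override = lgb_override,
                          ground_exclusion = ground_exclusion)
  do.call(rbind, lapply(CANOPY_DEFINITIONS, function(d) {
    csfi(grid, slab_for_definition(bounds, d))
  }))
}

#' Pairwise Pearson correlations of CSFI across definitions
#'
#' Takes a long CSFI table over many subplots (columns `subplot`,
#' `definition`, `csfi`, `valid`), pivots it wide, and returns the 4 x 4
#' Pearson correlation matrix over subplots where all four definitions are
#' valid. With fewer than two complete subplots the correlations are omitted
#' with a warning.
#'
#' @param csfi_table Long CSFI table, e.g. rows of [csfi_all_definitions()]
#'   bound together with a `subplot` column.
#' @return Symmetric 4 x 4 matrix with unit diagonal, or `NULL` (with a
#'   warning) if fewer than 2 complete subplots.
#' @export
csfi_correlations <- function(csfi_table) {
  wide <- stats::reshape(
    csfi_table[, c("subplot", "definition", "csfi")],
    idvar = "subplot", timevar = "definition", direction = "wide")
  cols <- paste0("csfi.", CANOPY_DEFINITIONS)
  stopifnot(all(cols %in% names(wide)))
  m <- as.matrix(wide[, cols])
  colnames(m) <- rownames(m) <- NULL
  complete <- stats::complete.cases(m)
  if (sum(complete) < 2) {
    warning("fewer than 2 subplots with all definitions valid; ",
            "correlations omitted")
    return(NULL)
  }
  r <- stats::cor(m[complete, , drop = FALSE])
  dimnames(r) <- list(CANOPY_DEFINITIONS, CANOPY_DEFINITIONS)
  r
}

#' CSFI table for one subplot cloud
#'
#' Convenience wrapper chaining grid construction, boundary detection and the
#' four definitions for one subplot point cloud.
#'
#' @param cloud Subplot [point_cloud()], buffer-clipped and ground-relative.
#' @param footprint Subplot footprint from [subplot_footprint()].
#' @param edge Voxel edge length (m), default 0.40.
#' @param tau Occupancy threshold for h10, default 0.10.
#' @param min_points Points per voxel for occupancy, default 1.
#' @param lgb_override Optional measured LGB (m).
#' @param ground_exclusion Ground-exclusion height (m), default 0.3.
#' @return Four-row CSFI data frame with an `out_of_bounds` attribute
#'   (points dropped at voxelisation).
#' @export
subplot_csfi <- function(cloud, footprint, edge = 0.4, tau = 0.10,
                         min_points = 1L, lgb_override = NULL,
                         ground_exclusion = 0.3) {
  if (!nrow(cloud)) stop("empty subplot cloud: no CSFI defined")
  spec <- grid_for_footprint(footprint, max_z = max(cloud$z), edge = edge,
                             min_points = min_points)
  grid <- voxelize(cloud, spec)
  out <- csfi_all_definitions(grid, tau = tau, lgb_override = lgb_override,
                              ground_exclusion = ground_exclusion)
  attr(out, "out_of_bounds") <- grid$out_of_bounds
  out
}
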