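# Shared fixtures and independent brute-force oracles. The oracles use
# deliberately naive all-pairs / per-cell loops so they share no code path
# with the implementation they check.

# Hand-built reference grid: 10 x 10 footprint, 10 layers, 0.4 m voxels.
# Bottom five layers fully occupied; each of the top five layers has exactly
# 5 occupied voxels (5% layer occupancy).
make_reference_grid <- function() {
  counts <- array(0L, c(10, 10, 10))
  counts[, , 1:5] <- 1L
  for (k in 6:10) counts[1:5, 1, k] <- 1L
  voxel_grid_from_counts(counts, edge = 0.4)
}

random_cloud <- function(n, xmax = 8, ymax = 8, zmax = 8) {
  point_cloud(runif(n, 0, xmax), runif(n, 0, ymax), runif(n, 0, zmax))
}

random_grid <- function(nx = 6, ny = 6, nz = 8, p_occupied = 0.4,
                        edge = 0.4) {
  counts <- array(as.integer(runif(nx * ny * nz) < p_occupied),
                  c(nx, ny, nz))
  voxel_grid_from_counts(counts, edge = edge)
}

# O(points x cells) voxelisation oracle: tests every point against every
# cell's half-open bounds.
brute_force_voxelize <- function(cloud, spec) {
  d <- spec$dims
  counts <- array(0L, dim = d)
  oob <- 0L
  for (p in seq_len(nrow(cloud))) {
    hit <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      lo <- spec$origin + (c(i, j, k) - 1) * spec$edge
      hi <- spec$origin + c(i, j, k) * spec$edge
      q <- c(cloud$x[p], cloud$y[p], cloud$z[p])
      if (all(q >= lo) && all(q < hi)) {
        counts[i, j, k] <- counts[i, j, k] + 1L
        hit <- TRUE
      }
    }
    if (!hit) oob <- oob + 1L
  }
  list(counts = counts, out_of_bounds = oob)
}

# Brute-force occupied/total count over the layers whose centres fall in
# [z_lo, z_hi], looping cell by cell.
brute_force_slab_count <- function(grid, z_lo, z_hi) {
  d <- grid$spec$dims
  occ <- 0L; tot <- 0L
  for (k in seq_len(d[3])) {
    centre <- grid$spec$origin[3] + (k - 0.5) * grid$spec$edge
    if (centre < z_lo || centre > z_hi) next
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      tot <- tot + 1L
      if (grid$counts[i, j, k] >= grid$spec$min_points) occ <- occ + 1L
    }
  }
  list(occupied = occ, total = tot)
}

# Minimal valid inventory data frame for productivity tests.
toy_inventory <- function() {
  data.frame(
    tree_id = c("t1", "t2", "t3", "t4"),
    plot_id = c("P1", "P1", "P2", "P2"),
    subplot_id = c("SW", "SE", "SW", "SE"),
    species = c("A", "A", "B", "C"),
    D1_cm = c(10, 12, 8, 9), H1_m = c(10, 11, 7, 8), alive_t1 = TRUE,
    D2_cm = c(14, 16, 11, 12), H2_m = c(13, 14, 9, 10), alive_t2 = TRUE)
}
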