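#' Default species trait table
#'
#' Six synthetic tropical plantation species spanning three growth guilds
#' (two each): fast-growing pioneers, light-intermediate species and
#' slow-growing shade-tolerant species. Traits drive the stand simulator:
#' first-census size distributions, annual growth rates, crown geometry
#' (vertical ellipsoids parameterised as fractions of tree height) and point
#' sampling density. Values are chosen as realistic magnitudes for a
#' ~16-year-old tropical plantation; they mimic no measured dataset.
#'
#' @return Data frame with one row per species: `species`, `guild`,
#'   `h1_mean`, `h1_sd` (m), `h_growth` (m/yr), `d1_mean`, `d1_sd` (cm),
#'   `d_growth` (cm/yr), `crown_base_frac` (crown base as fraction of
#'   height), `crown_radius_frac` (horizontal semi-axis as fraction of
#'   height), `point_density` (points per m^3 of crown volume).
#' @export
species_traits <- function() {
  data.frame(
    species = c("PIO1", "PIO2", "INT1", "INT2", "SHA1", "SHA2"),
    guild = rep(c("pioneer", "intermediate", "shade"), each = 2),
    h1_mean = c(11, 10.5, 9, 8.5, 6.5, 6),
    h1_sd = c(1.5, 1.5, 1.2, 1.2, 1.0, 1.0),
    h_growth = c(1.2, 1.1, 0.8, 0.75, 0.5, 0.45),
    d1_mean = c(14, 13, 11, 10.5, 8, 7.5),
    d1_sd = c(2.5, 2.5, 2.0, 2.0, 1.5, 1.5),
    d_growth = c(1.4, 1.3, 1.0, 0.95, 0.6, 0.55),
    crown_base_frac = c(0.55, 0.55, 0.45, 0.45, 0.32, 0.32),
    crown_radius_frac = c(0.15, 0.15, 0.18, 0.18, 0.22, 0.22),
    point_density = 50
  )
}

#' Simulation parameters
#'
#' Ground-truth parameters for the generative AWP model and nuisance
#' settings for the mechanistic stand simulator. The generative model is the
#' same gamma log-link mixed structure the analysis fits:
#' `AWP ~ Gamma(shape, mean = exp(beta0 + beta1*CSFI + beta2*mix +
#' beta3*CSFI*mix + b_plot))`, `b_plot ~ N(0, sd_plot^2)`.
#'
#' @param beta0 Link-scale intercept; default 12 puts subplot AWP at the
#'   hundreds of thousands of cm^3/yr typical of a young plantation subplot.
#' @param beta1 Link-scale CSFI effect (default 3, the order of magnitude a
#'   field study of this design reports).
#' @param beta2,beta3 Mixture main effect and CSFI x mixture interaction
#'   (default 0).
#' @param sd_plot Random-intercept SD (default 0.3).
#' @param shape Gamma shape (default 5).
#' @param mortality Per-tree probability of dying between censuses
#'   (default 0.05; survival over the interval is high by design).
#' @param density_scale Multiplier on species point densities (default 1).
#' @return A `sim_params` list.
#' @export
sim_params <- function(beta0 = 12, beta1 = 3, beta2 = 0, beta3 = 0,
                       sd_plot = 0.3, shape = 5, mortality = 0.05,
                       density_scale = 1) {
  stopifnot(shape > 0, sd_plot >= 0, mortality >= 0, mortality <= 1,
            density_scale > 0)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sd_plot = sd_plot, shape = shape, mortality = mortality,
                 density_scale = density_scale),
            class = "sim_params")
}

#' Build a monoculture/mixture experimental design
#'
#' Assembles plots of 45 x 45 m with four subplots each: `n_mono_per_species`
#' monocultures of every species, `n_mix3` three-species mixtures each
#' combining one species per guild, and `n_mix6` six-species mixtures.
#' Monoculture plots of species in `exclude` are then removed (emulating a
#' species whose monocultures failed). Deterministic given `seed`.
#'
#' @param n_mono_per_species Monoculture plots per species (default 2).
#' @param n_mix3 Three-species mixture plots (default 6).
#' @param n_mix6 Six-species mixture plots (default 6).
#' @param exclude Species codes whose monocultures are dropped (default
#'   `"PIO2"`, the second pioneer).
#' @param seed Integer seed for mix3 composition draws.
#' @param traits Species trait table (default [species_traits()]).
#' @return An `experiment_design` data frame: `plot_id`, `type` (mono /
#'   mix3 / mix6), `composition` (comma-joined species codes), `richness`;
#'   with attribute `n_subplots = 4 * nrow`.
#' @export
make_design <- function(n_mono_per_species = 2, n_mix3 = 6, n_mix6 = 6,
                        exclude = "PIO2", seed = 1,
                        traits = species_traits()) {
  set.seed(seed)
  guilds <- split(traits$species, traits$guild)
  if (any(lengths(guilds) < 1)) stop("each guild needs at least one species")
  plots <- list()
  for (sp in traits$species) {
    if (sp %in% exclude) next
    for (r in seq_len(n_mono_per_species)) {
      plots[[length(plots) + 1]] <- list(type = "mono", comp = sp)
    }
  }
  for (r in seq_len(n_mix3)) {
    comp <- vapply(guilds, function(g) sample(g, 1), character(1))
    plots[[length(plots) + 1]] <- list(type = "mix3",
                                       comp = paste(sort(unname(comp)),
                                                    collapse = ","))
  }
  for (r in seq_len(n_mix6)) {
    plots[[length(plots) + 1]] <- list(
      type = "mix6", comp = paste(sort(traits$species), collapse = ","))
  }
  out <- data.frame(
    plot_id = sprintf("P%02d", seq_along(plots)),
    type = vapply(plots, `[[`, character(1), "type"),
    composition = vapply(plots, `[[`, character(1), "comp"))
  out$richness <- lengths(strsplit(out$composition, ","))
  attr(out, "n_subplots") <- 4L * nrow(out)
  class(out) <- c("experiment_design", "data.frame")
  out
}

# Quadrant of a stem position within a plot-local 45 x 45 frame.
.position_quadrant <- function(x, y, side = 45) {
  east <- x >= side / 2
  north <- y >= side / 2
  ifelse(north, ifelse(east, "NE", "NW"), ifelse(east, "SE", "SW"))
}

#' Simulate tree stands for a design
#'
#' Every plot gets a full 3 m planting grid (15 x 15 = 225 positions on a
#' 45 m side, stems at 1.5, 4.5, ..., 43.5 m in plot-local coordinates).
#' Species are assigned round-robin through the plot's composition. Sizes at
#' the first census are drawn from the species' guild distributions; growth
#' to the second census applies the species' annual rates over the census
#' interval with mild lognormal noise; mortality removes trees from the
#' second census at the configured probability. Crown geometry (ellipsoid
#' semi-axes and crown-base height at the second census) is attached per
#' tree. Deterministic given `seed`.
#'
#' @param design An `experiment_design` from [make_design()].
#' @param params A [sim_params()].
#' @param traits Species trait table.
#' @param vol A [volume_params()] supplying the census years.
#' @param seed Integer seed.
#' @return A `stand` list: `inventory` (tree records, plot-local `x_m`,
#'   `y_m` positions and crown columns `crown_base_m`, `crown_rx_m`,
#'   `crown_rz_m`), `design`, `params`, `traits`, `vol`.
#' @export
simulate_stand <- function(design, params = sim_params(),
                           traits = species_traits(),
                           vol = volume_params(), seed = 1) {
  set.seed(seed)
  span <- vol$t2 - vol$t1
  pos <- seq(1.5, 43.5, by = 3)
  grid <- expand.grid(x_m = pos, y_m = pos)
  rows <- vector("list", nrow(design))
  for (p in seq_len(nrow(design))) {
    comp <- strsplit(design$composition[p], ",")[[1]]
    n <- nrow(grid)
    sp <- comp[(seq_len(n) - 1) %% length(comp) + 1]
    tr <- traits[match(sp, traits$species), ]
    h1 <- pmax(1, stats::rnorm(n, tr$h1_mean, tr$h1_sd))
    d1 <- pmax(1, stats::rnorm(n, tr$d1_mean, tr$d1_sd))
    gnoise <- stats::rlnorm(n, 0, 0.15)
    h2 <- h1 + span * tr$h_growth * gnoise
    d2 <- d1 + span * tr$d_growth * gnoise
    alive2 <- stats::runif(n) >= params$mortality
    rows[[p]] <- data.frame(
      tree_id = sprintf("%s_T%03d", design$plot_id[p], seq_len(n)),
      plot_id = design$plot_id[p],
      subplot_id = .position_quadrant(grid$x_m, grid$y_m),
      species = sp,
      D1_cm = d1, H1_m = h1, alive_t1 = TRUE,
      D2_cm = ifelse(alive2, d2, NA_real_),
      H2_m = ifelse(alive2, h2, NA_real_),
      alive_t2 = alive2,
      x_m = grid$x_m, y_m = grid$y_m,
      crown_base_m = tr$crown_base_frac * h2,
      crown_rx_m = tr$crown_radius_frac * h2,
      crown_rz_m = (1 - tr$crown_base_frac) * h2 / 2,
      point_density = tr$point_density * params$density_scale)
  }
  structure(list(inventory = do.call(rbind, rows), design = design,
                 params = params, traits = traits, vol = vol),
            class = "stand")
}

# Uniform points inside an axis-aligned ellipsoid centred at (cx, cy, cz)
# with semi-axes (rx, rx, rz): uniform direction + cube-root radius.
.runif_ellipsoid <- function(n, cx, cy, cz, rx, rz) {
  if (!n) return(matrix(numeric(), ncol = 3))
  z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
  nrm <- sqrt(x^2 + y^2 + z^2)
  r <- stats::runif(n)^(1 / 3)
  cbind(cx + rx * r * x / nrm, cy + rx * r * y / nrm, cz + rz * r * z / nrm)
}

#' Sample a point cloud for one plot of a stand
#'
#' Each living tree's crown (vertical ellipsoid at the second census) is
#' sampled with a Poisson number of points, mean = species point density x
#' crown volume, uniformly within the ellipsoid. A sparse vertical stem
#' line below the crown base is added so the trunk is visible to the
#' voxelisation. Heights are ground-relative (z = 0 at ground); no terrain
#' or ground returns are simulated. Deterministic given `seed`.
#'
#' @param stand A `stand` from [simulate_stand()].
#' @param plot_id Plot to sample.
#' @param seed Integer seed.
#' @param stem_points Points per metre of stem below the crown base
#'   (default 10; 0 disables stems).
#' @return A [point_cloud()] in plot-local coordinates (origin at the
#'   plot's lower-left corner).
#' @export
sample_point_cloud <- function(stand, plot_id, seed = 1, stem_points = 10) {
  set.seed(seed)
  inv <- stand$inventory
  trees <- inv[inv$plot_id == plot_id & inv$alive_t2, , drop = FALSE]
  if (!nrow(trees)) return(point_cloud(source_id = plot_id))
  vol_crown <- 4 / 3 * pi * trees$crown_rx_m^2 * trees$crown_rz_m
  n_pts <- stats::rpois(nrow(trees), trees$point_density * vol_crown)
  parts <- vector("list", nrow(trees))
  for (i in seq_len(nrow(trees))) {
    cz <- trees$crown_base_m[i] + trees$crown_rz_m[i]
    crown <- .runif_ellipsoid(n_pts[i], trees$x_m[i], trees$y_m[i], cz,
                              trees$crown_rx_m[i], trees$crown_rz_m[i])
    stem <- NULL
    if (stem_points > 0 && trees$crown_base_m[i] > 0) {
      ns <- max(1L, round(stem_points * trees$crown_base_m[i]))
      stem <- cbind(trees$x_m[i], trees$y_m[i],
                    stats::runif(ns, 0, trees$crown_base_m[i]))
    }
    parts[[i]] <- rbind(crown, stem)
  }
  m <- do.call(rbind, parts)
  point_cloud(m[, 1], m[, 2], m[, 3], source_id = plot_id)
}

#' Simulate per-subplot CSFI values for a design
#'
#' Draws one CSFI value per subplot from a beta distribution centred near
#' 0.33 (the magnitude a young, densely planted stand exhibits under the
#' total-canopy delineation), optionally spreading one mixture type's values
#' more than the other's around the common centre. This is the driver
#' variable of the generative AWP mode; the mechanistic pipeline computes
#' CSFI from point clouds instead.
#'
#' @param design An `experiment_design`.
#' @param seed Integer seed.
#' @param spread Named numeric: SD multipliers around the centre for
#'   `monoculture` and `mixture` subplots (default both 1).
#' @return Data frame: `plot_id`, `subplot_id`, `mixture_type`, `csfi`.
#' @export
simulate_csfi_table <- function(design, seed = 1,
                                spread = c(monoculture = 1, mixture = 1)) {
  set.seed(seed)
  quads <- c("SW", "SE", "NW", "NE")
  out <- data.frame(
    plot_id = rep(design$plot_id, each = 4),
    subplot_id = rep(quads, nrow(design)),
    mixture_type = rep(ifelse(design$richness == 1, "monoculture",
                              "mixture"), each = 4))
  centre <- 2.5 / (2.5 + 5)  # beta(2.5, 5) mean
  base <- stats::rbeta(nrow(out), 2.5, 5)
  s <- spread[out$mixture_type]
  out$csfi <- pmin(0.99, pmax(0.01, centre + s * (base - centre)))
  out
}

#' Generate AWP from CSFI through the gamma log-link model
#'
#' The generative mode: draws subplot AWP from
#' `Gamma(shape, mean = exp(beta0 + beta1*CSFI + beta2*mix + beta3*CSFI*mix
#' + b_plot))` with plot random intercepts `b_plot ~ N(0, sd_plot^2)`.
#' Ground truth (all parameters and the realised intercepts) is attached for
#' recovery tests.
#'
#' @param csfi_table Data frame with `plot_id`, `subplot_id`,
#'   `mixture_type`, `csfi` (one row per subplot).
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return The input table with an `awp` column (cm^3/yr) and a
#'   `ground_truth` attribute (params plus per-plot intercepts).
#' @export
generate_awp <- function(csfi_table, params = sim_params(), seed = 1) {
  set.seed(seed)
  plots <- unique(csfi_table$plot_id)
  b <- stats::rnorm(length(plots), 0, params$sd_plot)
  names(b) <- plots
  mix <- as.numeric(csfi_table$mixture_type == "mixture")
  eta <- params$beta0 + params$beta1 * csfi_table$csfi + params$beta2 * mix +
    params$beta3 * csfi_table$csfi * mix + b[csfi_table$plot_id]
  mu <- exp(eta)
  out <- csfi_table
  out$awp <- stats::rgamma(nrow(out), shape = params$shape,
                           rate = params$shape / mu)
  attr(out, "ground_truth") <- list(params = params, b_plot = b)
  out
}
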