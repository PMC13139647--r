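test_that("the default design reproduces the 22-plot, 88-subplot layout", {
  des <- make_design(seed = 1)
  expect_equal(nrow(des), 22)
  expect_equal(attr(des, "n_subplots"), 88L)
  expect_equal(sum(des$type == "mono"), 10)  # 2 per species, one excluded
  expect_equal(sum(des$type == "mix3"), 6)
  expect_equal(sum(des$type == "mix6"), 6)

  full <- make_design(exclude = character(), seed = 1)
  expect_equal(nrow(full), 24)
  expect_equal(attr(full, "n_subplots"), 96L)
})

test_that("designs are deterministic under a seed and vary across seeds", {
  expect_identical(make_design(seed = 5), make_design(seed = 5))
  a <- make_design(seed = 5); b <- make_design(seed = 6)
  expect_false(identical(a$composition, b$composition))
})

test_that("every three-species mixture holds one species per guild", {
  traits <- species_traits()
  for (s in 1:5) {
    des <- make_design(seed = s)
    mix3 <- des[des$type == "mix3", ]
    for (comp in strsplit(mix3$composition, ",")) {
      guilds <- traits$guild[match(comp, traits$species)]
      expect_equal(sort(guilds), c("intermediate", "pioneer", "shade"))
    }
  }
})

test_that("stands plant the full 3 m grid and respect mortality settings", {
  des <- make_design(n_mono_per_species = 1, n_mix3 = 1, n_mix6 = 1,
                     exclude = character(), seed = 2)
  stand <- simulate_stand(des, sim_params(mortality = 0), seed = 3)
  inv <- stand$inventory
  expect_equal(sum(inv$plot_id == des$plot_id[1]), 225)  # 15 x 15
  expect_true(all(inv$alive_t2))
  expect_equal(sort(unique(inv$subplot_id)), c("NE", "NW", "SE", "SW"))
  # composition respected: monoculture plots carry one species
  mono <- des$plot_id[des$type == "mono"][1]
  expect_equal(unique(inv$species[inv$plot_id == mono]),
               des$composition[des$type == "mono"][1])

  lethal <- simulate_stand(des, sim_params(mortality = 1), seed = 3)
  expect_false(any(lethal$inventory$alive_t2))
})

test_that("zero growth rates close the loop to zero AWP via productivity", {
  des <- make_design(n_mono_per_species = 1, n_mix3 = 0, n_mix6 = 0,
                     exclude = character(), seed = 4)
  traits <- species_traits()
  traits$h_growth <- 0; traits$d_growth <- 0
  stand <- simulate_stand(des, sim_params(mortality = 0), traits = traits,
                          seed = 5)
  tab <- awp_table(validate_inventory(stand$inventory))
  expect_true(all(abs(tab$awp_cm3_yr) < 1e-9))
  expect_true(all(tab$n_trees > 0))
})

test_that("point clouds are Poisson-sized and contained in their crowns", {
  des <- make_design(n_mono_per_species = 1, n_mix3 = 0, n_mix6 = 0,
                     exclude = setdiff(species_traits()$species, "PIO1"),
                     seed = 6)
  stand <- simulate_stand(des, sim_params(mortality = 0), seed = 7)
  pid <- des$plot_id[1]
  cloud <- sample_point_cloud(stand, pid, seed = 8, stem_points = 0)
  trees <- stand$inventory[stand$inventory$plot_id == pid, ]
  vol <- 4 / 3 * pi * trees$crown_rx_m^2 * trees$crown_rz_m
  expected <- sum(trees$point_density * vol)
  # Poisson total: within 4 SD
  expect_lt(abs(nrow(cloud) - expected), 4 * sqrt(expected))

  # containment: every point inside at least one crown ellipsoid
  inside_any <- rep(FALSE, nrow(cloud))
  for (t in seq_len(nrow(trees))) {
    cz <- trees$crown_base_m[t] + trees$crown_rz_m[t]
    d2 <- ((cloud$x - trees$x_m[t]) / trees$crown_rx_m[t])^2 +
      ((cloud$y - trees$y_m[t]) / trees$crown_rx_m[t])^2 +
      ((cloud$z - cz) / trees$crown_rz_m[t])^2
    inside_any <- inside_any | d2 <= 1 + 1e-9
  }
  expect_true(all(inside_any))
  expect_true(all(cloud$z >= 0))
})

test_that("cloud sampling is deterministic under a seed", {
  des <- make_design(n_mono_per_species = 1, n_mix3 = 1, n_mix6 = 0,
                     exclude = character(), seed = 9)
  stand <- simulate_stand(des, seed = 10)
  a <- sample_point_cloud(stand, des$plot_id[1], seed = 11)
  b <- sample_point_cloud(stand, des$plot_id[1], seed = 11)
  expect_identical(a$x, b$x)
  c <- sample_point_cloud(stand, des$plot_id[1], seed = 12)
  expect_false(identical(a$x, c$x))
})

test_that("raising the crown base raises the detected lowest green branch", {
  des <- make_design(n_mono_per_species = 1, n_mix3 = 0, n_mix6 = 0,
                     exclude = setdiff(species_traits()$species, "INT1"),
                     seed = 13)
  geom <- plot_geometry()
  lgb_at <- function(frac) {
    traits <- species_traits()
    traits$crown_base_frac <- frac
    stand <- simulate_stand(des, sim_params(mortality = 0), traits = traits,
                            seed = 14)
    cloud <- sample_point_cloud(stand, des$plot_id[1], seed = 15,
                                stem_points = 0)
    sub <- split_subplots(clip_buffer(cloud, geom), geom)$SW
    grid <- voxelize(sub, grid_for_footprint(subplot_footprint(geom, "SW"),
                                             max_z = max(sub$z)))
    detect_bounds(grid)$lgb
  }
  lgbs <- vapply(c(0.2, 0.4, 0.6), lgb_at, numeric(1))
  expect_true(all(diff(lgbs) > 0))
})

test_that("generative AWP obeys the null model and concentrates as shape grows", {
  des <- make_design(n_mono_per_species = 20, n_mix3 = 30, n_mix6 = 30,
                     seed = 16)  # large n for moment checks
  csfi <- simulate_csfi_table(des, seed = 17)
  p0 <- sim_params(beta0 = 10, beta1 = 0, sd_plot = 0, shape = 5)
  awp <- generate_awp(csfi, p0, seed = 18)
  expect_lt(abs(mean(awp$awp) - exp(10)) / exp(10), 0.05)

  pbig <- sim_params(beta0 = 10, beta1 = 0, sd_plot = 0, shape = 5000)
  awp2 <- generate_awp(csfi, pbig, seed = 19)
  cv <- sd(awp2$awp) / mean(awp2$awp)
  expect_lt(cv, 0.02)
  gt <- attr(awp2, "ground_truth")
  expect_equal(gt$params$shape, 5000)
  expect_equal(length(gt$b_plot), nrow(des))
})

test_that("the mixture-spread knob widens mixture CSFI only", {
  des <- make_design(seed = 20)
  t1 <- simulate_csfi_table(des, seed = 21)
  t2 <- simulate_csfi_table(des, seed = 21,
                            spread = c(monoculture = 1, mixture = 2))
  mono <- t1$mixture_type == "monoculture"
  expect_equal(t1$csfi[mono], t2$csfi[mono])
  expect_gt(sd(t2$csfi[!mono]), sd(t1$csfi[!mono]))
})
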