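test_that("boundary heights on the reference grid match the brute-force scan", {
  g <- make_reference_grid()
  b <- detect_bounds(g, lgb_override = 0)
  expect_equal(b$h_max, 4.0)
  expect_equal(b$h10, 2.0)
  expect_equal(b$lgb, 0)

  # single occupied voxel in the top layer: 0.01 < 0.10 everywhere -> h10 NA
  counts <- array(0L, c(10, 10, 5)); counts[1, 1, 5] <- 1L
  sparse <- voxel_grid_from_counts(counts, edge = 0.4)
  bs <- detect_bounds(sparse, lgb_override = 0)
  expect_true(is.na(bs$h10))
  expect_equal(bs$h_max, 2.0)

  # all layers full: h10 = h_max = top of grid, grid-derived lgb = 0... but
  # the ground-exclusion pushes the grid-derived LGB to the first layer
  # bottom at or above 0.3 m
  full <- voxel_grid_from_counts(array(1L, c(4, 4, 6)), edge = 0.4)
  bf <- detect_bounds(full, lgb_override = 0)
  expect_equal(bf$h_max, 2.4)
  expect_equal(bf$h10, 2.4)
  expect_equal(bf$lgb, 0)
  bf2 <- detect_bounds(full)  # grid-derived: lowest layer bottom >= 0.3 m
  expect_equal(bf2$lgb, 0.4)

  empty <- voxel_grid_from_counts(array(0L, c(3, 3, 3)))
  expect_error(detect_bounds(empty), "empty canopy")
})

test_that("the four definitions produce the expected slabs and flags", {
  g <- make_reference_grid()
  b <- detect_bounds(g, lgb_override = 0)
  expect_equal(slab_for_definition(b, "total")[c("z_lo", "z_hi")],
               list(z_lo = 0, z_hi = 4.0))
  top <- slab_for_definition(b, "top")
  expect_equal(top$z_lo, 8 / 3, tolerance = 1e-12)
  expect_equal(top$z_hi, 4.0)
  mid <- slab_for_definition(b, "mid")
  expect_equal(mid$z_lo, 4 / 3, tolerance = 1e-12)
  expect_equal(mid$z_hi, 2.0)
  expect_equal(slab_for_definition(b, "main")[c("z_lo", "z_hi")],
               list(z_lo = 0, z_hi = 2.0))

  # inverted bounds -> flagged invalid
  binv <- structure(list(h_max = 3, lgb = 0, h10 = 0.9, tau = 0.1),
                    class = "canopy_bounds")
  expect_false(slab_for_definition(binv, "mid")$valid)
  expect_match(slab_for_definition(binv, "mid")$reason, "empty slab")
  bna <- structure(list(h_max = 3, lgb = 0, h10 = NA_real_, tau = 0.1),
                   class = "canopy_bounds")
  expect_match(slab_for_definition(bna, "main")$reason, "h10 undefined")
})

test_that("CSFI on the reference grid matches brute-force voxel counts", {
  g <- make_reference_grid()
  tab <- csfi_all_definitions(g, lgb_override = 0)
  expect_equal(tab$csfi[tab$definition == "total"], 0.525)
  expect_equal(tab$csfi[tab$definition == "top"], 0.05)
  expect_equal(tab$csfi[tab$definition == "mid"], 1.0)
  expect_equal(tab$csfi[tab$definition == "main"], 1.0)
  # cross-check every slab against the independent cell-by-cell count
  for (r in seq_len(nrow(tab))) {
    oracle <- brute_force_slab_count(g, tab$z_lo[r], tab$z_hi[r])
    expect_equal(tab$occupied[r], oracle$occupied)
    expect_equal(tab$total[r], oracle$total)
  }
  # qualitative ordering of the definitions on this profile
  v <- setNames(tab$csfi, tab$definition)
  expect_true(v["mid"] >= v["main"] && v["main"] >= v["total"] &&
                v["total"] >= v["top"])
})

test_that("definitions coincide when their boundaries coincide", {
  # lgb = 0 and h10 = h_max makes total and main identical slabs
  full <- voxel_grid_from_counts(array(1L, c(5, 5, 4)), edge = 0.5)
  tab <- csfi_all_definitions(full, lgb_override = 0)
  expect_equal(tab$csfi[tab$definition == "total"],
               tab$csfi[tab$definition == "main"])
})

test_that("CSFI over a union of layer ranges is the voxel-weighted mean", {
  set.seed(21)
  for (rep in 1:20) {
    g <- random_grid(nz = 10, p_occupied = runif(1, 0.1, 0.9))
    cut <- sample(2:9, 1)
    a <- occupied_in_slab(g, 1:cut)
    b <- occupied_in_slab(g, (cut + 1):10)
    whole <- occupied_in_slab(g, 1:10)
    weighted <- (a$occupied / a$total * a$total +
                   b$occupied / b$total * b$total) / (a$total + b$total)
    expect_equal(whole$occupied / whole$total, weighted, tolerance = 1e-12)
  }
})

test_that("total slab contains the main slab and dominates its occupied count", {
  set.seed(22)
  for (rep in 1:20) {
    g <- random_grid(nz = 12, p_occupied = runif(1, 0.15, 0.7))
    b <- detect_bounds(g, lgb_override = 0)
    if (is.na(b$h10)) next
    total <- csfi(g, slab_for_definition(b, "total"))
    main <- csfi(g, slab_for_definition(b, "main"))
    if (!total$valid || !main$valid) next
    expect_lte(main$z_hi, total$z_hi)
    expect_gte(total$occupied, main$occupied)
  }
})

test_that("CSFI is invariant under uniform rescaling of heights and edge", {
  g <- make_reference_grid()
  g2 <- voxel_grid_from_counts(g$counts, edge = g$spec$edge * 3.7)
  t1 <- csfi_all_definitions(g, lgb_override = 0)
  t2 <- csfi_all_definitions(g2, lgb_override = 0)
  expect_equal(t1$csfi, t2$csfi)
})

test_that("pairwise CSFI correlations match a from-scratch computation", {
  set.seed(23)
  batch <- lapply(1:50, function(i) {
    g <- random_grid(nz = 10, p_occupied = runif(1, 0.15, 0.8))
    cbind(subplot = sprintf("s%02d", i),
          csfi_all_definitions(g, lgb_override = 0))
  })
  tab <- do.call(rbind, batch)
  r <- csfi_correlations(tab)
  expect_equal(dim(r), c(4, 4))
  expect_equal(diag(r), setNames(rep(1, 4), CANOPY_DEFINITIONS))
  expect_equal(r, t(r))
  # oracle: covariance / sd products computed by hand on the wide matrix
  wide <- sapply(CANOPY_DEFINITIONS, function(d) {
    x <- tab[tab$definition == d, ]
    x$csfi[order(x$subplot)]
  })
  ok <- stats::complete.cases(wide)
  wide <- wide[ok, ]
  for (i in 1:4) for (j in 1:4) {
    xi <- wide[, i]; xj <- wide[, j]
    num <- mean((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(mean((xi - mean(xi))^2) * mean((xj - mean(xj))^2))
    expect_equal(unname(r[i, j]), num / den, tolerance = 1e-12)
  }
})

test_that("correlations are omitted with a warning below two complete subplots", {
  g <- make_reference_grid()
  tab <- cbind(subplot = "only", csfi_all_definitions(g, lgb_override = 0))
  expect_warning(out <- csfi_correlations(tab), "fewer than 2")
  expect_null(out)
})

test_that("identical CSFI across definitions yields unit correlations", {
  set.seed(24)
  tab <- do.call(rbind, lapply(1:10, function(i) {
    v <- runif(1, 0.2, 0.8)
    data.frame(subplot = sprintf("s%d", i), definition = CANOPY_DEFINITIONS,
               csfi = v, valid = TRUE)
  }))
  r <- csfi_correlations(tab)
  expect_equal(unname(r), matrix(1, 4, 4))
})
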