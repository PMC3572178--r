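test_that("units are urban iff they touch the urban extent", {
  tg <- two_unit_grid(2)
  zones <- rasterize_zones(tg$units, tg$grid)
  empty <- cat_raster(tg$grid, rep(0L, 4), legend = c(`0` = "n", `1` = "y"))
  f0 <- classify_units_urban_rural(zones, empty)
  expect_false(any(f0$urban_flag))

  # exactly one cell of u1 (left column) inside the extent
  one <- cat_raster(tg$grid, c(1, 0, 0, 0), legend = c(`0` = "n", `1` = "y"))
  f1 <- classify_units_urban_rural(zones, one)
  expect_true(f1$urban_flag[f1$unit_id == "u1"])
  expect_false(f1$urban_flag[f1$unit_id == "u2"])
})

test_that("growth projection follows the compound formula with exact identities", {
  cs <- census_table("u", 1000, 2005L, urban_flag = FALSE)
  out <- project_population(cs, list(r_urban = 0.05, r_rural = 0.02,
                                     target_year = 2010))
  expect_equal(out$population, 1000 * 1.02^5, tolerance = 1e-12)
  expect_equal(out$population, 1104.0808, tolerance = 1e-4)

  same <- project_population(cs, list(r_urban = 0.05, r_rural = 0.02,
                                      target_year = 2005))
  expect_identical(same$population, cs$population)

  flat <- project_population(cs, list(r_urban = 0, r_rural = 0,
                                      target_year = 2030))
  expect_identical(flat$population, cs$population)

  urb <- census_table("u", 1000, 2005L, urban_flag = TRUE)
  out_u <- project_population(urb, list(r_urban = 0.05, r_rural = 0.02,
                                        target_year = 2010))
  expect_equal(out_u$population, 1000 * 1.05^5)

  expect_error(project_population(cs, list(r_urban = -1.5, r_rural = 0,
                                           target_year = 2010)), "-1")
  expect_error(project_population(census_table("u", 5, 2005L), list(
    r_urban = 0, r_rural = 0, target_year = 2010
  )), "urban_flag")
})

test_that("dasymetric redistribution matches the hand-evaluated formula", {
  # one unit of 4 cells: 3 x class A (w = 1), 1 x class B (w = 7), T = 100
  g <- grid_spec(2, 2)
  units <- admin_units("u", 1L, geometry = list(rect_geom(0, 2, 0, 2)))
  zones <- rasterize_zones(units, g)
  lc <- cat_raster(g, c(1, 1, 1, 2), legend = c(`1` = "A", `2` = "B"))
  climate <- cat_raster(g, rep(1L, 4))
  w <- popweave:::new_weight_table(tibble::tibble(
    climate_zone = 1L, land_cover = c(1L, 2L), weight = c(1, 7),
    n_units = NA_integer_, residual = NA_real_
  ))
  census <- census_table("u", 100, 2010L)
  pop <- dasymetric_redistribute(census, zones, lc, climate, w)
  expect_equal(as.vector(t(pop$values)), c(10, 10, 10, 70))

  # all weight mass on one class: population lands only there
  w2 <- popweave:::new_weight_table(tibble::tibble(
    climate_zone = 1L, land_cover = c(1L, 2L), weight = c(0, 5),
    n_units = NA_integer_, residual = NA_real_
  ))
  lc2 <- cat_raster(g, c(2, 1, 1, 2), legend = c(`1` = "A", `2` = "B"))
  pop2 <- dasymetric_redistribute(census_table("u", 50, 2010L),
                                  zones, lc2, climate, w2)
  expect_equal(as.vector(t(pop2$values)), c(25, 0, 0, 25))
})

test_that("degenerate zero-weight units fall back to uniform spread", {
  g <- grid_spec(2, 2)
  units <- admin_units("u", 1L, geometry = list(rect_geom(0, 2, 0, 2)))
  zones <- rasterize_zones(units, g)
  lc <- cat_raster(g, rep(1L, 4), legend = c(`1` = "A"))
  climate <- cat_raster(g, rep(1L, 4))
  w0 <- popweave:::new_weight_table(tibble::tibble(
    climate_zone = 1L, land_cover = 1L, weight = 0,
    n_units = NA_integer_, residual = NA_real_
  ))
  pop <- dasymetric_redistribute(census_table("u", 40, 2010L),
                                 zones, lc, climate, w0)
  expect_equal(as.vector(pop$values), rep(10, 4))
  expect_equal(attr(pop, "degenerate_units"), "u")
})

test_that("areal weighting divides each unit's count evenly", {
  g <- grid_spec(2, 2)
  units <- admin_units("u", 1L, geometry = list(rect_geom(0, 2, 0, 2)))
  zones <- rasterize_zones(units, g)
  pop <- areal_redistribute(census_table("u", 100, 2010L), zones)
  expect_equal(as.vector(pop$values), rep(25, 4))

  # two units, 1 and 3 cells
  g2 <- grid_spec(1, 4)
  u2 <- admin_units(c("a", "b"), 1L, geometry = list(
    rect_geom(0, 1, 0, 1), rect_geom(1, 4, 0, 1)
  ))
  z2 <- rasterize_zones(u2, g2)
  p2 <- areal_redistribute(census_table(c("a", "b"), c(10, 30), 2010L), z2)
  expect_equal(as.vector(p2$values), c(10, 10, 10, 10))

  p0 <- areal_redistribute(census_table("u", 0, 2010L), zones)
  expect_true(all(p0$values == 0))
})

test_that("grump-style concentration splits mass by the urban share", {
  # unit with 2 urban + 8 rural cells, T = 100, share = 0.6
  g <- grid_spec(2, 5)
  units <- admin_units("u", 1L, geometry = list(rect_geom(0, 5, 0, 2)))
  zones <- rasterize_zones(units, g)
  urb <- cat_raster(g, c(1, 1, rep(0, 8)), legend = c(`0` = "n", `1` = "y"))
  census <- census_table("u", 100, 2010L)
  pop <- grump_redistribute(census, zones, urb, urban_share = 0.6)
  v <- as.vector(t(pop$values))
  expect_equal(v[1:2], c(30, 30))
  expect_equal(v[3:10], rep(5, 8))

  # share 0 moves all mass off the urban cells
  p0 <- grump_redistribute(census, zones, urb, urban_share = 0)
  v0 <- as.vector(t(p0$values))
  expect_equal(v0[1:2], c(0, 0))
  expect_equal(v0[3:10], rep(100 / 8, 8))

  # with no urban cells anywhere, any share reduces to areal weighting
  pa <- areal_redistribute(census, zones)
  noturb <- cat_raster(g, rep(0L, 10), legend = c(`0` = "n", `1` = "y"))
  pe <- grump_redistribute(census, zones, noturb, urban_share = 0.7)
  expect_equal(pe$values, pa$values, tolerance = 1e-12)

  # share 1 with a single urban cell puts everything there
  urb1 <- cat_raster(g, c(1, rep(0, 9)), legend = c(`0` = "n", `1` = "y"))
  p1 <- grump_redistribute(census_table("u", 40, 2010L), zones, urb1, 1)
  expect_equal(as.vector(t(p1$values)), c(40, rep(0, 9)))

  # all-urban unit receives everything uniformly on its (urban) cells
  urball <- cat_raster(g, rep(1L, 10), legend = c(`0` = "n", `1` = "y"))
  pall <- grump_redistribute(census, zones, urball, 0.6)
  expect_equal(as.vector(pall$values), rep(10, 10))
})

test_that("national-total adjustment scales uniformly and hits the target", {
  g <- grid_spec(1, 3)
  pop <- value_raster(g, c(10, 20, 30))
  out <- adjust_to_national_total(pop, 120)
  expect_equal(as.vector(out$values), c(20, 40, 60))
  expect_equal(sum(out$values), 120, tolerance = 1e-12)
  ident <- adjust_to_national_total(pop, 60)
  expect_equal(ident$values, pop$values, tolerance = 1e-12)
  expect_error(adjust_to_national_total(value_raster(g, c(0, 0, 0)), 5), "zero")
})

test_that("every method conserves per-unit mass and nonnegativity on synthetic scenarios", {
  for (seed in c(2, 12)) {
    s <- synthetic_scenario(seed = seed, n_rows = 40, n_cols = 40)
    b <- generate_bundle(s)
    fine <- b$units[b$units$level == 2, ]
    zones <- rasterize_zones(fine, s$grid)
    rasters <- list(
      dasymetric_redistribute(b$census, zones, b$lc, b$climate, s$true_weights),
      areal_redistribute(b$census, zones),
      grump_redistribute(b$census, zones, b$urban_extent, 0.5)
    )
    for (pop in rasters) {
      expect_true(all(pop$values >= 0, na.rm = TRUE))
      sums <- evaluate(pop, zones, b$census)
      rel <- abs(sums$estimated - sums$observed) / pmax(sums$observed, 1)
      expect_lt(max(rel), 1e-9)
    }
    # GPW uniformity: within-unit max - min is exactly zero
    gpw <- rasters[[2]]
    zv <- as.vector(t(zones$values))
    pv <- as.vector(t(gpw$values))
    ok <- zv != s$grid$nodata_code
    rng <- tapply(pv[ok], zv[ok], function(x) max(x) - min(x))
    expect_true(all(rng == 0))
  }
})

test_that("constant weights collapse dasymetric and grump onto areal weighting", {
  s <- synthetic_scenario(seed = 4, n_rows = 32, n_cols = 32)
  b <- generate_bundle(s)
  zones <- rasterize_zones(b$units[b$units$level == 2, ], s$grid)
  wconst <- default_true_weights(classes = s$classes, n_zones = s$n_zones,
                                 base = stats::setNames(rep(2, 9), 1:9),
                                 zone_mult = 1)
  pd <- dasymetric_redistribute(b$census, zones, b$lc, b$climate, wconst)
  pa <- areal_redistribute(b$census, zones)
  expect_equal(pd$values, pa$values, tolerance = 1e-12)

  # grump with each unit's share set to its urban cell fraction is areal
  zt <- zonal_tabulate(zones, b$urban_extent)
  frac <- tidyr::pivot_wider(tibble::as_tibble(zt), names_from = "class",
                             values_from = "n", values_fill = 0L)
  shares <- stats::setNames(frac$`1` / (frac$`1` + frac$`0`), frac$unit_id)
  pg <- grump_redistribute(b$census, zones, b$urban_extent, shares)
  expect_equal(pg$values, pa$values, tolerance = 1e-12)

  # and an all-urban extent with share 1 is the degenerate case of the same
  urball <- cat_raster(s$grid, rep(1L, 32 * 32), legend = c(`0` = "n", `1` = "y"))
  pg1 <- grump_redistribute(b$census, zones, urball, 1)
  expect_equal(pg1$values, pa$values, tolerance = 1e-12)
})

test_that("projection and redistribution commute unit-wise", {
  s <- synthetic_scenario(seed = 6, n_rows = 32, n_cols = 32)
  b <- generate_bundle(s)
  zones <- rasterize_zones(b$units[b$units$level == 2, ], s$grid)
  flags <- classify_units_urban_rural(zones, b$urban_extent)
  census <- b$census
  census$urban_flag <- flags$urban_flag[match(census$unit_id, flags$unit_id)]
  growth <- list(r_urban = 0.04, r_rural = 0.01, target_year = 2015)

  before <- dasymetric_redistribute(project_population(census, growth),
                                    zones, b$lc, b$climate, s$true_weights)
  base <- dasymetric_redistribute(census, zones, b$lc, b$climate, s$true_weights)
  fac <- ifelse(census$urban_flag, 1.04, 1.01)^5
  names(fac) <- census$unit_id
  zv <- as.vector(t(zones$values))
  ok <- zv != s$grid$nodata_code
  uid <- unname(zones$legend[as.character(zv[ok])])
  scaled <- as.vector(t(base$values))
  scaled[ok] <- scaled[ok] * fac[uid]
  expect_equal(as.vector(t(before$values)), scaled, tolerance = 1e-12)
})

test_that("largest-remainder integerization preserves integer unit totals", {
  g <- grid_spec(2, 3)
  units <- admin_units("u", 1L, geometry = list(rect_geom(0, 3, 0, 2)))
  zones <- rasterize_zones(units, g)
  pop <- areal_redistribute(census_table("u", 100, 2010L), zones)
  ints <- integerize_population(pop, zones)
  expect_true(all(ints$values == floor(ints$values)))
  expect_equal(sum(ints$values), 100)
  expect_lte(max(ints$values) - min(ints$values), 1)
})
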