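test_that("aggregate_units sums children into parents", {
  geo <- function(i) rect_geom(i - 1, i, 0, 1)
  units <- admin_units(
    unit_id = c("p1", "p2", "p3", paste0("c", 1:12)),
    level = c(rep(1L, 3), rep(2L, 12)),
    parent_id = c(rep(NA, 3), rep(c("p1", "p2", "p3"), each = 4)),
    geometry = c(lapply(c(1, 5, 9), function(i) rect_geom(i - 1, i + 3, 0, 1)),
                 lapply(1:12, geo))
  )
  fine <- census_table(paste0("c", 1:12), rep(5, 12), 2010L)
  agg <- aggregate_units(fine, units)
  expect_equal(sort(agg$census$unit_id), c("p1", "p2", "p3"))
  expect_equal(agg$census$population, rep(20, 3))
  expect_equal(agg$units$area, rep(4, 3), ignore_attr = TRUE)

  two <- census_table(c("c1", "c2"), c(10, 20), 2010L)
  units2 <- units[units$unit_id %in% c("p1", "c1", "c2"), ]
  agg2 <- aggregate_units(two, units2)
  expect_equal(agg2$census$population, 30)

  single <- census_table("c1", 10, 2010L)
  agg1 <- aggregate_units(single, units[units$unit_id %in% c("p1", "c1"), ])
  expect_equal(agg1$census$population, 10)

  orphan <- admin_units("x", 2L, parent_id = NA_character_,
                        geometry = list(rect_geom(0, 1, 0, 1)))
  expect_error(aggregate_units(census_table("x", 1, 2010L), orphan), "parent")
})

test_that("evaluating a model at its own level returns the census exactly", {
  s <- synthetic_scenario(seed = 8, n_rows = 32, n_cols = 32)
  b <- generate_bundle(s)
  zones <- rasterize_zones(b$units[b$units$level == 2, ], s$grid)
  pop <- dasymetric_redistribute(b$census, zones, b$lc, b$climate, s$true_weights)
  pairs <- evaluate(pop, zones, b$census, method = "self")
  expect_equal(pairs$estimated, pairs$observed, tolerance = 1e-9)
})

test_that("GPW at the coarse level is exact for uniform truth on equal-area children", {
  # uniform true density: every cell w persons; coarse areal spread then
  # re-summing over equal-size children reproduces each child's count
  s <- synthetic_scenario(
    seed = 9, n_rows = 32, n_cols = 32,
    true_weights = default_true_weights(base = stats::setNames(rep(2, 9), 1:9),
                                        zone_mult = 1)
  )
  b <- generate_bundle(s)
  fine_zones <- rasterize_zones(b$units[b$units$level == 2, ], s$grid)
  agg <- aggregate_units(b$census, b$units)
  coarse_zones <- rasterize_zones(agg$units, s$grid)
  gpw <- areal_redistribute(agg$census, coarse_zones)
  pairs <- evaluate(gpw, fine_zones, b$census, method = "gpw")
  expect_equal(pairs$estimated, pairs$observed, tolerance = 1e-9)
})

test_that("error metrics reproduce the hand-computed fixture", {
  pairs <- tibble::tibble(
    unit_id = c("a", "b", "c"),
    observed = c(100, 200, 300), estimated = c(110, 190, 330),
    method = "demo"
  )
  m <- error_metrics(pairs)
  expect_equal(m$rmse, 19.1485, tolerance = 1e-4)
  expect_equal(m$mae, 16.6667, tolerance = 1e-4)
  expect_equal(m$pct_rmse, 9.5743, tolerance = 1e-4)

  perfect <- pairs
  perfect$estimated <- perfect$observed
  mp <- error_metrics(perfect)
  expect_equal(mp$rmse, 0)
  expect_equal(mp$mae, 0)
  expect_equal(mp$pearson_r, 1)

  linear <- tibble::tibble(unit_id = c("a", "b", "c"), observed = c(1, 2, 3),
                           estimated = c(2, 4, 6), method = "demo")
  expect_equal(error_metrics(linear)$pearson_r, 1)

  const <- tibble::tibble(unit_id = c("a", "b"), observed = c(1, 2),
                          estimated = c(5, 5), method = "demo")
  expect_true(is.na(error_metrics(const)$pearson_r))
})

test_that("error metrics are stable at census-scale magnitudes and RMSE >= MAE", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    obs <- stats::runif(n, 0, 1e9)
    est <- obs + stats::rnorm(n, 0, 1e5)
    m <- error_metrics(tibble::tibble(unit_id = as.character(1:n),
                                      observed = obs, estimated = pmax(est, 0),
                                      method = "x"))
    expect_gte(m$rmse, m$mae)
    expect_true(is.finite(m$rmse) && m$rmse < 1e7)
  }
})

test_that("Kruskal-Wallis comparison matches hand and brute-force rank computations", {
  res <- compare_methods(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(res$h, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2)

  ident <- compare_methods(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(ident$h, 0)
  expect_equal(ident$p_value, 1)
  expect_false(any(ident$pairwise$significant))

  # exhaustive check against the definitional rank statistic on small inputs,
  # with ties, across group-size splits of total size <= 8
  set.seed(77)
  for (rep in 1:40) {
    k <- sample(2:3, 1)
    sizes <- sample(2:3, k, replace = TRUE)
    while (sum(sizes) > 8) sizes <- sample(2:3, k, replace = TRUE)
    groups <- lapply(sizes, function(n) sample(1:4, n, replace = TRUE))
    names(groups) <- paste0("g", seq_len(k))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(compare_methods(groups)$h, brute_kw_h(groups),
                 tolerance = 1e-12)
  }

  expect_error(compare_methods(list(a = 1:3)), "2 groups")
  expect_error(compare_methods(list(a = 1, b = 1:2)), "2 ")
})

test_that("post-hoc pairwise procedure separates shifted groups but not identical ones", {
  set.seed(3)
  lo <- stats::runif(30, 0, 1)
  hi <- stats::runif(30, 10, 11)
  res <- compare_methods(list(low1 = lo, low2 = lo + stats::runif(30, 0, 0.1),
                              high = hi))
  pw <- res$pairwise
  expect_true(pw$significant[pw$method_a == "low1" & pw$method_b == "high"])
  expect_true(pw$significant[pw$method_a == "low2" & pw$method_b == "high"])
  expect_false(pw$significant[pw$method_a == "low1" & pw$method_b == "low2"])
})

test_that("error rasters fill each unit with its signed error", {
  tg <- two_unit_grid(2)
  zones <- rasterize_zones(tg$units, tg$grid)
  pairs <- tibble::tibble(unit_id = c("u1", "u2"), observed = c(10, 10),
                          estimated = c(15, 7), method = "m")
  er <- error_raster(pairs, zones)
  v <- as.vector(t(er$values))
  uid <- unname(zones$legend[as.character(as.vector(t(zones$values)))])
  expect_true(all(v[uid == "u1"] == 5))
  expect_true(all(v[uid == "u2"] == -3))

  zero <- pairs; zero$estimated <- zero$observed
  expect_true(all(error_raster(zero, zones)$values == 0))

  expect_error(error_raster(pairs[1, ], zones), "missing")
})

test_that("the dasymetric method outranks the baselines on class-driven landscapes", {
  wins <- purrr::map_lgl(1:20, function(seed) {
    s <- synthetic_scenario(seed = 100 + seed, n_rows = 40, n_cols = 40,
                            noise_model = "poisson")
    b <- generate_bundle(s)
    res <- assess_methods(b$census, b$units, b$lc, b$climate, b$urban_extent,
                          s$grid)
    m <- res$metrics
    expect_true(all(m$rmse >= m$mae))
    m$rmse[m$method == "asiapop"] < m$rmse[m$method == "gpw"] &&
      m$rmse[m$method == "asiapop"] < m$rmse[m$method == "grump"]
  })
  expect_gte(sum(wins), 18)
})
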