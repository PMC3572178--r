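# All generators run inside with_preserved_seed(): one explicit seed on the
# scenario drives every draw, and the caller's RNG state is untouched.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Ground-truth density weights for a synthetic scenario
#'
#' Persons-per-cell densities per land-cover class, varied across climate
#' zones by a per-zone multiplier. The class profile mimics the density
#' ordering real products estimate — essentially nobody on water, sparse
#' population on natural cover, moderate density on cropland, and one to two
#' orders of magnitude more on settlement classes — at magnitudes plausible
#' for roughly 1 ha cells.
#'
#' @param classes Land-cover codes in the model legend.
#' @param n_zones Number of climate zones.
#' @param base Named base density per class (persons per cell).
#' @param zone_mult Per-zone multipliers, recycled over zones.
#' @param scale Global scale factor on all weights (larger values give larger
#'   unit totals, e.g. for noise studies).
#' @return A `weight_table` covering every `(zone, class)` pair.
#' @export
default_true_weights <- function(classes = c(1L, 2L, 4L, 5L, 8L, 9L),
                                 n_zones = 2,
                                 base = c(`1` = 0, `2` = 0.3, `3` = 0.5,
                                          `4` = 1, `5` = 3, `6` = 0.5,
                                          `7` = 0.1, `8` = 150, `9` = 30),
                                 zone_mult = c(1, 0.7, 1.3),
                                 scale = 1) {
  zm <- rep_len(zone_mult, n_zones)
  tab <- tidyr::expand_grid(climate_zone = seq_len(n_zones), land_cover = classes) |>
    dplyr::mutate(
      weight = scale * unname(base[as.character(.data$land_cover)]) * zm[.data$climate_zone],
      n_units = NA_integer_, residual = NA_real_
    )
  new_weight_table(tab, provenance = "synthetic")
}

#' Define a synthetic study scenario
#'
#' A fully seeded recipe for one synthetic landscape: grid shape, land-cover
#' patchiness, climate banding, admin hierarchy, urban blobs, void injection
#' and the ground-truth density weights generating the census. The same
#' scenario always produces byte-identical fixtures.
#'
#' @param seed Integer seed driving every draw.
#' @param n_rows,n_cols Grid dimensions.
#' @param classes Land-cover codes present (model legend codes; 8 and 9 are
#'   the settlement classes).
#' @param n_zones Number of horizontal climate bands.
#' @param n_coarse Number of coarse admin units (tiled as near-square
#'   rectangles).
#' @param n_fine_per_coarse Fine units per coarse unit.
#' @param true_weights Ground-truth `weight_table`
#'   (default [default_true_weights()]).
#' @param urban_blob_count,urban_blob_radius Disk-shaped urban-extent blobs.
#' @param void_fraction Fraction of land-cover cells replaced by nodata
#'   voids, in `[0, 1)`.
#' @param noise_model `"none"` (counts equal their expectations exactly) or
#'   `"poisson"` (seeded Poisson draws at those expectations).
#' @param cells_per_patch Average land-cover patch size in cells.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, n_rows = 64, n_cols = 64,
                               classes = c(1L, 2L, 4L, 5L, 8L, 9L),
                               n_zones = 2, n_coarse = 16,
                               n_fine_per_coarse = 4,
                               true_weights = NULL,
                               urban_blob_count = 3, urban_blob_radius = 6,
                               void_fraction = 0,
                               noise_model = c("none", "poisson"),
                               cells_per_patch = 60) {
  noise_model <- match.arg(noise_model)
  stopifnot(void_fraction >= 0, void_fraction < 1, seed == as.integer(seed))
  if (is.null(true_weights)) {
    true_weights <- default_true_weights(classes = classes, n_zones = n_zones)
  }
  if (any(true_weights$weight < 0)) stop("true weights must be >= 0", call. = FALSE)
  structure(
    list(
      seed = as.integer(seed),
      grid = grid_spec(n_rows, n_cols),
      classes = as.integer(classes),
      n_zones = as.integer(n_zones),
      n_coarse = as.integer(n_coarse),
      n_fine_per_coarse = as.integer(n_fine_per_coarse),
      true_weights = true_weights,
      urban_blob_count = as.integer(urban_blob_count),
      urban_blob_radius = as.numeric(urban_blob_radius),
      void_fraction = as.numeric(void_fraction),
      noise_model = noise_model,
      cells_per_patch = as.numeric(cells_per_patch)
    ),
    class = "synthetic_scenario"
  )
}

# near-square factorisation: rows x cols = n with rows the largest
# divisor <= sqrt(n)
split_factors <- function(n) {
  r <- floor(sqrt(n))
  while (n %% r != 0) r <- r - 1
  c(rows = as.integer(r), cols = as.integer(n / r))
}

#' Generate the synthetic rasters of a scenario
#'
#' Land cover is built from seeded random patches: patch seed cells get a
#' random class and every cell takes the class of its nearest seed (Euclidean,
#' ties to the earlier seed) — a deterministic, platform-independent patch
#' mosaic. Climate zones are contiguous horizontal bands; the urban extent is
#' a union of disks around random centers; voids are injected at
#' `void_fraction` uniformly at random. This is a fixture generator, not a
#' landscape model.
#'
#' @param s A [synthetic_scenario()].
#' @return List with `lc`, `climate`, `urban_extent` (`cat_raster`s).
#' @export
generate_landscape <- function(s) {
  g <- s$grid
  n <- g$n_rows * g$n_cols
  n_patches <- max(length(s$classes), round(n / s$cells_per_patch))
  if (s$urban_blob_count > 0 &&
      (2 * s$urban_blob_radius > max(g$n_rows, g$n_cols))) {
    stop("grid too small for requested urban blobs", call. = FALSE)
  }
  with_preserved_seed(s$seed, {
    ct <- cell_centers(g)
    seed_idx <- sample.int(n, n_patches)
    # every class gets at least one early seed so all classes are present
    seed_class <- c(
      s$classes,
      sample(s$classes, max(0, n_patches - length(s$classes)), replace = TRUE)
    )[seq_len(n_patches)]
    sx <- ct$x[seed_idx]; sy <- ct$y[seed_idx]
    nearest <- integer(n)
    best <- rep(Inf, n)
    for (k in seq_len(n_patches)) {
      d2 <- (ct$x - sx[k])^2 + (ct$y - sy[k])^2
      upd <- d2 < best  # strict: ties stay with the earlier seed
      nearest[upd] <- k
      best[upd] <- d2[upd]
    }
    lc_vals <- seed_class[nearest]
    if (s$void_fraction > 0) {
      nv <- round(s$void_fraction * n)
      lc_vals[sample.int(n, nv)] <- g$nodata_code
    }
    band <- pmin(floor(ct$row / (g$n_rows / s$n_zones)) + 1, s$n_zones)
    urb <- rep(0L, n)
    if (s$urban_blob_count > 0) {
      cx <- stats::runif(s$urban_blob_count, 0, g$n_cols)
      cy <- stats::runif(s$urban_blob_count, 0, g$n_rows)
      for (k in seq_len(s$urban_blob_count)) {
        urb[(ct$x - cx[k])^2 + (ct$y - cy[k])^2 <= s$urban_blob_radius^2] <- 1L
      }
    }
    list(
      lc = cat_raster(g, lc_vals, legend = lc_legend()[as.character(sort(unique(
        lc_vals[lc_vals != g$nodata_code]
      )))]),
      climate = cat_raster(g, band),
      urban_extent = cat_raster(g, urb, legend = c(`0` = "not_urban", `1` = "urban"))
    )
  })
}

#' Generate the two-level synthetic admin hierarchy
#'
#' Coarse units tile the grid as near-square rectangles; each coarse unit is
#' split into `n_fine_per_coarse` fine rectangles with `parent_id` links set.
#' Every fine unit is guaranteed at least one cell center.
#'
#' @param s A [synthetic_scenario()].
#' @return An [admin_units()] tibble holding both levels (coarse = level 1,
#'   fine = level 2).
#' @export
generate_admin_hierarchy <- function(s) {
  g <- s$grid
  fc <- split_factors(s$n_coarse)
  ff <- split_factors(s$n_fine_per_coarse)
  if (fc["rows"] * ff["rows"] > g$n_rows || fc["cols"] * ff["cols"] > g$n_cols) {
    stop("infeasible tiling: more units than cells along one axis", call. = FALSE)
  }
  breaks <- function(extent, k) round(seq(0, extent, length.out = k + 1))
  rb <- breaks(g$n_rows, fc["rows"]); cb <- breaks(g$n_cols, fc["cols"])
  rect <- function(x0, x1, y0, y1) {
    list(cbind(
      x = g$origin_x + c(x0, x1, x1, x0) * g$cell_size,
      y = g$origin_y + c(y0, y0, y1, y1) * g$cell_size
    ))
  }
  ids <- character(); levels <- integer(); parents <- character(); geoms <- list()
  ci <- 0
  for (i in seq_len(fc["rows"])) {
    for (j in seq_len(fc["cols"])) {
      ci <- ci + 1
      cid <- sprintf("C%02d", ci)
      ids <- c(ids, cid); levels <- c(levels, 1L); parents <- c(parents, NA_character_)
      geoms <- c(geoms, list(rect(cb[j], cb[j + 1], rb[i], rb[i + 1])))
      frb <- breaks(rb[i + 1] - rb[i], ff["rows"]) + rb[i]
      fcb <- breaks(cb[j + 1] - cb[j], ff["cols"]) + cb[j]
      fi <- 0
      for (a in seq_len(ff["rows"])) {
        for (b in seq_len(ff["cols"])) {
          fi <- fi + 1
          ids <- c(ids, sprintf("%s_F%02d", cid, fi))
          levels <- c(levels, 2L); parents <- c(parents, cid)
          geoms <- c(geoms, list(rect(fcb[b], fcb[b + 1], frb[a], frb[a + 1])))
        }
      }
    }
  }
  admin_units(
    unit_id = ids, level = levels, parent_id = parents,
    country = "SYN", geometry = geoms
  )
}

#' Generate the fine-level census of a scenario
#'
#' The expected count of each fine unit is the linear form
#' `sum_c w[z, c] * n[j, c]` under the scenario's ground-truth weights, cell
#' by cell over the unit. With `noise_model = "none"` the counts equal these
#' expectations exactly (exact parameter recovery is then possible); with
#' `"poisson"` counts are seeded Poisson draws at the expectations.
#'
#' @param s A [synthetic_scenario()].
#' @param lc,climate Rasters from [generate_landscape()] (void-free land
#'   cover; fill voids first if `void_fraction > 0`).
#' @param units Hierarchy from [generate_admin_hierarchy()].
#' @return A [census_table()] at the fine level, with the expectation kept in
#'   an `expected` column.
#' @export
generate_census <- function(s, lc, climate, units) {
  fine <- units[units$level == max(units$level), ]
  zones <- rasterize_zones(fine, s$grid)
  zv <- as.vector(t(zones$values))
  cl <- as.vector(t(lc$values))
  cz <- as.vector(t(climate$values))
  ok <- zv != s$grid$nodata_code & cl != lc$grid$nodata_code
  if (!all(ok[zv != s$grid$nodata_code])) {
    stop("land cover has voids inside units; run fill_voids() first", call. = FALSE)
  }
  uid <- unname(zones$legend[as.character(zv[ok])])
  w <- lookup_weight(s$true_weights, cz[ok], cl[ok])
  expected <- tapply(w, uid, sum)
  counts <- as.numeric(expected)
  if (s$noise_model == "poisson") {
    counts <- with_preserved_seed(s$seed + 1000L, stats::rpois(length(counts), counts))
  }
  out <- census_table(
    unit_id = names(expected), population = counts,
    reference_year = 2010L, country = "SYN"
  )
  out$expected <- as.numeric(expected)
  out
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper running [generate_landscape()],
#' [generate_admin_hierarchy()] and [generate_census()] in one call, with the
#' land cover void-filled when the scenario injects voids.
#'
#' @param s A [synthetic_scenario()].
#' @return List with `lc` (void-filled), `lc_raw`, `climate`, `urban_extent`,
#'   `units`, `census`, and the scenario itself as `scenario`.
#' @export
generate_bundle <- function(s) {
  land <- generate_landscape(s)
  units <- generate_admin_hierarchy(s)
  lc <- if (s$void_fraction > 0) fill_voids(land$lc) else land$lc
  census <- generate_census(s, lc, land$climate, units)
  list(
    lc = lc, lc_raw = land$lc, climate = land$climate,
    urban_extent = land$urban_extent, units = units, census = census,
    scenario = s
  )
}
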