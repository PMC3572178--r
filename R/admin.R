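#' Build an administrative-unit set
#'
#' Census reporting polygons at one or more nested levels. Units live in grid
#' coordinates; geometries within one level must not overlap (cell-assignment
#' uniqueness is enforced at rasterization with a deterministic tie-break for
#' centers on shared boundaries).
#'
#' @param unit_id Character vector of unit identifiers, unique within a level.
#' @param level Integer administrative level (coarser levels are smaller
#'   numbers, e.g. district = 2, village = 3).
#' @param parent_id Identifier of the enclosing unit one level up, or `NA`.
#' @param country Country token.
#' @param geometry List of polygon geometries, one per unit. Each geometry is
#'   a list of rings; each ring an `n x 2` matrix of `(x, y)` vertices
#'   (closed implicitly). Interior rings are treated as holes under the
#'   even-odd rule.
#' @param area Unit areas in km2; if `NULL`, computed from the geometry by the
#'   shoelace formula (planar, `km_per_unit` scaling both axes).
#' @param km_per_unit Kilometres per grid coordinate unit, used only when
#'   computing areas from geometry.
#' @return A tibble of class `admin_units` with columns `unit_id`, `level`,
#'   `parent_id`, `country`, `area`, and a `geometry` list-column.
#' @export
admin_units <- function(unit_id, level, parent_id = NA_character_,
                        country = "XX", geometry, area = NULL,
                        km_per_unit = 1) {
  unit_id <- as.character(unit_id)
  n <- length(unit_id)
  u <- tibble::tibble(
    unit_id = unit_id,
    level = as.integer(rep_len(level, n)),
    parent_id = as.character(rep_len(parent_id, n)),
    country = as.character(rep_len(country, n)),
    geometry = geometry
  )
  u$area <- if (is.null(area)) {
    vapply(geometry, polygon_area, numeric(1)) * km_per_unit^2
  } else {
    rep_len(as.numeric(area), n)
  }
  validate_admin_units(u)
  class(u) <- c("admin_units", class(u))
  u
}

validate_admin_units <- function(u) {
  dup <- u |>
    dplyr::count(.data$level, .data$unit_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate unit_id within a level: ",
         paste(dup$unit_id, collapse = ", "), call. = FALSE)
  }
  for (lev in sort(unique(u$level))) {
    kids <- u[u$level == lev & !is.na(u$parent_id), ]
    if (nrow(kids)) {
      parents <- u$unit_id[u$level == lev - 1L]
      orphans <- setdiff(kids$parent_id, parents)
      if (length(orphans)) {
        stop("parent_id not found one level up: ",
             paste(orphans, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(u)
}

# Signed shoelace area summed over rings; holes (opposite winding) subtract.
polygon_area <- function(geom) {
  tot <- 0
  for (ring in geom) {
    x <- ring[, 1]; y <- ring[, 2]
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    tot <- tot + sum(x * y2 - x2 * y) / 2
  }
  abs(tot)
}

# Even-odd ray-casting point-in-polygon over all rings of a geometry.
# Points exactly on a ring edge count as inside (boundary-inclusive); the
# caller resolves shared-boundary ties by unit_id order.
points_in_geom <- function(px, py, geom, tol = 1e-12) {
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in geom) {
    x <- ring[, 1]; y <- ring[, 2]
    nv <- length(x)
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    for (k in seq_len(nv)) {
      x1k <- x[k]; y1k <- y[k]; x2k <- x2[k]; y2k <- y2[k]
      crosses <- ((y1k > py) != (y2k > py)) &
        (px < (x2k - x1k) * (py - y1k) / (y2k - y1k) + x1k)
      inside <- xor(inside, crosses)
      cross <- (x2k - x1k) * (py - y1k) - (y2k - y1k) * (px - x1k)
      within <- px >= pmin(x1k, x2k) - tol & px <= pmax(x1k, x2k) + tol &
        py >= pmin(y1k, y2k) - tol & py <= pmax(y1k, y2k) + tol
      on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    }
  }
  inside | on_edge
}

#' Rasterize admin-unit polygons onto a grid
#'
#' Each cell is labelled with the unit whose polygon contains its center. A
#' center lying on a shared boundary is assigned to the unit with the
#' lexicographically smallest `unit_id`, making the output deterministic.
#' Cells outside every unit get the nodata code.
#'
#' @param units An [admin_units()] tibble, all at one level.
#' @param grid A [grid_spec()].
#' @return A `cat_raster` whose legend maps integer codes to `unit_id`s.
#'   Units covering zero cell centers are reported via a warning (they cannot
#'   receive population) and recorded in the `attr(, "empty_units")`.
#' @export
rasterize_zones <- function(units, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(units) == 0) stop("empty unit set", call. = FALSE)
  if (length(unique(units$level)) != 1) {
    stop("rasterize_zones requires units all at one level", call. = FALSE)
  }
  ord <- order(units$unit_id, method = "radix")
  units <- units[ord, ]
  ct <- cell_centers(grid)
  lab <- rep(grid$nodata_code, nrow(ct))
  for (i in seq_len(nrow(units))) {
    free <- lab == grid$nodata_code
    if (!any(free)) break
    hit <- points_in_geom(ct$x[free], ct$y[free], units$geometry[[i]])
    lab[which(free)[hit]] <- i
  }
  legend <- stats::setNames(units$unit_id, as.character(seq_len(nrow(units))))
  r <- cat_raster(grid, lab, legend = legend)
  empty <- setdiff(seq_len(nrow(units)), unique(lab))
  empty_ids <- units$unit_id[empty]
  if (length(empty_ids)) {
    warning("units covering zero cell centers (cannot receive population): ",
            paste(empty_ids, collapse = ", "), call. = FALSE)
  }
  attr(r, "empty_units") <- empty_ids
  r
}

#' Cross-tabulate zone and class rasters
#'
#' Exact pixel-by-pixel count of cells of each class inside each zone, the
#' `n[j, c]` table driving weight estimation and redistribution. Cells that
#' are nodata in either raster are excluded and their count reported.
#'
#' @param zones A `cat_raster` of zone labels (typically from
#'   [rasterize_zones()]).
#' @param classes A `cat_raster` of class codes on the identical grid.
#' @return A tibble of class `zonal_table` with columns `unit_id`, `class`
#'   (integer code), `n` (cell count), plus attributes `excluded` (number of
#'   cells dropped for nodata) and `totals` (a tibble `unit_id`, `n_total`).
#' @export
zonal_tabulate <- function(zones, classes) {
  assert_same_grid(zones, classes)
  zv <- as.vector(zones$values)
  cv <- as.vector(classes$values)
  ok <- zv != zones$grid$nodata_code & cv != classes$grid$nodata_code
  excluded <- sum(!ok)
  zid <- unname(zones$legend[as.character(zv[ok])])
  zid[is.na(zid)] <- as.character(zv[ok][is.na(zid)])
  tab <- tibble::tibble(unit_id = zid, class = cv[ok]) |>
    dplyr::count(.data$unit_id, .data$class, name = "n")
  totals <- tab |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(n_total = sum(.data$n), .groups = "drop")
  structure(tab,
            excluded = excluded, totals = totals,
            class = c("zonal_table", class(tab)))
}

#' Mean spatial resolution of an administrative level
#'
#' The effective "cell size" of a set of census units: the square root of the
#' mean unit area. Reported in km when areas are km2.
#'
#' @param areas Numeric vector of unit areas (km2), all positive.
#' @return Square root of the mean area.
#' @examples
#' mean_spatial_resolution(c(100, 144))
#' @export
mean_spatial_resolution <- function(areas) {
  if (length(areas) == 0) stop("empty area list", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("all areas must be positive and finite", call. = FALSE)
  }
  sqrt(mean(areas))
}

#' Aggregate fine census units to their parents
#'
#' Sums child counts into each parent unit and unions child geometries, the
#' first step of the aggregation-based accuracy protocol: coarsen, re-model,
#' then score against the original fine counts.
#'
#' @param fine_census Census tibble (see [census_table()]) at the fine level.
#' @param units An [admin_units()] tibble containing both the fine units (with
#'   `parent_id` set) and their parents.
#' @return A list with `census`: the coarse census tibble, and `units`: the
#'   coarse `admin_units` (geometry = union of children as a multi-ring
#'   geometry; area = sum of child areas).
#' @export
aggregate_units <- function(fine_census, units) {
  fine_level <- max(units$level)
  fine <- units[units$level == fine_level, ]
  fine <- fine[fine$unit_id %in% fine_census$unit_id, ]
  orphan <- fine$unit_id[is.na(fine$parent_id)]
  if (length(orphan)) {
    stop("fine units without parent_id: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  joined <- fine_census |>
    dplyr::inner_join(
      tibble::as_tibble(fine)[, c("unit_id", "parent_id", "area")],
      by = "unit_id"
    )
  coarse_census <- joined |>
    dplyr::group_by(unit_id = .data$parent_id) |>
    dplyr::summarise(
      population = sum(.data$population),
      reference_year = .data$reference_year[1],
      country = .data$country[1],
      .groups = "drop"
    )
  geo <- split(fine$geometry, fine$parent_id)
  parent_ids <- names(geo)
  coarse_units <- admin_units(
    unit_id = parent_ids,
    level = fine_level - 1L,
    parent_id = NA_character_,
    country = fine$country[match(parent_ids, fine$parent_id)],
    geometry = lapply(geo, function(gs) do.call(c, gs)),
    area = vapply(split(fine$area, fine$parent_id), sum, numeric(1))
  )
  list(census = coarse_census, units = coarse_units)
}

#' Read and write admin units as GeoJSON
#'
#' A FeatureCollection of Polygon/MultiPolygon features with properties
#' `unit_id`, `level`, `parent_id`, `country` and optionally `area`.
#'
#' @param path File path.
#' @return `read_admin_geojson()` returns an [admin_units()] tibble;
#'   `write_admin_geojson()` returns `path` invisibly.
#' @export
read_admin_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- fc$features
  ring_mat <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    # drop the GeoJSON closing vertex; rings are closed implicitly here
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    if (g$type == "Polygon") {
      lapply(g$coordinates, ring_mat)
    } else if (g$type == "MultiPolygon") {
      do.call(c, lapply(g$coordinates, function(poly) lapply(poly, ring_mat)))
    } else {
      stop("unsupported geometry type: ", g$type, call. = FALSE)
    }
  })
  prop_chr <- function(name) {
    vapply(feats, function(f) {
      v <- f$properties[[name]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
    }, character(1))
  }
  areas <- vapply(feats, function(f) {
    v <- f$properties[["area"]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  admin_units(
    unit_id = prop_chr("unit_id"),
    level = as.integer(prop_chr("level")),
    parent_id = prop_chr("parent_id"),
    country = prop_chr("country"),
    geometry = geoms,
    area = if (all(is.na(areas))) NULL else areas
  )
}

#' @rdname read_admin_geojson
#' @param units An [admin_units()] tibble.
#' @export
write_admin_geojson <- function(units, path) {
  features <- lapply(seq_len(nrow(units)), function(i) {
    rings <- lapply(units$geometry[[i]], function(m) {
      m2 <- rbind(m, m[1, ])  # GeoJSON rings are explicitly closed
      lapply(seq_len(nrow(m2)), function(k) c(m2[k, 1], m2[k, 2]))
    })
    props <- list(
      unit_id = units$unit_id[i],
      level = units$level[i],
      parent_id = units$parent_id[i],
      country = units$country[i],
      area = units$area[i]
    )
    if (is.na(units$parent_id[i])) props$parent_id <- NULL
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
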