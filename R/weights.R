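#' Census count table
#'
#' One row per administrative unit: the unit's population count, census
#' reference year and country. The `urban_flag` column (set by
#' [classify_units_urban_rural()]) selects the urban or rural growth rate at
#' projection time.
#'
#' @param unit_id Character unit identifiers, unique.
#' @param population Nonnegative person counts.
#' @param reference_year Calendar year of the census or official estimate;
#'   constant within a country table.
#' @param country Country token.
#' @param urban_flag Optional logical.
#' @return A tibble of class `census_table`.
#' @export
census_table <- function(unit_id, population, reference_year,
                         country = "XX", urban_flag = NA) {
  unit_id <- as.character(unit_id)
  if (anyDuplicated(unit_id)) stop("duplicate unit_id in census table", call. = FALSE)
  if (any(population < 0)) stop("population counts must be >= 0", call. = FALSE)
  n <- length(unit_id)
  tab <- tibble::tibble(
    unit_id = unit_id,
    population = as.numeric(population),
    reference_year = as.integer(rep_len(reference_year, n)),
    country = as.character(rep_len(country, n)),
    urban_flag = rep_len(as.logical(urban_flag), n)
  )
  yr <- tab |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$reference_year), .groups = "drop")
  if (any(yr$k > 1)) {
    stop("reference_year must be constant within a country", call. = FALSE)
  }
  class(tab) <- c("census_table", class(tab))
  tab
}

#' Read a census CSV (`unit_id,population,reference_year[,country]`)
#' @param path CSV path.
#' @return A [census_table()].
#' @export
read_census_csv <- function(path) {
  raw <- utils::read.csv(path)
  census_table(
    unit_id = raw$unit_id,
    population = raw$population,
    reference_year = raw$reference_year,
    country = if ("country" %in% names(raw)) raw$country else "XX"
  )
}

#' @rdname read_census_csv
#' @param census A [census_table()].
#' @export
write_census_csv <- function(census, path) {
  utils::write.csv(
    tibble::as_tibble(census)[, c("unit_id", "population", "reference_year", "country")],
    path, row.names = FALSE
  )
  invisible(path)
}

# Nonnegative least squares with column normalisation for conditioning
# (weights rescale exactly); falls back to box-constrained quasi-Newton
# minimisation should the active-set solver fail to converge.
nnls_solve <- function(X, y) {
  cn <- sqrt(colSums(X^2))
  cn[cn == 0] <- 1
  Xs <- sweep(X, 2, cn, "/")
  fit <- tryCatch(
    pracma::lsqnonneg(Xs, y)$x,
    error = function(e) {
      stats::optim(
        par = rep(0, ncol(Xs)),
        fn = function(w) sum((Xs %*% w - y)^2),
        gr = function(w) as.vector(2 * crossprod(Xs, Xs %*% w - y)),
        method = "L-BFGS-B", lower = 0,
        control = list(maxit = 1000)
      )$par
    }
  )
  unname(pmax(fit, 0) / cn)
}

new_weight_table <- function(tab, provenance = character(), diagnostics = NULL) {
  structure(
    tab,
    provenance = provenance,
    diagnostics = diagnostics,
    class = c("weight_table", setdiff(class(tab), "weight_table"))
  )
}

#' Estimate per-climate-zone land-cover density weights
#'
#' The core of the dasymetric model: for each climate zone `z`, finds
#' nonnegative persons-per-cell weights `w[z, c]` such that each training
#' unit's census count is approximated by the weighted sum of its per-class
#' cell counts, `T_j ~ sum_c w[z, c] * n[j, c]`. The system is solved by
#' nonnegative least squares per zone, over the units whose majority of cells
#' lies in that zone (ties go to the smaller zone code); cross-zone units are
#' not split. An underdetermined zone is still solved (NNLS returns the
#' nonnegativity-constrained solution of the active set) and flagged in the
#' diagnostics.
#'
#' @param census A [census_table()] for the training country.
#' @param zones `cat_raster` of admin-unit labels (from [rasterize_zones()]).
#' @param lc `cat_raster` of land-cover classes.
#' @param climate `cat_raster` of climate-zone codes.
#' @return A tibble of class `weight_table` with columns `climate_zone`,
#'   `land_cover`, `weight`, `n_units`, `residual` (per-zone residual norm),
#'   attribute `provenance` (countries) and a per-zone `diagnostics` tibble
#'   (`climate_zone`, `n_units`, `n_classes`, `rank`, `residual`,
#'   `underdetermined`).
#' @export
estimate_weights <- function(census, zones, lc, climate) {
  assert_same_grid(zones, lc, climate)
  zt <- zonal_tabulate(zones, lc)
  present <- unique(zt$unit_id)
  missing <- setdiff(census$unit_id, present)
  if (length(missing)) {
    stop("census units absent from the zones raster: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  # majority climate zone per unit (ties -> smaller zone code)
  zv <- as.vector(zones$values); cz <- as.vector(climate$values)
  ok <- zv != zones$grid$nodata_code & cz != climate$grid$nodata_code
  uid <- unname(zones$legend[as.character(zv[ok])])
  zone_of <- tibble::tibble(unit_id = uid, climate_zone = cz[ok]) |>
    dplyr::count(.data$unit_id, .data$climate_zone) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$climate_zone, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "climate_zone")

  # per-unit per-class counts restricted to the unit's climate zone
  cl <- as.vector(lc$values)
  okc <- ok & cl != lc$grid$nodata_code
  uidc <- unname(zones$legend[as.character(zv[okc])])
  counts <- tibble::tibble(unit_id = uidc, land_cover = cl[okc],
                           climate_zone = cz[okc]) |>
    dplyr::inner_join(zone_of, by = c("unit_id", "climate_zone")) |>
    dplyr::count(.data$unit_id, .data$climate_zone, .data$land_cover, name = "n")

  train <- counts |>
    dplyr::inner_join(
      tibble::as_tibble(census)[, c("unit_id", "population")], by = "unit_id"
    )

  rows <- list(); diags <- list()
  for (z in sort(unique(train$climate_zone))) {
    dz <- train[train$climate_zone == z, ]
    units_z <- unique(dz$unit_id)
    classes_z <- sort(unique(dz$land_cover))
    X <- matrix(0, length(units_z), length(classes_z),
                dimnames = list(units_z, classes_z))
    X[cbind(match(dz$unit_id, units_z), match(dz$land_cover, classes_z))] <- dz$n
    y <- census$population[match(units_z, census$unit_id)]
    w <- nnls_solve(X, y)
    resid <- sqrt(sum((X %*% w - y)^2))
    rk <- qr(X)$rank
    under <- rk < length(classes_z)
    rows[[length(rows) + 1]] <- tibble::tibble(
      climate_zone = z, land_cover = classes_z, weight = w,
      n_units = length(units_z), residual = resid
    )
    diags[[length(diags) + 1]] <- tibble::tibble(
      climate_zone = z, n_units = length(units_z),
      n_classes = length(classes_z), rank = rk,
      residual = resid, underdetermined = under
    )
  }
  if (!length(rows)) stop("no climate zone contains training units", call. = FALSE)
  new_weight_table(
    dplyr::bind_rows(rows),
    provenance = unique(census$country),
    diagnostics = dplyr::bind_rows(diags)
  )
}

#' Average weight tables across training countries
#'
#' Per-zone per-class weights from several fine-scale census countries are
#' combined by the unweighted arithmetic mean over the tables in which the
#' `(zone, class)` pair is present; pairs present in a single table pass
#' through unchanged.
#'
#' @param tables List of `weight_table`s sharing a class legend.
#' @return A combined `weight_table`; provenance concatenates contributors.
#' @export
combine_weights <- function(tables) {
  if (length(tables) == 0) stop("empty list of weight tables", call. = FALSE)
  if (length(tables) == 1) return(tables[[1]])
  combined <- dplyr::bind_rows(lapply(tables, tibble::as_tibble)) |>
    dplyr::group_by(.data$climate_zone, .data$land_cover) |>
    dplyr::summarise(
      weight = mean(.data$weight),
      n_units = sum(.data$n_units),
      residual = NA_real_,
      .groups = "drop"
    )
  new_weight_table(
    combined,
    provenance = unique(unlist(lapply(tables, attr, "provenance"))),
    diagnostics = dplyr::bind_rows(lapply(tables, attr, "diagnostics"))
  )
}

#' Look up weights with zone fallback
#'
#' At prediction time a `(zone, class)` pair missing from the table falls back
#' to the across-zone mean weight for that class; a class never seen anywhere
#' gets weight 0.
#'
#' @param weights A `weight_table`.
#' @param climate_zone,land_cover Vectors (recycled to common length).
#' @return Numeric weight vector.
#' @export
lookup_weight <- function(weights, climate_zone, land_cover) {
  n <- max(length(climate_zone), length(land_cover))
  climate_zone <- rep_len(climate_zone, n)
  land_cover <- rep_len(land_cover, n)
  key <- paste(climate_zone, land_cover, sep = "\r")
  wkey <- paste(weights$climate_zone, weights$land_cover, sep = "\r")
  out <- weights$weight[match(key, wkey)]
  if (anyNA(out)) {
    class_mean <- tapply(weights$weight, weights$land_cover, mean)
    fb <- class_mean[as.character(land_cover)]
    out[is.na(out)] <- fb[is.na(out)]
    out[is.na(out)] <- 0
  }
  unname(out)
}

#' Read/write a weight table CSV
#' (`climate_zone,land_cover,weight,n_units,residual`)
#' @param path CSV path.
#' @return A `weight_table` / `path` invisibly.
#' @export
read_weights_csv <- function(path) {
  raw <- utils::read.csv(path)
  new_weight_table(tibble::tibble(
    climate_zone = as.integer(raw$climate_zone),
    land_cover = as.integer(raw$land_cover),
    weight = as.numeric(raw$weight),
    n_units = if ("n_units" %in% names(raw)) as.integer(raw$n_units) else NA_integer_,
    residual = if ("residual" %in% names(raw)) as.numeric(raw$residual) else NA_real_
  ))
}

#' @rdname read_weights_csv
#' @param weights A `weight_table`.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(tibble::as_tibble(weights), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d (zone, class) weights; countries: %s\n",
              nrow(x), paste(attr(x, "provenance"), collapse = ", ")))
  NextMethod()
}

#' Tidy a weight table
#'
#' @param x A `weight_table`.
#' @param ... Unused.
#' @return A plain tibble of per-`(zone, class)` weights.
#' @method tidy weight_table
#' @export
tidy.weight_table <- function(x, ...) {
  tibble::tibble(
    climate_zone = as.integer(x$climate_zone),
    land_cover = as.integer(x$land_cover),
    weight = unname(as.numeric(x$weight))
  )
}

#' One-row-per-zone summary of a weight fit
#'
#' @param x A `weight_table` carrying estimation diagnostics.
#' @param ... Unused.
#' @return Tibble with per-zone unit counts, design rank, residual norm and an
#'   underdetermined flag.
#' @method glance weight_table
#' @export
glance.weight_table <- function(x, ...) {
  d <- attr(x, "diagnostics")
  if (is.null(d)) {
    d <- tibble::as_tibble(x) |>
      dplyr::group_by(.data$climate_zone) |>
      dplyr::summarise(n_classes = dplyr::n(), .groups = "drop")
  }
  d
}
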