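#' Classify admin units as urban or rural
#'
#' A unit is urban if at least one of its cells coincides with the urban
#' extent; otherwise it is recoded rural. This drives which growth rate
#' (urban or rural) projects the unit's count forward.
#'
#' @param zones `cat_raster` of unit labels.
#' @param urban_extent Binary `cat_raster` on the identical grid.
#' @return A tibble `unit_id`, `urban_flag`.
#' @export
classify_units_urban_rural <- function(zones, urban_extent) {
  assert_same_grid(zones, urban_extent)
  zv <- as.vector(zones$values)
  uv <- as.vector(urban_extent$values)
  ok <- zv != zones$grid$nodata_code
  if (!any(ok)) stop("zones raster has no unit cells", call. = FALSE)
  uid <- unname(zones$legend[as.character(zv[ok])])
  tibble::tibble(unit_id = uid, hit = uv[ok] == 1L) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(urban_flag = any(.data$hit), .groups = "drop")
}

#' Project census counts by compound urban/rural growth
#'
#' Applies `P_target = P_d * (1 + r)^t`, with `r` the unit's urban or rural
#' average annual growth rate and `t = target_year - reference_year`. `t = 0`
#' and `r = 0` are exact identities. Fractional years are permitted if the
#' caller supplies a non-integer `target_year`.
#'
#' @param census A [census_table()] with `urban_flag` set (see
#'   [classify_units_urban_rural()]).
#' @param growth A list or one-row data frame with `r_urban`, `r_rural`
#'   (proportions per year, each > -1) and `target_year`.
#' @return The census tibble with `population` projected and
#'   `reference_year` advanced to the target year.
#' @examples
#' cs <- census_table("u1", 1000, 2005, urban_flag = FALSE)
#' project_population(cs, list(r_urban = 0.03, r_rural = 0.02, target_year = 2010))
#' @export
project_population <- function(census, growth) {
  if (any(is.na(census$urban_flag))) {
    stop("urban_flag must be set before projection", call. = FALSE)
  }
  r_u <- growth$r_urban; r_r <- growth$r_rural
  if (r_u <= -1 || r_r <= -1) stop("growth rates must exceed -1", call. = FALSE)
  t <- growth$target_year - census$reference_year
  r <- ifelse(census$urban_flag, r_u, r_r)
  out <- census
  out$population <- census$population * (1 + r)^t
  out$reference_year <- as.integer(round(growth$target_year))
  out
}

# Shared scaffolding for the redistribution methods: per-cell unit labels and
# census totals, with the pre-checks every method needs.
redistribution_frame <- function(census, zones) {
  zv <- as.vector(t(zones$values))  # row-major, aligned with cell_centers()
  ok <- zv != zones$grid$nodata_code
  uid <- rep(NA_character_, length(zv))
  uid[ok] <- unname(zones$legend[as.character(zv[ok])])
  rasterized <- unique(uid[ok])
  missing <- setdiff(census$unit_id, rasterized)
  if (length(missing)) {
    stop("census units with zero rasterized cells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  totals <- census$population[match(uid, census$unit_id)]
  list(uid = uid, ok = ok & !is.na(totals), totals = totals)
}

finish_population_raster <- function(grid, pop, ok) {
  pop[!ok] <- NA
  if (any(pop[ok] < 0)) stop("negative population produced", call. = FALSE)
  value_raster(grid, pop)
}

#' Dasymetric redistribution with land-cover/climate-zone weights
#'
#' The flagship method: within each admin unit, cell `i` receives
#' `T_j * w[z(i), c(i)] / sum_k w[z(k), c(k)]` over the unit's cells, so that
#' population concentrates on the land-cover classes (stratified by climate
#' zone) where the estimated density weights are large, while each unit's grid
#' sum still equals its census count exactly (mass conservation). A unit whose
#' total weight is zero falls back to uniform spread rather than losing its
#' population; such units are recorded in `attr(, "degenerate_units")`.
#'
#' @param census A [census_table()].
#' @param zones `cat_raster` of unit labels.
#' @param lc `cat_raster` of land-cover classes.
#' @param climate `cat_raster` of climate zones.
#' @param weights A `weight_table` (see [estimate_weights()]).
#' @return A `value_raster` of persons per cell; cells outside all units are
#'   nodata.
#' @export
dasymetric_redistribute <- function(census, zones, lc, climate, weights) {
  assert_same_grid(zones, lc, climate)
  fr <- redistribution_frame(census, zones)
  cl <- as.vector(t(lc$values))
  cz <- as.vector(t(climate$values))
  w <- numeric(length(fr$uid))
  w[fr$ok] <- lookup_weight(weights, cz[fr$ok], cl[fr$ok])
  wsum <- tapply(w[fr$ok], fr$uid[fr$ok], sum)
  degenerate <- names(wsum)[wsum <= 0]
  if (length(degenerate)) {
    ncell <- tapply(rep(1, sum(fr$ok)), fr$uid[fr$ok], sum)
    deg <- fr$ok & fr$uid %in% degenerate
    w[deg] <- 1
    wsum[degenerate] <- ncell[degenerate]
  }
  pop <- numeric(length(w))
  pop[fr$ok] <- fr$totals[fr$ok] * w[fr$ok] / as.numeric(wsum[fr$uid[fr$ok]])
  r <- finish_population_raster(zones$grid, pop, fr$ok)
  attr(r, "degenerate_units") <- degenerate
  r
}

#' Areal-weighting redistribution (GPW-style baseline)
#'
#' Distributes each unit's count uniformly over its cells: every cell of unit
#' `j` receives `T_j / n_j`. This is the uniformity assumption of the Gridded
#' Population of the World family, used here as a comparison baseline.
#'
#' @inheritParams dasymetric_redistribute
#' @return A `value_raster` of persons per cell.
#' @export
areal_redistribute <- function(census, zones) {
  fr <- redistribution_frame(census, zones)
  ncell <- tapply(rep(1, sum(fr$ok)), fr$uid[fr$ok], sum)
  pop <- numeric(length(fr$uid))
  pop[fr$ok] <- fr$totals[fr$ok] / as.numeric(ncell[fr$uid[fr$ok]])
  finish_population_raster(zones$grid, pop, fr$ok)
}

#' Urban-concentration redistribution (GRUMP-style baseline)
#'
#' Concentrates a share of each unit's population onto its urban-extent cells
#' and spreads the remainder uniformly over the rest: within a unit that
#' intersects the urban extent, `urban_share * T_j` is divided equally among
#' its urban cells and `(1 - urban_share) * T_j` among its non-urban cells.
#' Units with no urban cells are fully areal-weighted; a unit with only urban
#' cells receives everything on them. `urban_share` is a single configurable
#' stand-in for the per-settlement population accounting of the original
#' GRUMP product, whose details are not reproduced here.
#'
#' @inheritParams dasymetric_redistribute
#' @param urban_extent Binary `cat_raster`.
#' @param urban_share Proportion of a unit's population allotted to its urban
#'   cells, in `[0, 1]` (default 0.5). Either a single number or a vector
#'   named by `unit_id` (per-unit or per-country overrides); unnamed units
#'   fall back to 0.5.
#' @return A `value_raster` of persons per cell.
#' @export
grump_redistribute <- function(census, zones, urban_extent, urban_share = 0.5) {
  stopifnot(all(urban_share >= 0), all(urban_share <= 1))
  assert_same_grid(zones, urban_extent)
  fr <- redistribution_frame(census, zones)
  urb <- as.vector(t(urban_extent$values)) == 1L
  idx <- fr$ok
  n_urb <- tapply(as.numeric(urb[idx]), fr$uid[idx], sum)
  n_tot <- tapply(rep(1, sum(idx)), fr$uid[idx], sum)
  nu <- as.numeric(n_urb[fr$uid[idx]])
  nt <- as.numeric(n_tot[fr$uid[idx]])
  nr <- nt - nu
  ui <- urb[idx]
  us <- if (length(urban_share) == 1 && is.null(names(urban_share))) {
    rep(urban_share, sum(idx))
  } else {
    s <- urban_share[fr$uid[idx]]
    s[is.na(s)] <- 0.5
    as.numeric(s)
  }
  cellpop <- numeric(sum(idx))
  plain <- nu == 0                       # no urban cells: areal weighting
  cellpop[plain] <- fr$totals[idx][plain] / nt[plain]
  allurb <- nu > 0 & nr == 0             # only urban cells: everything on them
  cellpop[allurb] <- fr$totals[idx][allurb] / nu[allurb]
  mix <- nu > 0 & nr > 0
  cellpop[mix & ui] <- us[mix & ui] * fr$totals[idx][mix & ui] / nu[mix & ui]
  cellpop[mix & !ui] <- (1 - us[mix & !ui]) * fr$totals[idx][mix & !ui] / nr[mix & !ui]
  pop <- numeric(length(fr$uid))
  pop[idx] <- cellpop
  finish_population_raster(zones$grid, pop, idx)
}

#' Scale a population raster to a national total
#'
#' Multiplies every cell by `national_total / sum(pop)`, producing the
#' "adjusted" product variant whose total matches an external national
#' estimate. Scaling is linear, so applying it before or after gridding gives
#' identical results.
#'
#' @param pop A `value_raster` with positive total.
#' @param national_total Target total, `>= 0`.
#' @return A rescaled `value_raster`.
#' @export
adjust_to_national_total <- function(pop, national_total) {
  stopifnot(national_total >= 0)
  s <- sum(pop$values, na.rm = TRUE)
  if (s <= 0) stop("population raster sums to zero; cannot adjust", call. = FALSE)
  value_raster(pop$grid, as.vector(t(pop$values)) * (national_total / s))
}

#' Integerize a population raster by largest remainders
#'
#' Optional post-processing for users needing whole persons: within each unit,
#' cell values are floored and the unit's leftover persons are handed to the
#' cells with the largest fractional parts (ties to the earlier cell in
#' row-major order), preserving per-unit totals exactly when the input totals
#' are integers. Off by default in every pipeline; gridded products are
#' real-valued.
#'
#' @param pop A `value_raster`.
#' @param zones `cat_raster` of unit labels on the identical grid.
#' @return A `value_raster` with integer values.
#' @export
integerize_population <- function(pop, zones) {
  assert_same_grid(pop, zones)
  zv <- as.vector(t(zones$values))
  pv <- as.vector(t(pop$values))
  ok <- zv != zones$grid$nodata_code & !is.na(pv)
  out <- pv
  for (z in unique(zv[ok])) {
    i <- which(ok & zv == z)
    v <- pv[i]
    fl <- floor(v)
    left <- round(sum(v) - sum(fl))
    add <- integer(length(v))
    if (left > 0) {
      ord <- order(-(v - fl), seq_along(v))
      add[ord[seq_len(left)]] <- 1L
    }
    out[i] <- fl + add
  }
  value_raster(pop$grid, out)
}
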