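#' Pair observed fine-level counts with modelled estimates
#'
#' The accuracy protocol scores a map built from coarse counts against the
#' fine counts it never saw: each fine unit's estimate is the sum of modelled
#' raster cells inside it, paired with the observed fine census count.
#'
#' @param pop A `value_raster` modelled at the coarse level.
#' @param fine_zones `cat_raster` of fine unit labels on the identical grid.
#' @param fine_census A [census_table()] at the fine level (the observations).
#' @param method Label recorded on every pair (e.g. `"asiapop"`).
#' @return A tibble of class `evaluation_pairs` with columns `unit_id`,
#'   `observed`, `estimated`, `method`; fine units with zero rasterized cells
#'   are excluded and counted in `attr(, "excluded_units")`.
#' @export
evaluate <- function(pop, fine_zones, fine_census, method = "model") {
  assert_same_grid(pop, fine_zones)
  zv <- as.vector(t(fine_zones$values))
  pv <- as.vector(t(pop$values))
  ok <- zv != fine_zones$grid$nodata_code & !is.na(pv)
  uid <- unname(fine_zones$legend[as.character(zv[ok])])
  est <- tapply(pv[ok], uid, sum)
  pairs <- tibble::tibble(
    unit_id = fine_census$unit_id,
    observed = fine_census$population,
    estimated = as.numeric(est[fine_census$unit_id]),
    method = method
  )
  excluded <- pairs$unit_id[is.na(pairs$estimated)]
  pairs <- pairs[!is.na(pairs$estimated), ]
  structure(pairs, excluded_units = excluded,
            class = c("evaluation_pairs", class(pairs)))
}

#' Error metrics for one method
#'
#' `RMSE = sqrt(mean((est - obs)^2))`, `MAE = mean(|est - obs|)`,
#' `%RMSE = 100 * RMSE / mean(obs)` (the RMSE expressed as a percentage of
#' the mean unit population at the assessed administrative level), and
#' Pearson's r between estimates and observations. Always `RMSE >= MAE`.
#' When the estimates are constant, r is undefined and reported as `NA`
#' rather than 0; `%RMSE` is likewise `NA` when `mean(obs)` is 0. `r_squared`
#' accompanies `pearson_r` because published correlation tables are sometimes
#' ambiguous between the two.
#'
#' @param pairs An [evaluate()] result (or any tibble with `observed`,
#'   `estimated`, `method`).
#' @return One-row tibble per method: `method`, `n_units`, `rmse`,
#'   `pct_rmse`, `mae`, `pearson_r`, `r_squared`.
#' @examples
#' error_metrics(tibble::tibble(
#'   unit_id = c("a", "b", "c"), observed = c(100, 200, 300),
#'   estimated = c(110, 190, 330), method = "demo"
#' ))
#' @export
error_metrics <- function(pairs) {
  if (nrow(pairs) < 2) stop("need at least 2 observed/estimated pairs", call. = FALSE)
  pairs |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      rmse = sqrt(mean((.data$estimated - .data$observed)^2)),
      pct_rmse = if (mean(.data$observed) > 0) {
        100 * sqrt(mean((.data$estimated - .data$observed)^2)) / mean(.data$observed)
      } else NA_real_,
      mae = mean(abs(.data$estimated - .data$observed)),
      pearson_r = if (stats::sd(.data$estimated) > 0 && stats::sd(.data$observed) > 0) {
        stats::cor(.data$estimated, .data$observed)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(r_squared = .data$pearson_r^2)
}

#' Compare methods' error distributions by ranks
#'
#' Kruskal-Wallis test (tie-corrected H, chi-square p on `k - 1` df) on the
#' per-unit absolute errors of each method, followed by the Siegel-Castellan
#' post-hoc procedure: methods `i`, `j` differ when the absolute difference of
#' their mean ranks exceeds
#' `z[1 - alpha / (k (k - 1))] * sqrt(N (N + 1) / 12 * (1 / n_i + 1 / n_j))`.
#' When all values are identical across all groups, `H = 0`, `p = 1` and no
#' pair is significant.
#'
#' @param errors Named list of numeric vectors, one per method (typically
#'   `abs(estimated - observed)` per unit), each of length >= 2.
#' @param alpha Familywise significance level for the post-hoc pairs.
#' @return List with `h`, `p_value`, `df`, and `pairwise`: a tibble
#'   `method_a`, `method_b`, `mean_rank_diff`, `critical_difference`,
#'   `significant`.
#' @export
compare_methods <- function(errors, alpha = 0.05) {
  k <- length(errors)
  if (k < 2 || any(lengths(errors) < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  if (is.null(names(errors))) names(errors) <- paste0("method", seq_len(k))
  x <- unlist(errors, use.names = FALSE)
  g <- factor(rep(names(errors), lengths(errors)), levels = names(errors))
  if (length(unique(x)) == 1) {
    kw <- list(statistic = c(H = 0), p.value = 1, parameter = c(df = k - 1))
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  rk <- rank(x)
  mean_ranks <- tapply(rk, g, mean)
  n_i <- tapply(rk, g, length)
  N <- length(x)
  combos <- utils::combn(names(errors), 2)
  zcrit <- stats::qnorm(1 - alpha / (k * (k - 1)))
  pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- combos[1, j]; b <- combos[2, j]
    diff <- abs(mean_ranks[[a]] - mean_ranks[[b]])
    cd <- zcrit * sqrt(N * (N + 1) / 12 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    tibble::tibble(
      method_a = a, method_b = b,
      mean_rank_diff = diff, critical_difference = cd,
      significant = length(unique(x)) > 1 && diff >= cd
    )
  })
  list(
    h = unname(kw$statistic),
    p_value = unname(kw$p.value),
    df = unname(kw$parameter),
    pairwise = pairwise
  )
}

#' Map per-unit errors back onto the grid
#'
#' Fills every cell of fine unit `j` with the signed error
#' `estimated_j - observed_j`, the raster behind under/over-estimation maps
#' (negative = underestimated, positive = overestimated).
#'
#' @param pairs An [evaluate()] result for one method.
#' @param fine_zones `cat_raster` of fine unit labels.
#' @return A `value_raster` of signed per-unit errors; cells of units missing
#'   from `pairs` raise an error.
#' @export
error_raster <- function(pairs, fine_zones) {
  zv <- as.vector(t(fine_zones$values))
  ok <- zv != fine_zones$grid$nodata_code
  uid <- unname(fine_zones$legend[as.character(zv[ok])])
  missing <- setdiff(unique(uid), pairs$unit_id)
  if (length(missing)) {
    stop("rasterized units missing from pairs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  err <- pairs$estimated - pairs$observed
  names(err) <- pairs$unit_id
  out <- rep(NA_real_, length(zv))
  out[ok] <- err[uid]
  value_raster(fine_zones$grid, out)
}

#' Full aggregation-based accuracy assessment
#'
#' Runs the whole protocol: aggregate the fine census to the coarse level,
#' rebuild the population surface from the coarse counts with each requested
#' method, sum the modelled cells back over the fine units and score against
#' the observed fine counts, then compare the methods' absolute-error
#' distributions by ranks.
#'
#' @param fine_census A [census_table()] at the fine level.
#' @param units An [admin_units()] tibble with fine and coarse levels.
#' @param lc,climate,urban_extent Model input rasters.
#' @param weights A `weight_table` for the dasymetric method. If `NULL`, the
#'   weights are estimated from the coarse-level census itself.
#' @param grid The shared [grid_spec()].
#' @param methods Any subset of `c("asiapop", "gpw", "grump")`.
#' @param urban_share GRUMP-style concentration share.
#' @param alpha Post-hoc significance level.
#' @return List with `pairs` (all methods stacked), `metrics`
#'   (per-method [error_metrics()] rows), `comparison`
#'   ([compare_methods()] output) and `rasters` (named list of modelled
#'   `value_raster`s).
#' @export
assess_methods <- function(fine_census, units, lc, climate, urban_extent,
                           grid, weights = NULL,
                           methods = c("asiapop", "gpw", "grump"),
                           urban_share = 0.5, alpha = 0.05) {
  methods <- match.arg(methods, several.ok = TRUE)
  fine_level <- max(units$level)
  fine_units <- units[units$level == fine_level, ]
  fine_zones <- rasterize_zones(fine_units, grid)
  agg <- aggregate_units(fine_census, units)
  coarse_zones <- rasterize_zones(agg$units, grid)
  if (is.null(weights) && "asiapop" %in% methods) {
    weights <- estimate_weights(agg$census, coarse_zones, lc, climate)
  }
  rasters <- list()
  for (m in methods) {
    rasters[[m]] <- switch(
      m,
      asiapop = dasymetric_redistribute(agg$census, coarse_zones, lc, climate, weights),
      gpw = areal_redistribute(agg$census, coarse_zones),
      grump = grump_redistribute(agg$census, coarse_zones, urban_extent, urban_share)
    )
  }
  pairs <- dplyr::bind_rows(lapply(methods, function(m) {
    tibble::as_tibble(evaluate(rasters[[m]], fine_zones, fine_census, method = m))
  }))
  metrics <- error_metrics(pairs)
  comparison <- if (length(methods) >= 2) {
    errs <- lapply(split(pairs, pairs$method), function(d) abs(d$estimated - d$observed))
    compare_methods(errs[methods], alpha = alpha)
  } else NULL
  list(pairs = pairs, metrics = metrics, comparison = comparison,
       rasters = rasters, weights = weights)
}
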