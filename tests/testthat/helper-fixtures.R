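# Small in-code fixtures shared across the suite.

# rectangle geometry in grid coordinates: list of one ring
rect_geom <- function(x0, x1, y0, y1) {
  list(cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
}

# a k x k grid split into two vertical half-plane units
two_unit_grid <- function(k = 2) {
  g <- grid_spec(k, k)
  u <- admin_units(
    unit_id = c("u1", "u2"), level = 1L,
    geometry = list(rect_geom(0, k / 2, 0, k), rect_geom(k / 2, k, 0, k))
  )
  list(grid = g, units = u)
}

# brute-force nearest-donor void fill: exhaustive scan of every donor cell,
# tie-break smallest row then column (independent oracle for fill_voids)
brute_fill <- function(lc) {
  g <- lc$grid
  v <- lc$values
  out <- v
  donors <- which(v != g$nodata_code, arr.ind = TRUE)
  for (r in seq_len(g$n_rows)) {
    for (c in seq_len(g$n_cols)) {
      if (v[r, c] == g$nodata_code) {
        d2 <- (donors[, 1] - r)^2 + (donors[, 2] - c)^2
        ord <- order(d2, donors[, 1], donors[, 2])
        best <- donors[ord[1], ]
        out[r, c] <- v[best[1], best[2]]
      }
    }
  }
  cat_raster(g, as.vector(t(out)), legend = lc$legend)
}

# definitional tie-corrected Kruskal-Wallis H from mean ranks (independent of
# stats::kruskal.test): H = (N-1) * SS_between_ranks / SS_total_ranks
brute_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  rk <- rank(x)
  rbar <- mean(rk)
  ss_between <- sum(tapply(rk, g, function(r) length(r) * (mean(r) - rbar)^2))
  ss_total <- sum((rk - rbar)^2)
  if (ss_total == 0) return(0)
  (length(x) - 1) * ss_between / ss_total
}

# a deterministic landscape small enough to reason about by hand:
# 4x4 grid, one unit, two classes in known cells
tiny_landscape <- function() {
  g <- grid_spec(4, 4)
  lc <- cat_raster(g, c(
    1, 1, 2, 2,
    1, 1, 2, 2,
    1, 1, 1, 2,
    1, 1, 1, 1
  ), legend = c(`1` = "low", `2` = "high"))
  climate <- cat_raster(g, rep(1L, 16))
  units <- admin_units("only", 1L, geometry = list(rect_geom(0, 4, 0, 4)))
  list(grid = g, lc = lc, climate = climate, units = units)
}
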