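#' The fixed nine-class land-cover legend
#'
#' The model legend has nine land-cover types, two of which are the settlement
#' classes: `URBAN` (code 8) and `RURAL_SETTLEMENT` (code 9). The remaining
#' seven labels are configurable; the settlement codes are reserved because
#' the urban/rural split drives both weighting and growth-rate assignment.
#'
#' @param labels Optional character vector of length 7 renaming the
#'   non-settlement classes (codes 1-7).
#' @return Named character vector `code -> label`.
#' @export
lc_legend <- function(labels = c("water", "forest", "shrubland", "grassland",
                                 "cropland", "wetland", "bare")) {
  stopifnot(length(labels) == 7)
  stats::setNames(c(labels, "URBAN", "RURAL_SETTLEMENT"), as.character(1:9))
}

#' @rdname lc_legend
#' @export
URBAN_CODE <- 8L

#' @rdname lc_legend
#' @export
RURAL_SETTLEMENT_CODE <- 9L

settlement_codes <- function() c(URBAN_CODE, RURAL_SETTLEMENT_CODE)

#' Build a reclassification table
#'
#' Maps source land-cover codes onto the model's target legend. Codes listed
#' as void (cloud, shadow, no-data in the source product) are mapped to the
#' nodata sentinel so [fill_voids()] can repair them.
#'
#' @param map Named integer vector or two-column data frame
#'   (`source_code`, `target_code`).
#' @param void_codes Integer source codes to treat as voids.
#' @return A tibble of class `reclass_table` with columns `source_code`,
#'   `target_code` and attribute `void_codes`.
#' @export
reclass_table <- function(map, void_codes = integer()) {
  if (is.data.frame(map)) {
    tab <- tibble::tibble(
      source_code = as.integer(map$source_code),
      target_code = as.integer(map$target_code)
    )
  } else {
    tab <- tibble::tibble(
      source_code = as.integer(names(map)),
      target_code = as.integer(unname(map))
    )
  }
  structure(tab, void_codes = as.integer(void_codes),
            class = c("reclass_table", class(tab)))
}

#' Read a reclassification table from CSV
#'
#' Expects columns `source_code,target_code`; rows whose `target_code` is the
#' keyword `void` declare void source codes.
#'
#' @param path CSV path.
#' @return A [reclass_table()].
#' @export
read_reclass_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  is_void <- tolower(trimws(raw$target_code)) == "void"
  reclass_table(
    data.frame(
      source_code = as.integer(raw$source_code[!is_void]),
      target_code = as.integer(raw$target_code[!is_void])
    ),
    void_codes = as.integer(raw$source_code[is_void])
  )
}

#' Reclassify a land-cover raster to the model legend
#'
#' Every source code present in the raster must either appear in the table or
#' be a declared void code; unmapped codes are a hard failure listing the
#' offenders. Void codes map to the nodata sentinel for later filling.
#'
#' @param lc Source `cat_raster`.
#' @param table A [reclass_table()].
#' @param legend Target legend for the output (default [lc_legend()]).
#' @return A `cat_raster` in target codes.
#' @export
reclassify <- function(lc, table, legend = lc_legend()) {
  v <- as.vector(t(lc$values))
  nodata <- lc$grid$nodata_code
  voids <- attr(table, "void_codes")
  known <- c(table$source_code, voids, nodata)
  unmapped <- setdiff(unique(v), known)
  if (length(unmapped)) {
    stop("unmapped source codes: ", paste(sort(unmapped), collapse = ", "),
         call. = FALSE)
  }
  out <- v
  out[v %in% voids] <- nodata
  idx <- match(v, table$source_code)
  hit <- !is.na(idx) & !(v %in% voids) & v != nodata
  out[hit] <- table$target_code[idx[hit]]
  cat_raster(lc$grid, out, legend = legend)
}

# Shift matrix by (dr, dc): out[r, c] = m[r + dr, c + dc], NA out of bounds.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Neighbour offsets with squared distance <= r2max, sorted by
# (squared distance, dr, dc) — the deterministic nearest-donor order.
sorted_offsets <- function(rad) {
  dr <- rep(-rad:rad, each = 2 * rad + 1)
  dc <- rep(-rad:rad, times = 2 * rad + 1)
  keep <- !(dr == 0 & dc == 0)
  dr <- dr[keep]; dc <- dc[keep]
  d2 <- dr^2 + dc^2
  ord <- order(d2, dr, dc)
  cbind(d2 = d2[ord], dr = dr[ord], dc = dc[ord])
}

#' Fill nodata voids by nearest neighbour
#'
#' Every void cell takes the class of its nearest non-void cell, by Euclidean
#' distance between cell centers. Among equidistant donors the one with the
#' smallest row index, then smallest column index, wins — a deterministic tie
#' rule matching the common GIS nibble operation's spirit. The output has
#' zero void cells; non-void cells are never altered, and the operation is
#' idempotent.
#'
#' @param lc A `cat_raster` possibly containing nodata cells.
#' @return A void-free `cat_raster`.
#' @export
fill_voids <- function(lc) {
  nodata <- lc$grid$nodata_code
  v <- lc$values
  void <- v == nodata
  if (!any(void)) return(lc)
  if (all(void)) stop("all-void raster: no donor cells", call. = FALSE)
  donor <- v
  donor[void] <- NA  # only original non-void cells may donate
  out <- v
  remaining <- void
  rad <- 1L
  applied_d2 <- -1
  while (any(remaining)) {
    offs <- sorted_offsets(rad)
    # only offsets whose full distance ring fits in the current window
    offs <- offs[offs[, "d2"] <= rad^2 & offs[, "d2"] > applied_d2, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      if (!any(remaining)) break
      s <- shift_matrix(donor, offs[k, "dr"], offs[k, "dc"])
      fill <- remaining & !is.na(s)
      if (any(fill)) {
        out[fill] <- s[fill]
        remaining[fill] <- FALSE
      }
    }
    applied_d2 <- rad^2
    rad <- rad * 2L
    if (rad > 4L * max(dim(v))) stop("void fill failed to converge", call. = FALSE)
  }
  cat_raster(lc$grid, as.vector(t(out)), legend = lc$legend)
}

#' Split settlement into urban and rural via an urban-extent overlay
#'
#' Source land cover does not distinguish high-density urban cores from small
#' rural settlements, so an external urban-extent footprint (night-light
#' derived in the regional products) supplies the split: a cell is "built" if
#' its land-cover class is a settlement class or any supplied built/residential
#' mask flags it; built cells inside the urban extent become `URBAN`, built
#' cells outside become `RURAL_SETTLEMENT`; non-built cells are unchanged.
#'
#' @param lc A `cat_raster` in the model legend.
#' @param built_masks List of binary `cat_raster`s (1 = built); fused by
#'   logical OR. May be empty.
#' @param urban_extent Binary `cat_raster` (1 = urban).
#' @return A `cat_raster` with settlement cells recoded.
#' @export
refine_settlements <- function(lc, built_masks = list(), urban_extent) {
  do.call(assert_same_grid, c(list(lc), built_masks, list(urban_extent)))
  v <- lc$values
  built <- v %in% settlement_codes()
  dim(built) <- dim(v)
  for (m in built_masks) built <- built | (m$values == 1L)
  urb <- urban_extent$values == 1L
  out <- v
  out[built & urb] <- URBAN_CODE
  out[built & !urb] <- RURAL_SETTLEMENT_CODE
  legend <- lc$legend
  for (code in settlement_codes()) {
    if (!as.character(code) %in% names(legend)) {
      legend[as.character(code)] <- c("URBAN", "RURAL_SETTLEMENT")[code - 7L]
    }
  }
  cat_raster(lc$grid, as.vector(t(out)), legend = legend)
}
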