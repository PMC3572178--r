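#' Define the georeferencing of a raster grid
#'
#' A `grid_spec` fixes the shape and placement of every raster taking part in
#' one model run. All rasters combined in a pixel-wise operation must share an
#' identical spec; this is asserted before any such operation.
#'
#' The origin is the outer corner of cell (0, 0): cell `(r, c)` (0-based)
#' covers the half-open square
#' `[origin_x + c*cell_size, origin_x + (c+1)*cell_size) x
#'  [origin_y + r*cell_size, origin_y + (r+1)*cell_size)`,
#' so the cell center sits at `origin + (index + 0.5) * cell_size`.
#' Row index increases away from `origin_y`.
#'
#' @param n_rows,n_cols Grid dimensions, at least 1.
#' @param origin_x,origin_y Coordinates of the grid origin, in grid units.
#' @param cell_size Side length of a (square) cell in grid units. The
#'   production resolution of the regional products this package emulates is
#'   8.33e-4 degrees (about 100 m at the equator).
#' @param crs_label Free-text label for the coordinate reference system.
#' @param nodata_code Reserved integer sentinel for missing categorical values;
#'   never a valid class code.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(4, 4)
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = 0,
                      cell_size = 1, crs_label = "grid", nodata_code = -1L) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    is.numeric(cell_size), cell_size > 0
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size), crs_label = as.character(crs_label),
      nodata_code = as.integer(nodata_code)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, cell_size %g, origin (%g, %g), crs '%s', nodata %d\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
    x$crs_label, x$nodata_code
  ))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%g", x$n_rows, x$n_cols, x$cell_size)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b)))
}

assert_same_grid <- function(..., what = "rasters") {
  rs <- list(...)
  specs <- lapply(rs, function(r) if (inherits(r, "grid_spec")) r else r$grid)
  for (i in seq_along(specs)[-1]) {
    if (!grids_identical(specs[[1]], specs[[i]])) {
      stop(sprintf("grid mismatch: all %s must share an identical grid_spec", what),
           call. = FALSE)
    }
  }
  invisible(specs[[1]])
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell: 0-based `row`, `col` and the
#'   center coordinates `x`, `y`, in row-major order (row varies slowest).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  tibble::tibble(
    row = rows, col = cols,
    x = grid$origin_x + (cols + 0.5) * grid$cell_size,
    y = grid$origin_y + (rows + 0.5) * grid$cell_size
  )
}

new_raster <- function(grid, values, kind, legend = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  m <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  structure(
    list(grid = grid, values = m, legend = legend),
    class = c(paste0(kind, "_raster"), "pw_raster")
  )
}

#' Construct a categorical raster
#'
#' Integer-coded grid used for land cover, climate zones, admin-zone labels and
#' urban masks. Every non-nodata code must appear in the legend.
#'
#' @param grid A [grid_spec()].
#' @param values Integer codes, either a matrix (`n_rows` x `n_cols`, row 0 of
#'   the grid in matrix row 1) or a row-major vector.
#' @param legend Named character vector mapping `code -> label`; names are the
#'   integer codes. If `NULL`, a legend is synthesised from the codes present.
#' @return A `cat_raster`.
#' @examples
#' cat_raster(grid_spec(2, 2), c(1, 1, 2, 2), legend = c(`1` = "water", `2` = "forest"))
#' @export
cat_raster <- function(grid, values, legend = NULL) {
  v <- as.integer(round(values))
  if (is.null(legend)) {
    codes <- sort(unique(v[v != grid$nodata_code & !is.na(v)]))
    legend <- stats::setNames(as.character(codes), as.character(codes))
  }
  r <- new_raster(grid, v, "cat", legend = legend)
  validate_cat_raster(r)
  r
}

validate_cat_raster <- function(r) {
  v <- r$values
  codes <- unique(v[v != r$grid$nodata_code & !is.na(v)])
  missing <- setdiff(as.character(codes), names(r$legend))
  if (length(missing)) {
    stop("codes without legend entry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(dim(v), c(r$grid$n_rows, r$grid$n_cols))) {
    stop("raster dimensions do not match grid_spec", call. = FALSE)
  }
  invisible(r)
}

#' Construct a real-valued raster
#'
#' Holds persons-per-cell population surfaces or signed per-cell errors.
#' Values must be finite where not nodata; population surfaces are
#' additionally required to be nonnegative (checked by the producing
#' operations, not here, since error rasters are legitimately signed).
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix or row-major vector; `NA` marks nodata.
#' @return A `value_raster`.
#' @export
value_raster <- function(grid, values) {
  v <- as.numeric(values)
  if (any(is.infinite(v))) stop("value_raster must be finite where not NA", call. = FALSE)
  new_raster(grid, v, "value")
}

#' @export
print.pw_raster <- function(x, ...) {
  kind <- if (inherits(x, "cat_raster")) "cat_raster" else "value_raster"
  cat(sprintf("<%s> %s\n", kind, format(x$grid)))
  if (!is.null(x$legend)) {
    cat("legend:", paste(sprintf("%s=%s", names(x$legend), x$legend), collapse = ", "), "\n")
  }
  if (x$grid$n_rows <= 12 && x$grid$n_cols <= 12) print(x$values)
  invisible(x)
}

#' Convert a raster to a tidy cell table
#'
#' @param x A `cat_raster` or `value_raster`.
#' @param ... Unused.
#' @return A tibble with 0-based `row`, `col`, center `x`, `y` and `value`
#'   (`NA` for nodata cells).
#' @method as_tibble pw_raster
#' @export
as_tibble.pw_raster <- function(x, ...) {
  ct <- cell_centers(x$grid)
  v <- as.vector(t(x$values))
  if (inherits(x, "cat_raster")) v[v == x$grid$nodata_code] <- NA
  ct$value <- v
  ct
}

raster_is_nodata <- function(r) {
  if (inherits(r, "cat_raster")) r$values == r$grid$nodata_code else is.na(r$values)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of values from the top row of the map down. The package convention
#' places grid row 0 at `yllcorner`, so rows are reversed on the way in and
#' out.
#'
#' @param path File path.
#' @param type `"cat"` for integer categorical rasters, `"value"` for
#'   real-valued rasters.
#' @param legend Optional legend for categorical rasters.
#' @param crs_label Label recorded on the resulting `grid_spec`.
#' @return `read_ascii_grid()` returns a `cat_raster` or `value_raster`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, type = c("cat", "value"), legend = NULL,
                            crs_label = "grid") {
  type <- match.arg(type)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  g <- grid_spec(
    n_rows = hdr$nrows, n_cols = hdr$ncols,
    origin_x = hdr$xllcorner, origin_y = hdr$yllcorner,
    cell_size = hdr$cellsize, crs_label = crs_label,
    nodata_code = if (type == "cat") as.integer(nodata) else -9999L
  )
  body <- strsplit(trimws(lines[i:length(lines)]), "\\s+")
  vals <- suppressWarnings(as.numeric(unlist(body)))
  m <- matrix(vals, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m <- m[g$n_rows:1, , drop = FALSE]  # file is top-down; grid row 0 is at the bottom
  if (type == "cat") {
    cat_raster(g, as.vector(t(m)), legend = legend)
  } else {
    m[m == nodata] <- NA
    value_raster(g, as.vector(t(m)))
  }
}

#' @rdname read_ascii_grid
#' @param r Raster to write.
#' @export
write_ascii_grid <- function(r, path) {
  g <- r$grid
  if (inherits(r, "cat_raster")) {
    m <- r$values
    nodata <- g$nodata_code
  } else {
    m <- r$values
    nodata <- -9999
    m[is.na(m)] <- nodata
  }
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(m[g$n_rows:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
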