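#' Rectangular metric grid
#'
#' `grid2d()` builds the basic raster container used throughout the package:
#' a matrix of cell values on a regular metric grid. Row 1 is the northern
#' edge; `NA` marks nodata cells. The origin is the outer corner of the
#' top-left cell, so cell `(r, c)` has its centre at
#' `x = origin[1] + (c - 0.5) * cell_size`,
#' `y = origin[2] - (r - 0.5) * cell_size`.
#'
#' @param values numeric matrix (rows x cols); `NA` = nodata.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, `(x, y)` of the outer top-left corner.
#' @param crs_tag free-text identifier of a projected (metric) CRS.
#' @return an object of class `grid2d`.
#' @export
grid2d <- function(values, cell_size = 1000, origin = c(0, nrow(values) * cell_size),
                   crs_tag = "local-metric") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite coordinates")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must contain at least one cell")
  if (any(!is.finite(values[!is.na(values)])))
    stop("unmasked values must be finite")
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin), crs_tag = crs_tag),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid2d> %d x %d cells, cell_size %g m, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2], x$crs_tag))
  ok <- !is.na(v)
  cat(sprintf("  %d unmasked cells; range [%g, %g]\n", sum(ok),
              if (any(ok)) min(v[ok]) else NA, if (any(ok)) max(v[ok]) else NA))
  invisible(x)
}

#' @export
dim.grid2d <- function(x) dim(x$values)

grid_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    identical(a$crs_tag, b$crs_tag)
}

stopifnot_aligned <- function(...) {
  gs <- list(...)
  for (g in gs[-1]) if (!grid_compatible(gs[[1]], g))
    stop("grids are not aligned (dimensions, cell size, origin and crs must match)")
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param grid a `grid2d`.
#' @param rows,cols integer row/column indices (recycled together).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centers <- function(grid, rows, cols) {
  data.frame(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
             y = grid$origin[2] - (rows - 0.5) * grid$cell_size)
}

#' Locate points on a grid
#'
#' Maps x/y coordinates to row/column indices; points outside the grid
#' extent get `NA` indices.
#'
#' @inheritParams cell_centers
#' @param x,y point coordinates in grid units.
#' @return data.frame with columns `row`, `col`, `cell` (matrix linear index).
#' @export
cell_from_xy <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  bad <- is.na(row) | is.na(col) | row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col, cell = (col - 1L) * nr + row)
}

#' Extract grid values at point locations
#'
#' @inheritParams cell_from_xy
#' @return numeric vector; `NA` for points off the grid or on nodata cells.
#' @export
extract_at <- function(grid, x, y) {
  idx <- cell_from_xy(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$cell)
  out[ok] <- grid$values[idx$cell[ok]]
  out
}

#' Stack of aligned layers
#'
#' A `layer_stack` holds named `grid2d` layers on a shared geometry plus a
#' `kinds` vector tagging each layer `"continuous"` or `"categorical"` and an
#' optional `families` vector used by scenario generation to find
#' temperature-like and precipitation-like layers.
#'
#' @param layers named list of `grid2d` objects on one geometry.
#' @param kinds named character, `"continuous"` or `"categorical"` per layer.
#' @param families optional named character (e.g. `"temperature"`,
#'   `"precipitation"`, `"topography"`, `"landcover"`, `"footprint"`,
#'   `"other"`).
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(layers, kinds, families = NULL) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list")
  if (!all(names(layers) %in% names(kinds)))
    stop("every layer needs an entry in kinds")
  kinds <- kinds[names(layers)]
  if (!all(kinds %in% c("continuous", "categorical")))
    stop("kinds must be 'continuous' or 'categorical'")
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "grid2d")) stop("layer '", nm, "' is not a grid2d")
    if (!grid_compatible(layers[[1]], layers[[nm]]))
      stop("layer '", nm, "' is not aligned with the stack")
    if (kinds[[nm]] == "categorical") {
      v <- layers[[nm]]$values
      if (any(v[!is.na(v)] != round(v[!is.na(v)])))
        stop("categorical layer '", nm, "' must hold integer class codes")
    }
  }
  if (is.null(families)) {
    families <- stats::setNames(rep("other", length(layers)), names(layers))
  } else {
    missing <- setdiff(names(layers), names(families))
    families[missing] <- "other"
    families <- families[names(layers)]
  }
  structure(list(layers = layers, kinds = kinds, families = families),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<layer_stack> %d layers, %d x %d cells, cell_size %g m\n",
              length(x$layers), nrow(g$values), ncol(g$values), g$cell_size))
  cat(sprintf("  %s (%s)\n", names(x$layers), x$kinds), sep = "")
  invisible(x)
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text raster exchange format: a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by
#' rows of values north to south.
#'
#' @param grid a `grid2d`.
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `grid2d`.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  v <- grid$values
  nodata <- -9999
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2] - nrow(v) * grid$cell_size),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %d", nodata))
  vv <- v; vv[is.na(vv)] <- nodata
  lines <- apply(vv, 1L, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs_tag CRS label to attach on read.
#' @export
read_ascii_grid <- function(path, crs_tag = "local-metric") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  m[m == nodata] <- NA_real_
  grid2d(m, cell_size = cs, origin = c(xll, yll + nr * cs), crs_tag = crs_tag)
}

#' Write a layer stack as ASCII rasters plus an index file
#'
#' One `.asc` file per layer and a `stack.yaml` index recording layer
#' names, kinds and families.
#'
#' @param stack a `layer_stack`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  yaml::write_yaml(list(layers = names(stack$layers),
                        kinds = as.list(stack$kinds),
                        families = as.list(stack$families)),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  idx <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  layers <- lapply(idx$layers, function(nm)
    read_ascii_grid(file.path(dir, paste0(nm, ".asc"))))
  names(layers) <- idx$layers
  layer_stack(layers, unlist(idx$kinds), unlist(idx$families))
}

# seeded evaluation that leaves the caller's RNG untouched
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# deterministic sub-seed fan-out for pipeline stages
sub_seed <- function(seed, tag) {
  ch <- utf8ToInt(as.character(tag))
  h <- sum(ch * seq_along(ch)) %% 104729
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
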