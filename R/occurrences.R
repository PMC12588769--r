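#' Thin occurrences to one record per grid cell
#'
#' Keeps at most one record per grid cell. When several records share a
#' cell, the record with the most recent year wins; remaining ties fall
#' back to input order. Records off the grid are rejected as
#' `outside_polygon` (they cannot be assigned a cell).
#'
#' @param occ occurrence data.frame with columns `x`, `y` and optionally
#'   `elevation`, `year`.
#' @param grid a `grid2d` defining the thinning cells.
#' @return a `filter_report`: list with `kept` (data.frame) and `rejected`
#'   (data.frame with a `reason` column).
#' @export
thin_occurrences <- function(occ, grid) {
  occ <- as.data.frame(occ)
  if (nrow(occ) == 0L)
    return(filter_report(occ, cbind(occ, reason = character(0))))
  idx <- cell_from_xy(grid, occ$x, occ$y)
  reason <- rep(NA_character_, nrow(occ))
  reason[is.na(idx$cell)] <- "outside_polygon"
  yr <- if ("year" %in% names(occ)) occ$year else rep(NA_real_, nrow(occ))
  yr[is.na(yr)] <- -Inf
  ord <- order(idx$cell, -yr, seq_len(nrow(occ)))
  seen <- duplicated(idx$cell[ord])
  dup <- logical(nrow(occ)); dup[ord[seen]] <- TRUE
  reason[is.na(reason) & dup] <- "duplicate_cell"
  filter_report(occ[is.na(reason), , drop = FALSE],
                data.frame(occ[!is.na(reason), , drop = FALSE],
                           reason = reason[!is.na(reason)]))
}

filter_report <- function(kept, rejected) {
  structure(list(kept = kept, rejected = rejected), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, rejected %d\n",
              nrow(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

#' Filter occurrences by range polygon, elevation and land cover
#'
#' Applies the three occurrence exclusion rules in order: (1) the point
#' must fall inside the range polygon; (2) its elevation (the record's own
#' value if present, else the elevation layer at its cell) must lie within
#' `[elev_min - elev_buffer, elev_max + elev_buffer]`, bounds inclusive;
#' (3) the land-cover class at its cell must be one of the allowed habitat
#' classes. The first failing rule is recorded as the rejection reason;
#' points off the raster extent are rejected as `outside_polygon`.
#'
#' @param occ occurrence data.frame (`x`, `y`, optional `elevation`).
#' @param range_polygon two-column matrix of polygon vertices (a closed or
#'   open ring), or `NULL` to skip the polygon rule.
#' @param elevation `grid2d` of elevations.
#' @param elev_min,elev_max species elevation range in metres.
#' @param elev_buffer buffer added to both ends of the range (default 100 m).
#' @param landcover categorical `grid2d` of land-cover codes.
#' @param allowed_classes integer codes accepted as habitat.
#' @return a `filter_report`.
#' @export
filter_occurrences <- function(occ, range_polygon, elevation,
                               elev_min, elev_max, elev_buffer = 100,
                               landcover = NULL, allowed_classes = NULL) {
  occ <- as.data.frame(occ)
  if (elev_min > elev_max) stop("elev_min must be <= elev_max")
  n <- nrow(occ)
  reason <- rep(NA_character_, n)
  if (n == 0L) return(filter_report(occ, cbind(occ, reason = character(0))))
  idx <- cell_from_xy(elevation, occ$x, occ$y)
  off <- is.na(idx$cell)
  reason[off] <- "outside_polygon"
  if (!is.null(range_polygon)) {
    inside <- mgcv::in.out(close_ring(range_polygon),
                           cbind(occ$x, occ$y))
    reason[is.na(reason) & !inside] <- "outside_polygon"
  }
  elev_rec <- if ("elevation" %in% names(occ)) occ$elevation
              else rep(NA_real_, n)
  elev_use <- ifelse(is.na(elev_rec), extract_at(elevation, occ$x, occ$y),
                     elev_rec)
  bad_elev <- is.na(elev_use) | elev_use < elev_min - elev_buffer |
    elev_use > elev_max + elev_buffer
  reason[is.na(reason) & bad_elev] <- "elevation_out_of_range"
  if (!is.null(landcover) && !is.null(allowed_classes)) {
    lc <- extract_at(landcover, occ$x, occ$y)
    bad_lc <- is.na(lc) | !(lc %in% allowed_classes)
    reason[is.na(reason) & bad_lc] <- "landcover_mismatch"
  }
  filter_report(occ[is.na(reason), , drop = FALSE],
                data.frame(occ[!is.na(reason), , drop = FALSE],
                           reason = reason[!is.na(reason)]))
}

close_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (!identical(poly[1, ], poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Draw pseudo-absence sets from the study grid
#'
#' Draws `n_sets` independent sets of `n` cell centres, uniformly without
#' replacement within each set, from the unmasked cells of `valid_mask`
#' excluding any presence cell. Each set is reproducible from
#' `(seed, set_id)`.
#'
#' @param valid_mask `grid2d`; unmasked (non-`NA`) cells are candidates.
#' @param n points per set.
#' @param presence_cells integer linear cell indices occupied by presences
#'   (e.g. from [cell_from_xy()]).
#' @param n_sets number of sets.
#' @param seed base RNG seed.
#' @return list of `pseudo_absence_set` objects: `set_id`, `points`
#'   (data.frame `x`, `y`), `cells`, `seed`.
#' @export
sample_pseudo_absences <- function(valid_mask, n, presence_cells = integer(0),
                                   n_sets = 3, seed = 1L) {
  cand <- setdiff(which(!is.na(valid_mask$values)), presence_cells)
  if (length(cand) < n)
    stop("requested ", n, " pseudo-absences but only ", length(cand),
         " valid non-presence cells are available")
  nr <- nrow(valid_mask$values)
  lapply(seq_len(n_sets), function(set_id) {
    cells <- cand[with_seed(sub_seed(seed, paste0("pa", set_id)),
                            sample.int(length(cand), n))]
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    structure(list(set_id = set_id,
                   points = cell_centers(valid_mask, rows, cols),
                   cells = cells, seed = seed),
              class = "pseudo_absence_set")
  })
}

#' Read / write occurrence CSV
#'
#' @param occ occurrence data.frame.
#' @param path CSV path.
#' @return `read_occurrences` returns a data.frame with at least `x`, `y`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(occ)))
    stop("occurrence CSV needs columns x and y")
  occ
}

#' Write points or a polygon as GeoJSON
#'
#' @param occ occurrence data.frame (`x`, `y`, extra columns become
#'   properties).
#' @param path output path.
#' @export
write_occurrences_geojson <- function(occ, path) {
  feats <- lapply(seq_len(nrow(occ)), function(i) {
    props <- as.list(occ[i, setdiff(names(occ), c("x", "y")), drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(occ$x[i], occ$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_occurrences_geojson
#' @param poly two-column vertex matrix.
#' @export
write_polygon_geojson <- function(poly, path) {
  ring <- close_ring(poly)
  jsonlite::write_json(
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = stats::setNames(list(), character(0))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_occurrences_geojson
#' @export
read_polygon_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  geom <- if (!is.null(j$geometry)) j$geometry else j
  ring <- geom$coordinates[[1]]
  do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
}
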