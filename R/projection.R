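#' Resolve retained variables against a base stack
#'
#' Turns the retained multi-scale variable names (e.g. `"tri"` or
#' `"landcover_forest"`) and their chosen radii into an explicit recipe:
#' which stack layer to aggregate, with which focal statistic, at which
#' radius. The recipe is what allows the fitted ensemble to be re-applied
#' to any scenario stack.
#'
#' @param profiles a `scale_profiles` object.
#' @param retained character vector of retained variable base names.
#' @param stack the base `layer_stack`.
#' @param classes categorical class map as in [build_multiscale_stack()].
#' @return data.frame with columns `name` (feature column name), `base`,
#'   `layer`, `class_code`, `radius_km`.
#' @export
ms_variables <- function(profiles, retained, stack, classes = list()) {
  rows <- lapply(retained, function(v) {
    p <- unclass(profiles)[[v]]
    if (is.null(p) || is.na(p$chosen_radius_km))
      stop("variable '", v, "' has no chosen scale")
    r <- p$chosen_radius_km
    if (v %in% names(stack$layers)) {
      data.frame(name = sprintf("%s_r%gkm", v, r), base = v, layer = v,
                 class_code = NA_real_, radius_km = r)
    } else {
      for (lay in names(classes)) {
        for (ci in seq_along(classes[[lay]])) {
          if (v == paste0(lay, "_", names(classes[[lay]])[ci]))
            return(data.frame(name = sprintf("%s_r%gkm", v, r), base = v,
                              layer = lay,
                              class_code = classes[[lay]][[ci]],
                              radius_km = r))
        }
      }
      stop("cannot resolve variable '", v, "' against the stack")
    }
  })
  do.call(rbind, rows)
}

#' Compute the feature grids of a variable recipe on a stack
#'
#' @param stack a `layer_stack`.
#' @param variables recipe data.frame from [ms_variables()].
#' @return named list of `grid2d`, keyed by feature name.
#' @export
compute_feature_grids <- function(stack, variables) {
  cell_km <- stack$layers[[1]]$cell_size / 1000
  out <- list()
  for (i in seq_len(nrow(variables))) {
    lay <- variables$layer[i]
    if (!lay %in% names(stack$layers))
      stop("scenario stack lacks required layer '", lay, "'")
    rc <- variables$radius_km[i] / cell_km
    g <- if (is.na(variables$class_code[i]))
      focal_mean(stack$layers[[lay]], rc)
    else focal_fraction(stack$layers[[lay]], variables$class_code[i], rc)
    out[[variables$name[i]]] <- g
  }
  out
}

#' Extract a feature data.frame at point locations
#'
#' @param feature_grids named list of `grid2d` from [compute_feature_grids()].
#' @param x,y point coordinates.
#' @return data.frame, one column per feature.
#' @export
features_at <- function(feature_grids, x, y) {
  as.data.frame(lapply(feature_grids, function(g) extract_at(g, x, y)))
}

#' Project ensemble suitability onto a (scenario) stack
#'
#' Recomputes every retained variable's focal layer at its chosen radius on
#' the given stack, scores the ensemble at each jointly unmasked cell, and
#' returns the suitability surface. Projecting the training stack
#' reproduces the training-time prediction.
#'
#' @param ensemble an `sdm_ensemble` whose `variables` recipe is set (the
#'   pipeline sets it; see [ms_variables()]).
#' @param stack the base or scenario `layer_stack`.
#' @return a `grid2d` of suitabilities in `[0, 1]`.
#' @export
project_suitability <- function(ensemble, stack) {
  if (is.null(ensemble$variables))
    stop("ensemble carries no variable recipe; set ensemble$variables")
  fg <- compute_feature_grids(stack, ensemble$variables)
  tmpl <- fg[[1]]
  ok <- Reduce(`&`, lapply(fg, function(g) !is.na(g$values)))
  cells <- which(ok)
  M <- as.data.frame(lapply(fg, function(g) g$values[cells]))
  out <- matrix(NA_real_, nrow(tmpl$values), ncol(tmpl$values))
  out[cells] <- predict(ensemble, M)
  grid2d(out, tmpl$cell_size, tmpl$origin, tmpl$crs_tag)
}

#' Average suitability maps across climate models
#'
#' @param suitability_maps list of aligned `grid2d` suitability maps.
#' @return cellwise mean `grid2d`.
#' @export
average_gcms <- function(suitability_maps) {
  if (!length(suitability_maps)) stop("need at least one map")
  do.call(stopifnot_aligned, suitability_maps)
  tmpl <- suitability_maps[[1]]
  vals <- Reduce(`+`, lapply(suitability_maps, function(g) g$values)) /
    length(suitability_maps)
  grid2d(vals, tmpl$cell_size, tmpl$origin, tmpl$crs_tag)
}

#' Binarize a suitability map
#'
#' Cells with suitability at or above the threshold become habitat (1),
#' the rest non-habitat (0); the inclusive rule keeps the maxSSS threshold
#' candidate itself suitable.
#'
#' @param suitability a `grid2d` in `[0, 1]`.
#' @param threshold cutoff in `[0, 1]`.
#' @param scenario_label,period_label optional labels carried on the map.
#' @return a `binary_map`: `grid2d` plus threshold and labels.
#' @export
binarize <- function(suitability, threshold, scenario_label = "current",
                     period_label = "current") {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  v <- (suitability$values >= threshold) + 0
  structure(list(grid = grid2d(v, suitability$cell_size, suitability$origin,
                               suitability$crs_tag),
                 threshold_used = threshold,
                 scenario_label = scenario_label,
                 period_label = period_label),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  v <- x$grid$values
  cat(sprintf("<binary_map> %s/%s, threshold %.3f, %d suitable cells\n",
              x$scenario_label, x$period_label, x$threshold_used,
              sum(v == 1, na.rm = TRUE)))
  invisible(x)
}

#' Constrain a binary map by dispersal ability
#'
#' `"perfect"` dispersal returns the map unchanged. `"limited"` dispersal
#' zeroes suitable cells whose centres lie farther than `buffer_km` from
#' the range polygon (cells inside the polygon are at distance 0).
#'
#' @param binary a `binary_map`.
#' @param mode `"perfect"` or `"limited"`.
#' @param range_polygon two-column vertex matrix (required for limited).
#' @param buffer_km buffer distance in kilometres.
#' @return a `binary_map`.
#' @export
apply_dispersal_mask <- function(binary, mode = c("perfect", "limited"),
                                 range_polygon = NULL, buffer_km = 110) {
  mode <- match.arg(mode)
  if (mode == "perfect") return(binary)
  if (is.null(range_polygon)) stop("limited dispersal requires a range polygon")
  poly <- close_ring(range_polygon)
  g <- binary$grid
  v <- g$values
  suit <- which(!is.na(v) & v == 1)
  if (length(suit)) {
    nr <- nrow(v)
    rows <- (suit - 1L) %% nr + 1L
    cols <- (suit - 1L) %/% nr + 1L
    ctr <- cell_centers(g, rows, cols)
    inside <- mgcv::in.out(poly, cbind(ctr$x, ctr$y))
    d <- rep(0, length(suit))
    outp <- which(!inside)
    if (length(outp))
      d[outp] <- point_poly_distance(ctr$x[outp], ctr$y[outp], poly)
    v[suit[d > buffer_km * 1000]] <- 0
  }
  structure(list(grid = grid2d(v, g$cell_size, g$origin, g$crs_tag),
                 threshold_used = binary$threshold_used,
                 scenario_label = binary$scenario_label,
                 period_label = paste0(binary$period_label, "_limited")),
            class = "binary_map")
}

# minimum distance from points to a polygon boundary
point_poly_distance <- function(px, py, poly) {
  n <- nrow(poly) - 1L
  d2 <- matrix(Inf, length(px), n)
  for (i in seq_len(n)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1, 1]; by <- poly[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px))
         else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2[, i] <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
  }
  sqrt(apply(d2, 1L, min))
}

#' Habitat change accounting between two binary maps
#'
#' Areas of stable, gained and lost habitat plus the derived rates:
#' net change = 100 (future - current) / current, and turnover =
#' 100 (gain + loss) / (current + gain). Raw values are kept at full
#' precision; use [format_change_summary()] for the one-decimal report.
#'
#' @param current,future aligned `binary_map`s.
#' @param cell_area_km2 nominal area of one cell (default 1).
#' @return a `change_summary` list: `area_current`, `area_future`,
#'   `area_stable`, `area_gain`, `area_loss`, `net_change_pct`,
#'   `turnover_pct`, `undefined` (TRUE when current + gain is empty).
#' @export
change_metrics <- function(current, future, cell_area_km2 = 1) {
  stopifnot_aligned(current$grid, future$grid)
  cv <- current$grid$values; fv <- future$grid$values
  ok <- !is.na(cv) & !is.na(fv)
  c1 <- cv == 1 & ok; f1 <- fv == 1 & ok
  stable <- sum(c1 & f1); gain <- sum(!c1 & f1); loss <- sum(c1 & !f1)
  a <- function(n) n * cell_area_km2
  cur <- a(stable + loss); fut <- a(stable + gain)
  undefined <- (cur + a(gain)) == 0
  structure(list(area_current = cur, area_future = fut,
                 area_stable = a(stable), area_gain = a(gain),
                 area_loss = a(loss),
                 net_change_pct = if (cur > 0) 100 * (fut - cur) / cur
                                  else NA_real_,
                 turnover_pct = if (!undefined)
                   100 * (a(gain) + a(loss)) / (cur + a(gain)) else NA_real_,
                 undefined = undefined),
            class = "change_summary")
}

#' Change accounting directly from area components
#'
#' Applies the same formulas as [change_metrics()] to already-measured
#' stable/gain/loss areas (e.g. a published accounting table).
#'
#' @param area_stable,area_gain,area_loss areas in km^2.
#' @return a `change_summary`.
#' @export
change_summary_from_areas <- function(area_stable, area_gain, area_loss) {
  cur <- area_stable + area_loss; fut <- area_stable + area_gain
  undefined <- (cur + area_gain) == 0
  structure(list(area_current = cur, area_future = fut,
                 area_stable = area_stable, area_gain = area_gain,
                 area_loss = area_loss,
                 net_change_pct = if (cur > 0) 100 * (fut - cur) / cur
                                  else NA_real_,
                 turnover_pct = if (!undefined)
                   100 * (area_gain + area_loss) / (cur + area_gain)
                   else NA_real_,
                 undefined = undefined),
            class = "change_summary")
}

#' Round a change summary to report precision
#'
#' Percentages to one decimal (half away from zero), areas to whole km^2.
#'
#' @param x a `change_summary`.
#' @return data.frame with one row.
#' @export
format_change_summary <- function(x) {
  r1 <- function(v) if (is.na(v)) NA_real_ else
    sign(v) * floor(abs(v) * 10 + 0.5) / 10
  data.frame(area_current = round(x$area_current),
             area_future = round(x$area_future),
             area_stable = round(x$area_stable),
             area_gain = round(x$area_gain),
             area_loss = round(x$area_loss),
             net_change_pct = r1(x$net_change_pct),
             turnover_pct = r1(x$turnover_pct))
}

#' @export
print.change_summary <- function(x, ...) {
  print(format_change_summary(x))
  invisible(x)
}

#' Classify per-cell habitat trajectories across periods
#'
#' Codes: 0 = NEVER suitable, 1 = STABLE (suitable in every period),
#' 2 = EXPANSION (one switch from unsuitable to suitable, no later loss),
#' 3 = CONTRACTION (one switch from suitable to unsuitable, no later gain),
#' 4 = FLUCTUATION (any other alternation).
#'
#' @param binaries ordered list of >= 2 aligned `binary_map`s.
#' @return a `time_step_map`: list with `grid` (class codes), `codes`
#'   (named legend), `period_labels`.
#' @export
time_step_map <- function(binaries) {
  if (length(binaries) < 2L) stop("need at least two periods")
  do.call(stopifnot_aligned, lapply(binaries, function(b) b$grid))
  tmpl <- binaries[[1]]$grid
  M <- vapply(binaries, function(b) as.numeric(b$grid$values),
              numeric(length(tmpl$values)))
  ok <- rowSums(is.na(M)) == 0
  lo <- apply(M, 1L, min); hi <- apply(M, 1L, max)
  dif <- M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE]
  nondec <- apply(dif >= 0, 1L, all); noninc <- apply(dif <= 0, 1L, all)
  code <- rep(4, nrow(M))
  code[hi == 0] <- 0
  code[lo == 1] <- 1
  code[M[, 1] == 0 & M[, ncol(M)] == 1 & nondec] <- 2
  code[M[, 1] == 1 & M[, ncol(M)] == 0 & noninc] <- 3
  code[!ok] <- NA_real_
  structure(list(grid = grid2d(matrix(code, nrow(tmpl$values)),
                               tmpl$cell_size, tmpl$origin, tmpl$crs_tag),
                 codes = c(NEVER = 0, STABLE = 1, EXPANSION = 2,
                           CONTRACTION = 3, FLUCTUATION = 4),
                 period_labels = vapply(binaries, function(b)
                   as.character(b$period_label), "")),
            class = "time_step_map")
}

#' @export
print.time_step_map <- function(x, ...) {
  cat("<time_step_map> periods:", paste(x$period_labels, collapse = " -> "),
      "\n")
  v <- x$grid$values
  for (nm in names(x$codes))
    cat(sprintf("  %-12s %d cells\n", nm,
                sum(v == x$codes[[nm]], na.rm = TRUE)))
  invisible(x)
}

#' Area suitable in every period
#'
#' @param binaries list of aligned `binary_map`s.
#' @param cell_area_km2 area per cell.
#' @return area in km^2 of the cellwise intersection.
#' @export
resilient_area <- function(binaries, cell_area_km2 = 1) {
  do.call(stopifnot_aligned, lapply(binaries, function(b) b$grid))
  inter <- Reduce(`&`, lapply(binaries, function(b)
    !is.na(b$grid$values) & b$grid$values == 1))
  sum(inter) * cell_area_km2
}

#' Equal-interval suitability bins
#'
#' Shares of unmasked cells in `n_bins` equal-width suitability classes on
#' `[0, 1]`; bins are left-closed and the last bin is closed on both ends.
#'
#' @param suitability a `grid2d` in `[0, 1]`.
#' @param n_bins number of bins (default 5).
#' @return data.frame with `bin_lower`, `bin_upper`, `percent`.
#' @export
bin_suitability <- function(suitability, n_bins = 5) {
  v <- suitability$values[!is.na(suitability$values)]
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
             percent = 100 * counts / length(v))
}
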