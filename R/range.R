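#' Minimum convex polygon of occurrence points
#'
#' The classic home-range MCP: drop the `ceiling((1 - coverage) * n)`
#' points farthest (Euclidean) from the centroid of all points, then take
#' the convex hull of the remainder. Distance ties are resolved by
#' dropping the later record in input order.
#'
#' @param points data.frame or matrix with columns `x`, `y`.
#' @param coverage fraction of points retained (default 0.95).
#' @return a `convex_region`: list with `vertices` (counter-clockwise ring
#'   matrix, closed) and `area` (coordinate units squared).
#' @export
mcp <- function(points, coverage = 0.95) {
  pts <- as.data.frame(points)
  x <- pts$x; y <- pts$y
  n <- length(x)
  drop_n <- ceiling((1 - coverage) * n)
  if (drop_n > 0) {
    d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
    # farthest first; ties broken toward the later record
    ord <- order(-d, -seq_len(n))
    keep <- sort(ord[-seq_len(drop_n)])
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3L) stop("fewer than 3 points remain after trimming")
  h <- grDevices::chull(x, y)          # clockwise indices
  h <- rev(h)                          # counter-clockwise
  vx <- x[h]; vy <- y[h]
  a <- shoelace_area(vx, vy)
  if (a <= 0) stop("points are collinear; the MCP has no area")
  structure(list(vertices = cbind(x = c(vx, vx[1]), y = c(vy, vy[1])),
                 area = a),
            class = "convex_region")
}

#' @export
print.convex_region <- function(x, ...) {
  cat(sprintf("<convex_region> %d vertices, area %g\n",
              nrow(x$vertices) - 1L, x$area))
  invisible(x)
}

# signed ring area (positive for counter-clockwise), absolute value returned
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clip of convex subject ring by convex clip ring
clip_convex <- function(subject, clip) {
  subject <- subject[-nrow(subject), , drop = FALSE]   # open rings
  clip <- clip[-nrow(clip), , drop = FALSE]
  # ensure counter-clockwise clip ring
  if (sum((clip[c(2:nrow(clip), 1), 1] - clip[, 1]) *
          (clip[c(2:nrow(clip), 1), 2] + clip[, 2])) > 0)
    clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[i %% nc + 1L, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      dc <- a - b; dp <- p - q
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c((n1 * dp[1] - n2 * dc[1]) / den, (n1 * dp[2] - n2 * dc[2]) / den)
    }
    nw <- list()
    m <- nrow(out)
    for (j in seq_len(m)) {
      p <- out[j, ]; q <- out[j %% m + 1L, ]
      pi <- inside(p); qi <- inside(q)
      if (pi) nw[[length(nw) + 1L]] <- p
      if (pi != qi) nw[[length(nw) + 1L]] <- inter(p, q)
    }
    out <- if (length(nw)) do.call(rbind, nw)
           else matrix(numeric(0), 0, 2)
  }
  out
}

#' Overlap fractions of two convex regions
#'
#' The intersection area divided by each region's own area.
#'
#' @param region_a,region_b `convex_region` objects from [mcp()].
#' @return list with `frac_a`, `frac_b`, `intersection_area`.
#' @export
mcp_overlap <- function(region_a, region_b) {
  if (region_a$area <= 0 || region_b$area <= 0)
    stop("overlap is undefined for a zero-area region")
  inter <- clip_convex(region_a$vertices, region_b$vertices)
  ia <- if (nrow(inter) >= 3L) shoelace_area(inter[, 1], inter[, 2]) else 0
  list(frac_a = ia / region_a$area, frac_b = ia / region_b$area,
       intersection_area = ia)
}

#' Elevation-distribution shift between two occurrence periods
#'
#' Resolves an elevation for every record (its own `elevation` column when
#' present, else the elevation layer at its location), reports per-period
#' means and their difference, and returns binned densities for plotting.
#'
#' @param occ_a,occ_b occurrence data.frames (`x`, `y`, optional
#'   `elevation`) for the two periods.
#' @param elevation `grid2d` of elevations.
#' @param n_bins histogram bins for the density summary (default 20).
#' @return list with `mean_a`, `mean_b`, `delta` (b - a), `unresolved_a`,
#'   `unresolved_b`, `density` (data.frame `mid`, `density_a`, `density_b`).
#' @export
elevation_shift <- function(occ_a, occ_b, elevation, n_bins = 20) {
  resolve <- function(occ) {
    occ <- as.data.frame(occ)
    if (nrow(occ) == 0L) stop("both occurrence sets must be non-empty")
    e <- if ("elevation" %in% names(occ)) occ$elevation
         else rep(NA_real_, nrow(occ))
    miss <- is.na(e)
    e[miss] <- extract_at(elevation, occ$x[miss], occ$y[miss])
    e
  }
  ea <- resolve(occ_a); eb <- resolve(occ_b)
  ua <- sum(is.na(ea)); ub <- sum(is.na(eb))
  ea <- ea[!is.na(ea)]; eb <- eb[!is.na(eb)]
  if (!length(ea) || !length(eb)) stop("no resolvable elevations")
  rng <- range(c(ea, eb))
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ha <- graphics::hist(ea, breaks = brk, plot = FALSE)
  hb <- graphics::hist(eb, breaks = brk, plot = FALSE)
  list(mean_a = mean(ea), mean_b = mean(eb), delta = mean(eb) - mean(ea),
       unresolved_a = ua, unresolved_b = ub,
       density = data.frame(mid = ha$mids, density_a = ha$density,
                            density_b = hb$density))
}

#' Write a convex region as GeoJSON
#'
#' @param region a `convex_region`.
#' @param path output path.
#' @export
write_region_geojson <- function(region, path) {
  write_polygon_geojson(region$vertices, path)
}
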