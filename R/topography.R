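#' Northness of a slope/aspect pair
#'
#' Northness = sin(slope) * cos(aspect): +1 for a vertical north-facing
#' wall, -1 south-facing, 0 on flat ground.
#'
#' @param slope_deg slope in degrees.
#' @param aspect_deg aspect in degrees clockwise from north.
#' @return numeric in `[-1, 1]`.
#' @export
northness <- function(slope_deg, aspect_deg) {
  sin(slope_deg * pi / 180) * cos(aspect_deg * pi / 180)
}

#' Derive topographic layers from elevation
#'
#' Computes slope and aspect with Horn's 8-neighbour finite differences,
#' northness, and the terrain ruggedness index (mean absolute elevation
#' difference between a cell and its 8 neighbours). The outermost ring of
#' cells (incomplete neighbourhoods) is masked; flat cells get aspect 0 and
#' northness 0.
#'
#' @param elevation a `grid2d` of elevations in metres.
#' @return a `layer_stack` with layers `slope` (degrees), `aspect` (degrees
#'   clockwise from north), `northness`, `tri` (metres).
#' @export
derive_topography <- function(elevation) {
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("elevation needs at least a 3x3 interior")
  if (all(is.na(z))) stop("elevation is fully masked")
  cs <- elevation$cell_size
  # shifted copies: s[dr,dc] = z shifted so that s[i,j] = z[i+dr, j+dc]
  shift <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    ri <- seq_len(nr) + dr; ci <- seq_len(nc) + dc
    ok_r <- ri >= 1L & ri <= nr; ok_c <- ci >= 1L & ci <= nc
    out[ok_r, ok_c] <- z[ri[ok_r], ci[ok_c]]
    out
  }
  a <- shift(-1, -1); b <- shift(-1, 0); cc <- shift(-1, 1)
  d <- shift(0, -1);                    f <- shift(0, 1)
  g <- shift(1, -1);  h <- shift(1, 0); i <- shift(1, 1)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)   # dz/dx, eastward
  gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)   # dz/dy, northward
  slope_rad <- atan(sqrt(gx^2 + gy^2))
  aspect_deg <- (atan2(-gx, -gy) * 180 / pi) %% 360       # downslope direction
  flat <- !is.na(slope_rad) & slope_rad == 0
  aspect_deg[flat] <- 0
  north <- sin(slope_rad) * cos(aspect_deg * pi / 180)
  north[flat] <- 0
  tri_num <- abs(z - a) + abs(z - b) + abs(z - cc) + abs(z - d) +
    abs(z - f) + abs(z - g) + abs(z - h) + abs(z - i)
  tri <- tri_num / 8
  edge <- matrix(FALSE, nr, nc)
  edge[c(1L, nr), ] <- TRUE; edge[, c(1L, nc)] <- TRUE
  mask <- function(m) { m[edge] <- NA_real_; m }
  mk <- function(m) grid2d(mask(m), cs, elevation$origin, elevation$crs_tag)
  layer_stack(list(slope = mk(slope_rad * 180 / pi), aspect = mk(aspect_deg),
                   northness = mk(north), tri = mk(tri)),
              kinds = c(slope = "continuous", aspect = "continuous",
                        northness = "continuous", tri = "continuous"),
              families = c(slope = "topography", aspect = "topography",
                           northness = "topography", tri = "topography"))
}
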