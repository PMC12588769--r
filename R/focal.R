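#' Moving-window focal statistics
#'
#' `focal_mean()` assigns to every cell the mean of the unmasked cells whose
#' centres lie within a Euclidean distance of `radius_cells` cell widths of
#' the focal cell's centre (the focal cell itself included).
#' `focal_fraction()` does the same for the fraction of window cells equal to
#' a categorical class code. Windows are circular, truncated at the grid
#' border, and nodata cells are excluded from both numerator and denominator.
#' Masked focal cells stay masked.
#'
#' Window sums are computed by FFT convolution with a binary disc kernel;
#' integer cell counts are rounded back to exact integers so fractions are
#' exact.
#'
#' @param grid a `grid2d`.
#' @param radius_cells window radius in cell widths (>= 0; need not be an
#'   integer). Radius 0 returns the input.
#' @return a `grid2d` on the same geometry.
#' @export
focal_mean <- function(grid, radius_cells) {
  if (!is.numeric(radius_cells) || length(radius_cells) != 1L || radius_cells < 0)
    stop("radius_cells must be a single non-negative number")
  v <- grid$values
  K <- disc_kernel(radius_cells)
  if (nrow(K) == 1L) return(grid)
  valid <- !is.na(v)
  v0 <- v; v0[!valid] <- 0
  num <- conv2d_sum(v0, K)
  den <- round(conv2d_sum(valid + 0, K))
  out <- num / den
  out[den == 0] <- NA_real_
  out[!valid] <- NA_real_
  grid2d(out, grid$cell_size, grid$origin, grid$crs_tag)
}

#' @rdname focal_mean
#' @param class_code integer class whose window fraction is computed.
#' @export
focal_fraction <- function(grid, class_code, radius_cells) {
  if (!is.numeric(radius_cells) || length(radius_cells) != 1L || radius_cells < 0)
    stop("radius_cells must be a single non-negative number")
  v <- grid$values
  valid <- !is.na(v)
  ind <- (v == class_code) + 0
  ind[!valid] <- 0
  K <- disc_kernel(radius_cells)
  if (nrow(K) == 1L) {
    out <- ind
    out[!valid] <- NA_real_
    return(grid2d(out, grid$cell_size, grid$origin, grid$crs_tag))
  }
  num <- round(conv2d_sum(ind, K))
  den <- round(conv2d_sum(valid + 0, K))
  out <- num / den
  out[den == 0] <- NA_real_
  out[!valid] <- NA_real_
  grid2d(out, grid$cell_size, grid$origin, grid$crs_tag)
}

# binary disc: offsets (du, dv) with du^2 + dv^2 <= r^2
disc_kernel <- function(radius_cells) {
  R <- floor(radius_cells)
  off <- seq(-R, R)
  d2 <- outer(off^2, off^2, "+")
  (d2 <= radius_cells^2) + 0
}

# truncated window sum of A (zeros outside) with centred kernel K, via FFT
conv2d_sum <- function(A, K) {
  R <- (nrow(K) - 1L) / 2L
  if (R == 0L) return(A * K[1, 1])
  pr <- nrow(A) + 2L * R; pc <- ncol(A) + 2L * R
  P <- matrix(0, pr, pc); P[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  Kp <- matrix(0, pr, pc); Kp[seq_len(nrow(K)), seq_len(ncol(K))] <- K
  C <- Re(stats::fft(stats::fft(P) * stats::fft(Kp), inverse = TRUE)) / (pr * pc)
  C[(1L + R):(nrow(A) + R), (1L + R):(ncol(A) + R)]
}

#' Build the multi-scale predictor set
#'
#' Applies `focal_mean()` to every continuous layer and `focal_fraction()`
#' to every configured class of every categorical layer, at each candidate
#' radius. Layer names follow the public convention
#' `"<base>_r<radius_km>km"` (categorical layers contribute
#' `"<base>_<class>_r<radius_km>km"`).
#'
#' @param stack a `layer_stack` of base predictors.
#' @param radii_km candidate window radii in kilometres.
#' @param classes named list: for each categorical layer, a named integer
#'   vector of class codes to turn into fraction layers
#'   (e.g. `list(landcover = c(forest = 1, cropland = 2))`).
#' @param layers optional character vector restricting which base layers are
#'   expanded (default: all).
#' @return a list of `multiscale_layer` objects, each a list with
#'   `base_name`, `radius_km`, `grid`, `kind`.
#' @export
build_multiscale_stack <- function(stack, radii_km, classes = list(), layers = NULL) {
  cell_km <- stack$layers[[1]]$cell_size / 1000
  if (is.null(layers)) layers <- names(stack$layers)
  radii_km <- as.numeric(radii_km)
  out <- list()
  for (nm in layers) {
    g <- stack$layers[[nm]]
    for (r in radii_km) {
      rc <- r / cell_km
      if (rc > 0 && rc < 0.5) {
        warning("radius ", r, " km is below half a cell; treated as radius 0")
        rc <- 0
      }
      if (stack$kinds[[nm]] == "continuous") {
        ml <- list(base_name = nm, radius_km = r,
                   grid = focal_mean(g, rc), kind = "continuous")
        class(ml) <- "multiscale_layer"
        out[[sprintf("%s_r%gkm", nm, r)]] <- ml
      } else {
        cls <- classes[[nm]]
        if (is.null(cls)) next
        for (ci in seq_along(cls)) {
          base <- paste0(nm, "_", names(cls)[ci])
          ml <- list(base_name = base, radius_km = r,
                     grid = focal_fraction(g, cls[[ci]], rc),
                     kind = "categorical-fraction")
          class(ml) <- "multiscale_layer"
          out[[sprintf("%s_r%gkm", base, r)]] <- ml
        }
      }
    }
  }
  out
}
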