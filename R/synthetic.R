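#' Spatially autocorrelated Gaussian field
#'
#' Smooths seeded white noise with an isotropic Gaussian kernel whose
#' standard deviation is the correlation length (in cells), then
#' standardises to zero mean and unit variance. Generation happens on a
#' padded grid so border cells have the same correlation structure as the
#' interior. Correlation length 0 gives standardised white noise.
#'
#' @param rows,cols grid dimensions.
#' @param correlation_length_cells Gaussian kernel sd in cell widths (>= 0).
#' @param seed RNG seed; the same arguments always return the same field.
#' @param cell_size,origin,crs_tag passed to [grid2d()].
#' @return a `grid2d` with mean 0 and sd 1.
#' @export
generate_autocorrelated_field <- function(rows, cols, correlation_length_cells,
                                          seed, cell_size = 1000,
                                          origin = c(0, rows * cell_size),
                                          crs_tag = "local-metric") {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  if (correlation_length_cells < 0) stop("correlation length must be >= 0")
  L <- correlation_length_cells
  f <- with_seed(seed, {
    if (L == 0) {
      matrix(stats::rnorm(rows * cols), rows, cols)
    } else {
      pad <- ceiling(3 * L)
      w <- matrix(stats::rnorm((rows + 2 * pad) * (cols + 2 * pad)),
                  rows + 2 * pad, cols + 2 * pad)
      off <- seq(-pad, pad)
      K <- exp(-outer(off^2, off^2, "+") / (2 * L^2))
      sm <- conv2d_sum(w, K)
      sm[(pad + 1):(pad + rows), (pad + 1):(pad + cols)]
    }
  })
  f <- (f - mean(f)) / stats::sd(f)
  grid2d(f, cell_size = cell_size, origin = origin, crs_tag = crs_tag)
}

#' Ground-truth parameters for a synthetic landscape
#'
#' Encodes the generating model that downstream stages try to recover: the
#' characteristic radius (km) at which each driver acts, and the shape of
#' its response — unimodal (`list(opt=, width=)`, a negative-quadratic bump)
#' or monotone (`list(slope=)`). Defaults follow the structure the analysis
#' assumes for a montane forest bird: suitability unimodal in the warmest
#' month temperature and in terrain ruggedness, and increasing in the forest
#' fraction within a 7 km radius.
#'
#' @param true_radii named numeric, characteristic radius in km per variable.
#' @param response_params named list of `list(opt, width)` or `list(slope)`.
#' @param intercept linear-predictor intercept.
#' @param seed integer seed driving all landscape randomness.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_radii = c(forest = 7, tem_warmmon = 6, tri = 8),
                            response_params = list(
                              forest = list(slope = 40),
                              tem_warmmon = list(opt = 15, width = 12),
                              tri = list(opt = 90, width = 600)),
                            intercept = -30, seed = 1L) {
  for (p in response_params) {
    if (!is.null(p$width) && p$width <= 0) stop("response widths must be > 0")
  }
  structure(list(true_radii = true_radii, response_params = response_params,
                 intercept = intercept, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Land-cover class codes used by the synthetic landscape
#' @return named integer vector `c(forest = 1, cropland = 2, other = 3)`.
#' @export
landcover_codes <- function() c(forest = 1L, cropland = 2L, other = 3L)

#' Generate a synthetic predictor landscape
#'
#' Builds an aligned predictor stack with the statistical structure the
#' analysis assumes: an autocorrelated elevation field with derived slope,
#' aspect, northness and ruggedness; temperature layers lapse-coupled to
#' elevation (so they correlate negatively with it); precipitation layers
#' including a near-duplicate pair (to exercise correlation screening); a
#' temperature-seasonality layer independent of the suitability truth (so
#' at least one variable shows no presence/background contrast); a
#' categorical land-cover layer (cropland concentrated at low elevation,
#' open/other cover at high elevation, forest between); and a human
#' footprint layer increasing toward low, cultivated terrain.
#'
#' @param rows,cols grid dimensions in cells.
#' @param cell_size cell edge in metres (default 1000 = the 1-km analysis grid).
#' @param truth a [synthetic_truth()]; its seed drives all randomness.
#' @return a `layer_stack`.
#' @export
generate_landscape <- function(rows = 64, cols = 64, cell_size = 1000,
                               truth = synthetic_truth()) {
  cell_km <- cell_size / 1000
  max_r <- if (length(truth$true_radii)) max(truth$true_radii) / cell_km else 0
  if (min(rows, cols) <= 2 * max_r + 2)
    stop("grid too small to support the largest characteristic radius")
  fld <- function(tag, L) generate_autocorrelated_field(
    rows, cols, L, sub_seed(truth$seed, tag), cell_size = cell_size)
  elev_f <- fld("elev", 6)
  elev <- grid2d(2500 + 900 * elev_f$values, cell_size, elev_f$origin)
  topo <- derive_topography(elev)
  elev_km <- elev$values / 1000
  zelev <- (elev$values - mean(elev$values)) / stats::sd(elev$values)
  g <- function(vals) grid2d(matrix(vals, rows, cols), cell_size, elev$origin)

  tem_warm <- g(28 - 6.5 * elev_km + 2.0 * fld("twarm", 5)$values)
  tem_cold <- g(10 - 6.5 * elev_km + 2.0 * fld("tcold", 5)$values)
  annualtem <- g((tem_warm$values + tem_cold$values) / 2 +
                   0.5 * fld("tann", 5)$values)
  temvar <- g(8 + 1.5 * fld("temvar", 4)$values)

  annualprec <- g(1200 + 300 * fld("pann", 6)$values)
  prec_wet <- g(0.25 * annualprec$values + 20 * fld("pwet", 4)$values)
  prec_dry <- g(pmax(0, 15 + 8 * fld("pdry", 4)$values))
  prec_var <- g(60 + 10 * fld("pvar", 3)$values)

  crop_score <- 0.2 * zelev + fld("lc_crop", 0.5)$values
  open_score <- 0.2 * zelev + fld("lc_open", 0.5)$values
  codes <- landcover_codes()
  lc <- matrix(codes[["forest"]], rows, cols)
  lc[crop_score < stats::quantile(crop_score, 0.25)] <- codes[["cropland"]]
  open <- open_score > stats::quantile(open_score, 0.75)
  lc[open & lc != codes[["cropland"]]] <- codes[["other"]]
  landcover <- g(lc)

  footprint <- g(pmin(50, pmax(0, 30 - 8 * zelev +
                                 5 * (lc == codes[["cropland"]]) +
                                 3 * fld("foot", 2)$values)))

  layers <- c(list(elevation = elev), topo$layers,
              list(annualtem = annualtem, temvar = temvar,
                   tem_warmmon = tem_warm, tem_coldmon = tem_cold,
                   annualprec = annualprec, prec_wetmon = prec_wet,
                   prec_drymon = prec_dry, prec_var = prec_var,
                   landcover = landcover, footprint = footprint))
  kinds <- stats::setNames(rep("continuous", length(layers)), names(layers))
  kinds["landcover"] <- "categorical"
  families <- c(elevation = "topography", slope = "topography",
                aspect = "topography", northness = "topography",
                tri = "topography",
                annualtem = "temperature", temvar = "other",
                tem_warmmon = "temperature", tem_coldmon = "temperature",
                annualprec = "precipitation", prec_wetmon = "precipitation",
                prec_drymon = "precipitation", prec_var = "other",
                landcover = "landcover", footprint = "footprint")
  layer_stack(layers, kinds, families)
}

# focally aggregated driver used by the generating model
truth_driver <- function(stack, truth, var) {
  cell_km <- stack$layers[[1]]$cell_size / 1000
  r_km <- if (var %in% names(truth$true_radii)) truth$true_radii[[var]] else 0
  rc <- r_km / cell_km
  codes <- landcover_codes()
  if (var %in% names(codes)) {
    if (!"landcover" %in% names(stack$layers))
      stop("stack lacks the landcover layer required for '", var, "'")
    focal_fraction(stack$layers[["landcover"]], codes[[var]], rc)
  } else {
    if (!var %in% names(stack$layers))
      stop("stack lacks the layer '", var, "' named in the truth")
    focal_mean(stack$layers[[var]], rc)
  }
}

#' True habitat suitability of a synthetic landscape
#'
#' Evaluates the generating model: each driver is focally aggregated at its
#' true radius, passed through its response (negative-quadratic for unimodal
#' terms, linear for monotone terms), summed with the intercept, and mapped
#' through the logistic function.
#'
#' @param stack a `layer_stack` from [generate_landscape()].
#' @param truth the matching [synthetic_truth()].
#' @return a `grid2d` of suitabilities in `[0, 1]`.
#' @export
true_suitability <- function(stack, truth) {
  g1 <- stack$layers[[1]]
  lp <- matrix(truth$intercept, nrow(g1$values), ncol(g1$values))
  for (var in names(truth$response_params)) {
    p <- truth$response_params[[var]]
    x <- truth_driver(stack, truth, var)$values
    term <- if (!is.null(p$opt)) -((x - p$opt) / p$width)^2 else p$slope * x
    lp <- lp + term
  }
  grid2d(stats::plogis(lp), g1$cell_size, g1$origin, g1$crs_tag)
}

#' Sample presence points proportional to suitability
#'
#' Draws cells with probability proportional to suitability (with
#' replacement) and places one record at each drawn cell's centre.
#'
#' @param suitability a `grid2d` with values in `[0, 1]`.
#' @param n number of points (>= 1).
#' @param seed RNG seed.
#' @param elevation optional `grid2d` used to populate the elevation column.
#' @param year optional year stamp for all records.
#' @return a data.frame with columns `x`, `y`, `elevation`, `year`,
#'   `source_tag`.
#' @export
sample_occurrences <- function(suitability, n, seed, elevation = NULL,
                               year = NA_integer_) {
  if (n < 1) stop("n must be >= 1")
  v <- suitability$values
  ok <- which(!is.na(v) & v > 0)
  if (!length(ok)) stop("suitability has no positive unmasked cells to sample")
  cells <- ok[with_seed(seed, sample.int(length(ok), n, replace = TRUE,
                                         prob = v[ok]))]
  nr <- nrow(v)
  rows <- (cells - 1L) %% nr + 1L
  cols <- (cells - 1L) %/% nr + 1L
  ctr <- cell_centers(suitability, rows, cols)
  elev <- if (!is.null(elevation)) extract_at(elevation, ctr$x, ctr$y)
          else NA_real_
  data.frame(x = ctr$x, y = ctr$y, elevation = elev, year = year,
             source_tag = "synthetic", stringsAsFactors = FALSE)
}

#' Scenario specification for future stacks
#'
#' @param label scenario label (e.g. an SSP-RCP analog).
#' @param period period label (e.g. "2070").
#' @param gcm_label climate-model label.
#' @param warming_offset degrees C added to temperature-family layers.
#' @param precip_factor multiplier on precipitation-family layers (> 0).
#' @param forest_to_crop_rate fraction of forest cells converted to
#'   cropland, in `[0, 1]`.
#' @param seed RNG seed for the conversion draw.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, period, gcm_label = "gcm1",
                          warming_offset = 0, precip_factor = 1,
                          forest_to_crop_rate = 0, seed = 1L) {
  if (forest_to_crop_rate < 0 || forest_to_crop_rate > 1)
    stop("forest_to_crop_rate must be in [0, 1]")
  if (precip_factor <= 0) stop("precip_factor must be > 0")
  structure(list(label = label, period = period, gcm_label = gcm_label,
                 warming_offset = warming_offset,
                 precip_factor = precip_factor,
                 forest_to_crop_rate = forest_to_crop_rate,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Project a landscape under a warming / land-conversion scenario
#'
#' Temperature-family layers are shifted by the warming offset,
#' precipitation-family layers scaled by the precipitation factor, and a
#' fraction of forest cells is re-coded cropland. Conversion preferentially
#' removes low-elevation forest (sampling weights proportional to the
#' inverse elevation rank), emulating cultivation pressure moving upslope.
#' Topography and all other layers are unchanged.
#'
#' @param stack a `layer_stack` from [generate_landscape()].
#' @param spec a [scenario_spec()].
#' @return a new `layer_stack` on the same geometry.
#' @export
generate_future_stack <- function(stack, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  layers <- stack$layers
  for (nm in names(layers)) {
    fam <- stack$families[[nm]]
    if (fam == "temperature")
      layers[[nm]]$values <- layers[[nm]]$values + spec$warming_offset
    if (fam == "precipitation")
      layers[[nm]]$values <- layers[[nm]]$values * spec$precip_factor
  }
  if (spec$forest_to_crop_rate > 0 && "landcover" %in% names(layers)) {
    codes <- landcover_codes()
    lc <- layers[["landcover"]]$values
    forest_cells <- which(!is.na(lc) & lc == codes[["forest"]])
    n_conv <- round(spec$forest_to_crop_rate * length(forest_cells))
    if (n_conv > 0) {
      wts <- if ("elevation" %in% names(layers)) {
        ev <- layers[["elevation"]]$values[forest_cells]
        rank(-ev, ties.method = "first")
      } else rep(1, length(forest_cells))
      conv <- forest_cells[with_seed(spec$seed,
                                     sample.int(length(forest_cells),
                                                n_conv, prob = wts))]
      lc[conv] <- codes[["cropland"]]
      layers[["landcover"]]$values <- lc
    }
  }
  layer_stack(layers, stack$kinds, stack$families)
}
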