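lag_autocor <- function(m, lag) {
  # direct autocovariance along rows, both orientations averaged
  a <- as.vector(m[, seq_len(ncol(m) - lag)])
  b <- as.vector(m[, seq_len(ncol(m) - lag) + lag])
  c <- as.vector(m[seq_len(nrow(m) - lag), ])
  d <- as.vector(m[seq_len(nrow(m) - lag) + lag, ])
  (cor(a, b) + cor(c, d)) / 2
}

test_that("autocorrelated fields have the requested statistical structure", {
  # white-noise case
  f0 <- generate_autocorrelated_field(64, 64, 0, seed = 3)
  expect_lt(abs(mean(f0$values)), 3 / sqrt(64 * 64))
  expect_lt(abs(lag_autocor(f0$values, 1)), 0.05)
  # determinism
  expect_identical(generate_autocorrelated_field(32, 40, 4, seed = 9)$values,
                   generate_autocorrelated_field(32, 40, 4, seed = 9)$values)
  # longer correlation length raises long-range autocorrelation
  a2 <- lag_autocor(generate_autocorrelated_field(128, 128, 2, 5)$values, 5)
  a10 <- lag_autocor(generate_autocorrelated_field(128, 128, 10, 5)$values, 5)
  expect_gt(a10, a2)
  expect_error(generate_autocorrelated_field(10, 10, -1, 1), "correlation")
})

test_that("generated landscapes satisfy the stack contract", {
  tr <- synthetic_truth(seed = 21)
  st <- generate_landscape(64, 64, 1000, tr)
  expect_s3_class(st, "layer_stack")
  fam <- st$families
  expect_true("elevation" %in% names(st$layers))
  expect_gte(sum(fam == "temperature"), 2)
  expect_gte(sum(fam == "precipitation"), 2)
  expect_identical(unname(st$kinds["landcover"]), "categorical")
  expect_true(all(st$layers$landcover$values %in% landcover_codes()))
  # lapse coupling: temperature drops with elevation
  for (nm in names(fam)[fam == "temperature"])
    expect_lt(cor(as.vector(st$layers$elevation$values),
                  as.vector(st$layers[[nm]]$values)), -0.5)
  # at least one highly collinear pair (feeds the correlation screen)
  cont <- names(st$kinds)[st$kinds == "continuous"]
  M <- sapply(st$layers[cont], function(g) as.vector(g$values))
  cm <- abs(cor(M, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  expect_gt(max(cm), 0.7)
  # determinism and size guard
  expect_identical(generate_landscape(64, 64, 1000, tr)$layers$elevation$values,
                   st$layers$elevation$values)
  expect_error(generate_landscape(10, 10, 1000, tr), "too small")
})

test_that("true suitability evaluates the generating responses", {
  tr <- synthetic_truth(seed = 2)
  st <- generate_landscape(48, 48, 1000, tr)
  # all-zero responses give logistic(0) = 0.5 everywhere
  flat <- synthetic_truth(response_params = list(forest = list(slope = 0)),
                          intercept = 0, seed = 2)
  expect_true(all(true_suitability(st, flat)$values == 0.5))
  # unimodal-only: maximal where the aggregated driver is nearest its optimum
  tem6 <- focal_mean(st$layers$tem_warmmon, 6)
  uni <- synthetic_truth(true_radii = c(tem_warmmon = 6),
                         response_params = list(
                           tem_warmmon = list(opt = 12, width = 2)),
                         intercept = 0, seed = 2)
  s <- true_suitability(st, uni)
  expect_equal(which.max(s$values), which.min(abs(tem6$values - 12)))
  # monotone forest term tracks the forest fraction at the true radius
  mono <- synthetic_truth(true_radii = c(forest = 7),
                          response_params = list(forest = list(slope = 10)),
                          intercept = -5, seed = 2)
  sf <- true_suitability(st, mono)
  ff <- focal_fraction(st$layers$landcover, landcover_codes()[["forest"]], 7)
  expect_gt(cor(as.vector(sf$values), as.vector(ff$values),
                method = "spearman"), 0.9)
  bad <- synthetic_truth(true_radii = c(bogus = 3),
                         response_params = list(bogus = list(slope = 1)))
  expect_error(true_suitability(st, bad), "bogus")
})

test_that("presence sampling is suitability-weighted, seeded and guarded", {
  v <- matrix(0, 10, 10); v[4, 7] <- 1
  g <- grid2d(v, cell_size = 1000)
  occ <- sample_occurrences(g, 5, seed = 1)
  expect_true(all(occ$x == 6500 & occ$y == 6500))
  expect_error(sample_occurrences(grid2d(matrix(0, 4, 4)), 3, 1), "positive")
  tr <- synthetic_truth(seed = 14)
  st <- generate_landscape(48, 48, 1000, tr)
  suit <- true_suitability(st, tr)
  occ2 <- sample_occurrences(suit, 200, seed = 8,
                             elevation = st$layers$elevation)
  expect_gt(mean(extract_at(suit, occ2$x, occ2$y)),
            mean(suit$values, na.rm = TRUE))
  expect_false(any(is.na(occ2$elevation)))
  expect_identical(occ2, sample_occurrences(suit, 200, seed = 8,
                                            elevation = st$layers$elevation))
})

test_that("future stacks apply offsets, scaling and seeded forest conversion", {
  tr <- synthetic_truth(seed = 5)
  st <- generate_landscape(48, 48, 1000, tr)
  ident <- generate_future_stack(st, scenario_spec("s", "p"))
  for (nm in names(st$layers))
    expect_identical(ident$layers[[nm]]$values, st$layers[[nm]]$values)
  warm <- generate_future_stack(st, scenario_spec("s", "p",
                                                  warming_offset = 2))
  for (nm in names(st$families)[st$families == "temperature"])
    expect_equal(warm$layers[[nm]]$values, st$layers[[nm]]$values + 2)
  expect_identical(warm$layers$elevation$values, st$layers$elevation$values)
  sp <- scenario_spec("s", "p", forest_to_crop_rate = 0.5, seed = 77)
  conv <- generate_future_stack(st, sp)
  codes <- landcover_codes()
  n_forest <- sum(st$layers$landcover$values == codes[["forest"]])
  n_left <- sum(conv$layers$landcover$values == codes[["forest"]])
  expect_equal(n_forest - n_left, round(0.5 * n_forest))
  expect_identical(conv$layers$landcover$values,
                   generate_future_stack(st, sp)$layers$landcover$values)
  # conversion prefers low-elevation forest
  lost <- st$layers$landcover$values == codes[["forest"]] &
    conv$layers$landcover$values == codes[["cropland"]]
  keptf <- conv$layers$landcover$values == codes[["forest"]]
  expect_lt(mean(st$layers$elevation$values[lost]),
            mean(st$layers$elevation$values[keptf]))
  expect_error(scenario_spec("s", "p", forest_to_crop_rate = 1.2), "rate")
  expect_error(scenario_spec("s", "p", precip_factor = 0), "precip")
})
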