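test_that("binarize applies the inclusive threshold rule", {
  v <- matrix(c(0.1, 0.42, 0.427, 0.9, NA, 0.3), 2)
  g <- grid2d(v, cell_size = 1000)
  b <- binarize(g, 0.427)
  expect_equal(b$grid$values[!is.na(v)], (v[!is.na(v)] >= 0.427) + 0)
  expect_true(is.na(b$grid$values[is.na(v)]))
  expect_true(all(binarize(grid2d(matrix(0.1, 3, 3)), 0.5)$grid$values == 0))
  # random maps agree with the cellwise comparison oracle
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(runif(400), 20)
    t <- runif(1)
    expect_identical(binarize(grid2d(m), t)$grid$values, (m >= t) + 0)
  }
  expect_error(binarize(g, 1.5), "threshold")
})

test_that("climate-model averaging is a cellwise commutative mean", {
  a <- grid2d(matrix(0, 4, 4)); b <- grid2d(matrix(1, 4, 4))
  expect_true(all(average_gcms(list(a, b))$values == 0.5))
  expect_identical(average_gcms(list(a, a, a))$values, a$values)
  set.seed(3)
  maps <- lapply(1:3, function(i) grid2d(matrix(runif(16), 4)))
  expect_equal(average_gcms(maps)$values,
               average_gcms(rev(maps))$values, tolerance = 1e-15)
  expect_error(average_gcms(list(a, grid2d(matrix(1, 3, 3)))), "aligned")
})

test_that("dispersal masking keeps suitable cells near the range polygon", {
  b <- make_binary(rep(1, 100), 10)
  expect_identical(apply_dispersal_mask(b, "perfect"), b)
  # polygon covering everything: identity
  big <- cbind(c(-1e5, 2e5, 2e5, -1e5), c(-1e5, -1e5, 2e5, 2e5))
  expect_identical(apply_dispersal_mask(b, "limited", big, 1)$grid$values,
                   b$grid$values)
  # tiny polygon at one cell centre with a 2-km buffer: distance oracle
  ctr <- cell_centers(b$grid, 5, 5)
  pt <- cbind(ctr$x + c(-1, 1, 1, -1), ctr$y + c(-1, -1, 1, 1))
  lim <- apply_dispersal_mask(b, "limited", pt, 2)
  nr <- 10
  kept <- which(lim$grid$values == 1)
  all_xy <- cell_centers(b$grid, (seq_len(100) - 1) %% nr + 1,
                         (seq_len(100) - 1) %/% nr + 1)
  d <- sqrt((all_xy$x - ctr$x)^2 + (all_xy$y - ctr$y)^2)
  expect_setequal(kept, which(d <= 2000 + 2))   # polygon half-width slack
  expect_error(apply_dispersal_mask(b, "limited"), "polygon")
})

test_that("change accounting reproduces hand counts and identities", {
  same <- make_binary(c(1, 1, 0, 0), 2)
  cs0 <- change_metrics(same, same)
  expect_equal(cs0$area_gain, 0); expect_equal(cs0$area_loss, 0)
  expect_equal(cs0$net_change_pct, 0); expect_equal(cs0$turnover_pct, 0)
  # 4-cell worked example: stable 1, gain 1, loss 1, turnover 2/3
  cur <- make_binary(c(1, 1, 0, 0), 2); fut <- make_binary(c(1, 0, 1, 0), 2)
  cs <- change_metrics(cur, fut)
  expect_equal(cs$area_stable, 1); expect_equal(cs$area_gain, 1)
  expect_equal(cs$area_loss, 1)
  expect_equal(cs$turnover_pct, 100 * 2 / 3)
  # identities on random maps
  set.seed(44)
  for (i in 1:20) {
    a <- make_binary(rbinom(64, 1, 0.4), 8)
    b <- make_binary(rbinom(64, 1, 0.5), 8)
    s <- change_metrics(a, b, cell_area_km2 = 2)
    expect_equal(s$area_future, s$area_stable + s$area_gain)
    expect_equal(s$area_current, s$area_stable + s$area_loss)
    if (!s$undefined) {
      expect_gte(s$turnover_pct, 0); expect_lte(s$turnover_pct, 100)
      if (identical(a$grid$values, b$grid$values))
        expect_equal(s$turnover_pct, 0)
    }
  }
  # empty current habitat flags the rates undefined
  z <- make_binary(rep(0, 4), 2)
  expect_true(is.na(change_metrics(z, z)$net_change_pct))
})

test_that("trajectory classification matches the 8-trajectory enumeration", {
  tra <- expand.grid(p1 = 0:1, p2 = 0:1, p3 = 0:1)
  maps <- lapply(1:3, function(p) make_binary(tra[[p]], 2, period = p))
  ts <- time_step_map(maps)
  got <- as.vector(ts$grid$values)
  want <- apply(tra, 1, function(z) {
    if (all(z == 0)) 0
    else if (all(z == 1)) 1
    else if (z[1] == 0 && z[3] == 1 && all(diff(z) >= 0)) 2
    else if (z[1] == 1 && z[3] == 0 && all(diff(z) <= 0)) 3
    else 4
  })
  expect_equal(got, unname(want))
  # spot checks from the trajectory table
  expect_equal(got[tra$p1 == 1 & tra$p2 == 0 & tra$p3 == 0], 3)
  expect_equal(got[tra$p1 == 0 & tra$p2 == 0 & tra$p3 == 1], 2)
  expect_equal(got[tra$p1 == 1 & tra$p2 == 0 & tra$p3 == 1], 4)
  # stable count equals the resilient area
  expect_equal(sum(got == 1), resilient_area(maps))
  ones <- lapply(1:3, function(p) make_binary(rep(1, 4), 2))
  expect_true(all(time_step_map(ones)$grid$values == 1))
})

test_that("resilient area is an intersection with subset bounds", {
  a <- make_binary(c(1, 1, 0, 0), 2)
  expect_equal(resilient_area(list(a, a)), 2)
  b <- make_binary(c(0, 0, 1, 1), 2)
  expect_equal(resilient_area(list(a, b)), 0)
  set.seed(77)
  for (i in 1:100) {
    x <- make_binary(rbinom(36, 1, 0.5), 6)
    y <- make_binary(rbinom(36, 1, 0.5), 6)
    expect_lte(resilient_area(list(x, y)),
               min(sum(x$grid$values), sum(y$grid$values)))
  }
})

test_that("suitability bins follow the equal-interval convention", {
  half <- bin_suitability(grid2d(matrix(0.5, 5, 5)))
  expect_equal(half$percent, c(0, 0, 100, 0, 0))
  edge <- bin_suitability(grid2d(matrix(0.2, 2, 2)))
  expect_equal(edge$percent[2], 100)   # 0.2 falls in [0.2, 0.4)
  one <- bin_suitability(grid2d(matrix(1, 2, 2)))
  expect_equal(one$percent[5], 100)    # last bin closed above
  set.seed(5)
  u <- bin_suitability(grid2d(matrix(runif(10000), 100)))
  expect_true(all(abs(u$percent - 20) < 3))
  expect_equal(sum(u$percent), 100)
})

test_that("projection reproduces the training map and responds to warming", {
  w <- quick_world(seed = 41)
  f <- quick_features(w)
  ens <- build_ensemble(f$presence, list(f$background),
                        specs = lapply(c("GLM", "XGB"), base_learner_spec),
                        k = 4, repeats = 1, seed = 9)
  expect_error(project_suitability(ens, w$stack), "recipe")
  ens$variables <- f$vars
  cur <- project_suitability(ens, w$stack)
  expect_true(all(cur$values >= 0 & cur$values <= 1, na.rm = TRUE))
  # identity scenario reproduces the current map bit-for-bit
  ident <- generate_future_stack(w$stack, scenario_spec("s", "p"))
  expect_identical(project_suitability(ens, ident)$values, cur$values)
  # strong warming pushes the temperature driver past its optimum:
  # mean suitability must not rise
  hot <- generate_future_stack(w$stack,
                               scenario_spec("s", "p", warming_offset = 8))
  expect_lt(mean(project_suitability(ens, hot)$values, na.rm = TRUE),
            mean(cur$values, na.rm = TRUE))
})
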