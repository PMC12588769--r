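test_that("Welch t-test matches the closed-form oracle", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1),
               tolerance = 1e-12)
  sep <- welch_t_test(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_lt(sep$p, 1e-4)
  a <- c(2.1, 2.5, 2.3); b <- c(2.2, 2.4, 2.6)
  got <- welch_t_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 1e-6)
  # degenerate constants
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2)), list(t = 0, p = 1))
  expect_equal(welch_t_test(c(3, 3), c(2, 2))$p, 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

ms_toy <- function(grids, radii) {
  # wrap plain matrices as a one-variable multi-scale layer list
  out <- list()
  for (i in seq_along(radii)) {
    out[[sprintf("v_r%gkm", radii[i])]] <- structure(
      list(base_name = "v", radius_km = radii[i],
           grid = grid2d(grids[[i]], cell_size = 1000),
           kind = "continuous"), class = "multiscale_layer")
  }
  out
}

test_that("characteristic-scale selection picks the lowest significant p", {
  g <- grid2d(matrix(0, 20, 20), cell_size = 1000)
  pres <- cell_centers(g, rep(1:10, 2), rep(1:10, each = 2))
  bg <- cell_centers(g, rep(11:20, 4), rep(seq(1, 20, 2), each = 4))
  set.seed(1)
  sig <- matrix(rnorm(400), 20); sig[1:10, ] <- sig[1:10, ] + 3
  noise <- matrix(rnorm(400), 20)
  # contrast at radius 3 only
  prof <- select_characteristic_scales(ms_toy(list(noise, sig), c(1, 3)),
                                       pres, bg)
  expect_equal(prof[["v"]]$chosen_radius_km, 3)
  expect_false(prof[["v"]]$excluded)
  # no contrast at any radius: excluded
  prof0 <- select_characteristic_scales(ms_toy(list(noise), 1), pres, bg)
  expect_true(prof0[["v"]]$excluded)
  expect_true(is.na(prof0[["v"]]$chosen_radius_km))
  # single significant radius is chosen outright
  prof1 <- select_characteristic_scales(ms_toy(list(sig), 5), pres, bg)
  expect_equal(prof1[["v"]]$chosen_radius_km, 5)
  # raising the cutoff never excludes a previously included variable
  profl <- select_characteristic_scales(ms_toy(list(sig), 5), pres, bg,
                                        alpha = 0.10)
  expect_false(profl[["v"]]$excluded)
})

fake_profiles <- function(pvals) {
  structure(lapply(names(pvals), function(v)
    list(variable = v, chosen_radius_km = 1, chosen_p = pvals[[v]],
         excluded = FALSE)) |> stats::setNames(names(pvals)),
    class = "scale_profiles")
}

test_that("correlation screening is greedy by ascending p", {
  set.seed(9)
  base <- matrix(rnorm(900), 30)
  mk <- function(m) grid2d(m, cell_size = 1000)
  # duplicate layer: keep the lower-p variable
  dup <- correlation_screen(list(A = mk(base), B = mk(base)),
                            fake_profiles(c(A = 1e-10, B = 1e-3)))
  expect_identical(dup$retained, "A")
  expect_equal(dup$dropped$against, "A")
  expect_equal(dup$dropped$r, 1, tolerance = 1e-12)
  # all weakly correlated: everything retained
  ind <- correlation_screen(list(A = mk(base),
                                 B = mk(matrix(rnorm(900), 30))),
                            fake_profiles(c(A = 1e-4, B = 1e-3)))
  expect_setequal(ind$retained, c("A", "B"))
  # chain A-B, B-C correlated, A-C not: greedy keeps {A, C}
  e1 <- matrix(rnorm(900), 30)
  A <- base
  C <- matrix(0.3 * scale(as.vector(A)) + 0.95 * scale(as.vector(e1)), 30)
  B <- matrix(scale(as.vector(A)) + scale(as.vector(C)), 30)
  ch <- correlation_screen(list(A = mk(A), B = mk(B), C = mk(C)),
                           fake_profiles(c(A = 1e-9, B = 1e-6, C = 1e-3)))
  expect_identical(ch$retained, c("A", "C"))
  expect_identical(ch$dropped$variable, "B")
  # soundness: retained pairs never exceed the threshold
  cm <- abs(ch$cor_matrix[ch$retained, ch$retained])
  diag(cm) <- 0
  expect_true(all(cm <= 0.7))
  # fewer than two variables passes through
  one <- correlation_screen(list(A = mk(base)), fake_profiles(c(A = 0.01)))
  expect_identical(one$retained, "A")
})

test_that("scale recovery works on a generated landscape", {
  # spot-check at one seed; the acceptance suite scans 20 seeds
  tr <- synthetic_truth(seed = 4)
  st <- generate_landscape(64, 64, 1000, tr)
  occ <- sample_occurrences(true_suitability(st, tr), 150, seed = 1004)
  pa <- sample_pseudo_absences(st$layers$elevation, 2000,
                               cell_from_xy(st$layers$elevation,
                                            occ$x, occ$y)$cell, 1, seed = 4)
  ms <- build_multiscale_stack(st, 1:10,
                               list(landcover = landcover_codes()["forest"]),
                               layers = "landcover")
  prof <- select_characteristic_scales(ms, occ, pa[[1]]$points)
  expect_equal(prof[["landcover_forest"]]$chosen_radius_km, 7)
  tab <- scaling_table(prof)
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$chosen), 1)
})
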