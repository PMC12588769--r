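test_that("AUC-weighted ensembling follows the inclusion and weight rules", {
  s1 <- c(0.2, 0.6, 0.9)
  # single member passes through
  expect_equal(ensemble_weighted_mean(cbind(s1), 0.9), s1)
  # equal AUCs average the members
  expect_equal(ensemble_weighted_mean(cbind(rep(0.2, 3), rep(0.6, 3)),
                                      c(0.8, 0.8)), rep(0.4, 3))
  # members {0.9, 0.8, 0.6}: third excluded, weights 9/17 and 8/17
  M <- cbind(rep(1, 2), rep(0, 2), rep(100, 2))
  expect_equal(ensemble_weighted_mean(M, c(0.9, 0.8, 0.6)),
               rep(9 / 17, 2))
  # convexity: ensemble bounded by member extrema; weights sum to 1
  set.seed(6)
  S <- matrix(runif(40), 10, 4)
  a <- c(0.95, 0.85, 0.75, 0.72)
  e <- ensemble_weighted_mean(S, a)
  expect_true(all(e >= apply(S, 1, min) - 1e-12 &
                    e <= apply(S, 1, max) + 1e-12))
  expect_equal(sum(a / sum(a)), 1, tolerance = 1e-12)
  expect_error(ensemble_weighted_mean(S, c(0.6, 0.5, 0.4, 0.3)), "cutoff")
})

test_that("cross-validation enumerates runs and partitions records", {
  set.seed(10)
  pres <- data.frame(v1 = rnorm(30, 1.5), v2 = rnorm(30))
  bgs <- list(data.frame(v1 = rnorm(60), v2 = rnorm(60)),
              data.frame(v1 = rnorm(60), v2 = rnorm(60)))
  specs <- lapply(c("GLM", "XGB"), base_learner_spec)
  cv <- cross_validate(pres, bgs, specs, k = 3, repeats = 2, seed = 1)
  # algorithms x pa sets x repeats x folds
  expect_equal(nrow(cv$runs), 2 * 2 * 2 * 3)
  expect_true(all(cv$runs$auc >= 0 & cv$runs$auc <= 1))
  # every presence is held out exactly once per repeat
  for (r in 1:2) {
    n_held <- sum(sapply(1:3, function(f)
      length(cv$scores[[sprintf("GLM|pa1|r%d|f%d", r, f)]]$presence)))
    expect_equal(n_held, nrow(pres))
  }
  expect_error(cross_validate(pres, bgs, specs, k = 50), "presences")
})

test_that("ensembles form, threshold and predict on synthetic data", {
  w <- quick_world(seed = 31)
  f <- quick_features(w)
  ens <- build_ensemble(f$presence, list(f$background),
                        specs = lapply(c("GLM", "MAXENT_LIKE", "XGB"),
                                       base_learner_spec),
                        k = 4, repeats = 1, seed = 5)
  expect_s3_class(ens, "sdm_ensemble")
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_true(all(vapply(ens$members, function(m) m$auc, 0)[
    ens$weights > 0] > 0.7))
  expect_gte(ens$threshold_maxsss, 0)
  expect_lte(ens$threshold_maxsss, 1)
  p <- predict(ens, f$presence)
  expect_true(all(p >= 0 & p <= 1))
  # ensemble ranks presences above background
  expect_gt(auc(p, predict(ens, f$background)), 0.8)
})

test_that("permutation importance isolates the driving variable", {
  set.seed(20)
  X <- data.frame(a = rnorm(300), b = rnorm(300))
  # scorer ignores b entirely
  sc <- linear_scorer(c(a = 2, b = 0))
  expect_lt(variable_importance(sc, X, "b"), 1e-6)
  expect_gt(variable_importance(sc, X, "a"), 0.9)
  expect_identical(variable_importance(sc, X, "a", seed = 3),
                   variable_importance(sc, X, "a", seed = 3))
  # constant scorer has zero importance by convention
  expect_equal(variable_importance(linear_scorer(c(a = 0, b = 0)), X, "a"),
               0)
})

test_that("response curves preserve shape and match direct evaluation", {
  set.seed(21)
  X <- data.frame(a = runif(200, -2, 2), b = rnorm(200))
  sc <- linear_scorer(c(a = 1.5, b = 0.4))
  rc <- response_curve(sc, X, "a", n_points = 50)
  expect_true(all(diff(rc$score) > 0))
  # endpoints equal the model evaluated at the same fixed vectors
  nd <- data.frame(a = range(X$a), b = median(X$b))
  expect_equal(rc$score[c(1, 50)], predict(sc, nd), tolerance = 1e-12)
})
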