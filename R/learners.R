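#' Base-learner specification
#'
#' The five algorithms of the ensemble: regularized logistic regression
#' (`GLM`), generalized additive model (`GAM`), an L1-penalised
#' linear/quadratic/product-feature logistic model (`MAXENT_LIKE`), random
#' forest (`RF`) and gradient boosting (`XGB`).
#'
#' @param algorithm one of `"GLM"`, `"GAM"`, `"MAXENT_LIKE"`, `"RF"`,
#'   `"XGB"`.
#' @param hyperparams named list overriding the algorithm's defaults
#'   (`lambda` for the glmnet-based learners; `num.trees`, `max.depth` for
#'   RF; `nrounds`, `max_depth`, `eta` for XGB; `k` for GAM smooths).
#' @return an object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(algorithm = c("GLM", "GAM", "MAXENT_LIKE",
                                            "RF", "XGB"),
                              hyperparams = list()) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, hyperparams = hyperparams),
            class = "base_learner_spec")
}

#' Default ensemble member specifications
#' @return list of the five [base_learner_spec()] objects.
#' @export
default_learner_specs <- function() {
  lapply(c("GLM", "GAM", "MAXENT_LIKE", "RF", "XGB"), base_learner_spec)
}

hp <- function(spec, name, default) {
  v <- spec$hyperparams[[name]]
  if (is.null(v)) default else v
}

# linear + quadratic (+ pairwise product) design matrix
feat_expand <- function(X, products = FALSE) {
  X <- as.matrix(X)
  out <- cbind(X, X^2)
  colnames(out) <- c(colnames(X), paste0(colnames(X), "_sq"))
  if (products && ncol(X) > 1L) {
    cmb <- utils::combn(ncol(X), 2)
    prods <- X[, cmb[1, ], drop = FALSE] * X[, cmb[2, ], drop = FALSE]
    colnames(prods) <- paste0(colnames(X)[cmb[1, ]], "_x_",
                              colnames(X)[cmb[2, ]])
    out <- cbind(out, prods)
  }
  out
}

#' Fit one base learner on presence / background features
#'
#' Background records are down-weighted so that the total presence weight
#' equals the total background weight (the standard presence /
#' pseudo-absence class balance). All training is seeded and deterministic.
#'
#' @param spec a [base_learner_spec()].
#' @param presence_features,background_features data.frames (or matrices)
#'   sharing the same predictor columns.
#' @param weights_scheme `"equal_total"` (default) or `"none"`.
#' @param seed RNG seed for the stochastic learners.
#' @return an object of class `sdm_learner` with a [predict][predict.sdm_learner]
#'   method returning scores in `[0, 1]`.
#' @export
fit_base_learner <- function(spec, presence_features, background_features,
                             weights_scheme = c("equal_total", "none"),
                             seed = 1L) {
  weights_scheme <- match.arg(weights_scheme)
  Xp <- as.data.frame(presence_features)
  Xb <- as.data.frame(background_features)
  if (!identical(names(Xp), names(Xb)))
    stop("presence and background features must share columns")
  if (nrow(Xp) < 2L || nrow(Xb) < 2L)
    stop("need at least 2 presence and 2 background records")
  X <- rbind(Xp, Xb)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xb)))
  w <- if (weights_scheme == "equal_total")
    c(rep(1, nrow(Xp)), rep(nrow(Xp) / nrow(Xb), nrow(Xb)))
  else rep(1, length(y))
  Xm <- as.matrix(X)
  alg <- spec$algorithm
  fit <- with_seed(seed, switch(alg,
    GLM = {
      M <- feat_expand(Xm)
      list(model = glmnet::glmnet(M, y, family = "binomial", alpha = 0,
                                  weights = w, lambda = c(1, 0.1, 0.01,
                                                          hp(spec, "lambda", 1e-3))),
           s = hp(spec, "lambda", 1e-3), expand = FALSE)
    },
    MAXENT_LIKE = {
      M <- feat_expand(Xm, products = TRUE)
      list(model = glmnet::glmnet(M, y, family = "binomial", alpha = 1,
                                  weights = w, lambda = c(1, 0.1, 0.01,
                                                          hp(spec, "lambda", 1e-3))),
           s = hp(spec, "lambda", 1e-3), products = TRUE)
    },
    GAM = {
      k <- hp(spec, "k", 4)
      terms <- vapply(names(X), function(v) {
        if (length(unique(X[[v]])) > k) sprintf("s(%s, k = %d)", v, k) else v
      }, "")
      dat <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(mgcv::gam(
        stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
        family = stats::binomial(), data = dat, weights = w,
        method = "REML"))
    },
    RF = {
      dat <- data.frame(.y = factor(y, levels = c(0, 1)), X,
                        check.names = FALSE)
      ranger::ranger(stats::as.formula(".y ~ ."), data = dat,
                     probability = TRUE,
                     num.trees = hp(spec, "num.trees", 300),
                     max.depth = hp(spec, "max.depth", 0),
                     case.weights = w, seed = seed, num.threads = 1)
    },
    XGB = {
      dm <- xgboost::xgb.DMatrix(Xm, label = y, weight = w)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = hp(spec, "max_depth", 3),
                                       eta = hp(spec, "eta", 0.1),
                                       nthread = 1, seed = seed),
                         data = dm, nrounds = hp(spec, "nrounds", 100),
                         verbose = 0)
    }))
  structure(list(algorithm = alg, fit = fit, feature_names = names(X),
                 seed = seed),
            class = "sdm_learner")
}

#' Predict habitat suitability from a fitted learner
#'
#' @param object an `sdm_learner`.
#' @param newdata data.frame or matrix with the training predictor columns.
#' @param ... unused.
#' @return numeric scores in `[0, 1]`.
#' @export
predict.sdm_learner <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  Xm <- as.matrix(X)
  p <- switch(object$algorithm,
    GLM = as.numeric(stats::predict(object$fit$model, feat_expand(Xm),
                                    s = object$fit$s, type = "response")),
    MAXENT_LIKE = as.numeric(stats::predict(object$fit$model,
                                            feat_expand(Xm, products = TRUE),
                                            s = object$fit$s,
                                            type = "response")),
    GAM = as.numeric(stats::predict(object$fit, newdata = X,
                                    type = "response")),
    RF = stats::predict(object$fit, data = X,
                        num.threads = 1)$predictions[, "1"],
    XGB = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(Xm))))
  pmin(1, pmax(0, p))
}

#' @export
print.sdm_learner <- function(x, ...) {
  cat(sprintf("<sdm_learner> %s on %d features\n", x$algorithm,
              length(x$feature_names)))
  invisible(x)
}
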