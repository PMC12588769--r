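#' Repeated k-fold cross-validation of the base learners
#'
#' Presences and background points are partitioned into folds separately
#' (so every fold holds presences), jointly re-randomised per repeat, and
#' every record is held out exactly once per repeat. Runs are enumerated
#' algorithm x pseudo-absence set x repeat x fold. Held-out metrics are
#' AUC, TSS at the held-out maxSSS threshold, and the continuous Boyce
#' index with the held-out background as the landscape sample.
#'
#' @param presence_features data.frame of presence predictors.
#' @param background_sets list of background predictor data.frames, one per
#'   pseudo-absence set.
#' @param specs list of [base_learner_spec()] (default all five).
#' @param k folds (default 5).
#' @param repeats repeats (default 3).
#' @param seed RNG seed.
#' @param keep_scores keep held-out scores (needed to evaluate the
#'   ensemble on held-out data).
#' @return a `cv_result`: list with `runs` (data.frame algorithm, pa_set,
#'   repeat_index, fold, auc, tss, boyce) and, if requested, `scores`.
#' @export
cross_validate <- function(presence_features, background_sets,
                           specs = default_learner_specs(), k = 5,
                           repeats = 3, seed = 1L, keep_scores = TRUE) {
  np <- nrow(presence_features)
  if (k > np) stop("k exceeds the number of presences")
  runs <- list(); scores <- list()
  for (s in seq_along(background_sets)) {
    bg <- as.data.frame(background_sets[[s]])
    nb <- nrow(bg)
    for (r in seq_len(repeats)) {
      fseed <- sub_seed(seed, sprintf("fold_s%d_r%d", s, r))
      fold_p <- with_seed(fseed, sample(rep_len(seq_len(k), np)))
      fold_b <- with_seed(fseed + 1L, sample(rep_len(seq_len(k), nb)))
      for (f in seq_len(k)) {
        trp <- presence_features[fold_p != f, , drop = FALSE]
        trb <- bg[fold_b != f, , drop = FALSE]
        tep <- presence_features[fold_p == f, , drop = FALSE]
        teb <- bg[fold_b == f, , drop = FALSE]
        for (sp in specs) {
          fit <- fit_base_learner(sp, trp, trb,
                                  seed = sub_seed(seed, sp$algorithm))
          sp_p <- predict(fit, tep); sp_b <- predict(fit, teb)
          a <- auc(sp_p, sp_b)
          tm <- tss_max(sp_p, sp_b)
          bo <- suppressWarnings(boyce_index(sp_p, c(sp_p, sp_b)))
          key <- sprintf("%s|pa%d|r%d|f%d", sp$algorithm, s, r, f)
          runs[[key]] <- data.frame(algorithm = sp$algorithm, pa_set = s,
                                    repeat_index = r, fold = f, auc = a,
                                    tss = tm$tss, boyce = bo)
          if (keep_scores)
            scores[[key]] <- list(presence = sp_p, background = sp_b)
        }
      }
    }
  }
  structure(list(runs = do.call(rbind, c(runs, list(make.row.names = FALSE))),
                 scores = if (keep_scores) scores else NULL,
                 k = k, repeats = repeats),
            class = "cv_result")
}

#' AUC-weighted ensemble of member scores
#'
#' Members whose AUC exceeds the cutoff contribute with weights
#' proportional to their AUC; the rest are excluded. The result is a
#' convex combination, so it is bounded by the member score extrema.
#'
#' @param member_scores numeric matrix (rows = cases, columns = members) or
#'   list of equal-length score vectors.
#' @param member_aucs numeric AUC per member.
#' @param auc_cutoff inclusion cutoff (default 0.7, strict inequality).
#' @return numeric vector of ensemble scores.
#' @export
ensemble_weighted_mean <- function(member_scores, member_aucs,
                                   auc_cutoff = 0.7) {
  if (is.list(member_scores)) member_scores <- do.call(cbind, member_scores)
  member_scores <- as.matrix(member_scores)
  if (ncol(member_scores) != length(member_aucs))
    stop("one AUC per member column is required")
  keep <- member_aucs > auc_cutoff
  if (!any(keep)) stop("no member exceeds the AUC cutoff of ", auc_cutoff)
  w <- member_aucs[keep] / sum(member_aucs[keep])
  as.numeric(member_scores[, keep, drop = FALSE] %*% w)
}

#' Fit the AUC-weighted ensemble
#'
#' Cross-validates every algorithm on every pseudo-absence set, refits each
#' (algorithm, set) member on its full data, weights members by their mean
#' cross-validated AUC (members at or below the cutoff are excluded), and
#' computes the maxSSS binarization threshold from the ensemble scores at
#' the presences versus the pooled background.
#'
#' @inheritParams cross_validate
#' @param auc_cutoff member inclusion cutoff (default 0.7).
#' @return an `sdm_ensemble`: members with weights, CV tables (including
#'   per-fold held-out ensemble metrics under algorithm `"ENSEMBLE"`),
#'   `threshold_maxsss`, and the training feature names.
#' @export
build_ensemble <- function(presence_features, background_sets,
                           specs = default_learner_specs(), k = 5,
                           repeats = 3, seed = 1L, auc_cutoff = 0.7) {
  cv <- cross_validate(presence_features, background_sets, specs, k,
                       repeats, seed, keep_scores = TRUE)
  agg <- stats::aggregate(cbind(auc, tss, boyce) ~ algorithm + pa_set,
                          data = cv$runs, FUN = mean)
  members <- list()
  for (i in seq_len(nrow(agg))) {
    alg <- agg$algorithm[i]; pa <- agg$pa_set[i]
    sp <- specs[[which(vapply(specs, function(s) s$algorithm, "") == alg)[1]]]
    fit <- fit_base_learner(sp, presence_features, background_sets[[pa]],
                            seed = sub_seed(seed, alg))
    members[[sprintf("%s_pa%d", alg, pa)]] <-
      list(algorithm = alg, pa_set = pa, fit = fit, auc = agg$auc[i],
           tss = agg$tss[i], boyce = agg$boyce[i])
  }
  aucs <- vapply(members, function(m) m$auc, 0)
  keep <- aucs > auc_cutoff
  if (!any(keep)) stop("no ensemble member exceeds the AUC cutoff")
  weights <- stats::setNames(rep(0, length(members)), names(members))
  weights[keep] <- aucs[keep] / sum(aucs[keep])

  # held-out ensemble metrics: weighted member scores per (pa_set, repeat, fold)
  ens_runs <- list()
  for (pa in unique(cv$runs$pa_set)) for (r in seq_len(repeats)) {
    ep <- c(); eb <- c()
    for (f in seq_len(k)) {
      algs <- unique(cv$runs$algorithm)
      mp <- sapply(algs, function(a)
        cv$scores[[sprintf("%s|pa%d|r%d|f%d", a, pa, r, f)]]$presence)
      mb <- sapply(algs, function(a)
        cv$scores[[sprintf("%s|pa%d|r%d|f%d", a, pa, r, f)]]$background)
      wa <- vapply(algs, function(a) {
        m <- members[[sprintf("%s_pa%d", a, pa)]]; m$auc
      }, 0)
      if (!any(wa > auc_cutoff)) next
      ep <- c(ep, ensemble_weighted_mean(matrix(mp, ncol = length(algs)),
                                         wa, auc_cutoff))
      eb <- c(eb, ensemble_weighted_mean(matrix(mb, ncol = length(algs)),
                                         wa, auc_cutoff))
    }
    if (length(ep) && length(eb)) {
      tm <- tss_max(ep, eb)
      ens_runs[[sprintf("pa%d_r%d", pa, r)]] <-
        data.frame(algorithm = "ENSEMBLE", pa_set = pa, repeat_index = r,
                   fold = NA_integer_, auc = auc(ep, eb), tss = tm$tss,
                   boyce = suppressWarnings(boyce_index(ep, c(ep, eb))))
    }
  }
  cv_runs <- rbind(cv$runs, do.call(rbind, c(ens_runs,
                                             list(make.row.names = FALSE))))

  pooled_bg <- do.call(rbind, lapply(background_sets, as.data.frame))
  sc_p <- predict_members(members, weights, presence_features, auc_cutoff)
  sc_b <- predict_members(members, weights, pooled_bg, auc_cutoff)
  structure(list(members = members, weights = weights,
                 auc_cutoff = auc_cutoff,
                 threshold_maxsss = max_sss_threshold(sc_p, sc_b),
                 feature_names = names(as.data.frame(presence_features)),
                 cv_runs = cv_runs,
                 variables = NULL),
            class = "sdm_ensemble")
}

predict_members <- function(members, weights, newdata, auc_cutoff) {
  keep <- which(weights > 0)
  M <- vapply(members[keep], function(m) predict(m$fit, newdata),
              numeric(nrow(as.data.frame(newdata))))
  as.numeric(as.matrix(M) %*% (weights[keep] / sum(weights[keep])))
}

#' Predict ensemble suitability
#'
#' @param object an `sdm_ensemble`.
#' @param newdata data.frame with the training predictor columns.
#' @param ... unused.
#' @return numeric scores in `[0, 1]`.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  predict_members(object$members, object$weights, newdata, object$auc_cutoff)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %d members (%d weighted), maxSSS threshold %.3f\n",
              length(x$members), sum(x$weights > 0), x$threshold_maxsss))
  ens <- x$cv_runs[x$cv_runs$algorithm == "ENSEMBLE", ]
  if (nrow(ens))
    cat(sprintf("  held-out ensemble: AUC %.3f, TSS %.3f, Boyce %.3f\n",
                mean(ens$auc), mean(ens$tss), mean(ens$boyce, na.rm = TRUE)))
  invisible(x)
}

#' Permutation importance of one variable
#'
#' Importance = mean over seeded permutations of
#' `1 - |Pearson r(pred_original, pred_permuted)|`; 0 for a variable the
#' model ignores, approaching 1 when predictions are fully driven by it.
#' Constant predictions give 0 by convention.
#'
#' @param model object with a `predict` method returning scores.
#' @param eval_features data.frame of evaluation cases.
#' @param variable column to permute.
#' @param n_perm number of permutations (default 5).
#' @param seed RNG seed.
#' @return importance in `[0, 1]`.
#' @export
variable_importance <- function(model, eval_features, variable, n_perm = 5,
                                seed = 1L) {
  X <- as.data.frame(eval_features)
  if (!variable %in% names(X)) stop("variable '", variable, "' not in features")
  p0 <- predict(model, X)
  if (stats::sd(p0) == 0) return(0)
  vals <- vapply(seq_len(n_perm), function(i) {
    Xp <- X
    Xp[[variable]] <- with_seed(sub_seed(seed, paste0(variable, i)),
                                sample(Xp[[variable]]))
    p1 <- predict(model, Xp)
    if (stats::sd(p1) == 0) return(1)
    1 - abs(stats::cor(p0, p1))
  }, 0)
  mean(vals)
}

#' Evaluation-strip response curve
#'
#' Sweeps one variable across its observed range while every other
#' variable is held at its training median.
#'
#' @param model object with a `predict` method.
#' @param train_features training predictor data.frame (supplies ranges and
#'   medians).
#' @param variable variable to sweep.
#' @param n_points curve resolution (default 100).
#' @return data.frame with columns `value`, `score`.
#' @export
response_curve <- function(model, train_features, variable, n_points = 100) {
  X <- as.data.frame(train_features)
  if (!variable %in% names(X)) stop("variable '", variable, "' not in features")
  grid_v <- seq(min(X[[variable]]), max(X[[variable]]),
                length.out = n_points)
  med <- lapply(X, stats::median)
  nd <- as.data.frame(med)[rep(1, n_points), , drop = FALSE]
  nd[[variable]] <- grid_v
  rownames(nd) <- NULL
  data.frame(value = grid_v, score = predict(model, nd))
}
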