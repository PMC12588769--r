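# shared fixtures and independent oracles

# naive double-loop focal statistics (the enumeration oracle)
oracle_focal <- function(values, radius, stat = c("mean", "fraction"),
                         class_code = NULL) {
  stat <- match.arg(stat)
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(values[i, j])) next
    acc <- c()
    for (u in seq_len(nr)) for (v in seq_len(nc)) {
      if ((u - i)^2 + (v - j)^2 <= radius^2 && !is.na(values[u, v]))
        acc <- c(acc, values[u, v])
    }
    out[i, j] <- if (stat == "mean") mean(acc) else mean(acc == class_code)
  }
  out
}

# hand-rolled Welch t-test (closed-form oracle)
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# AUC by exhaustive pair enumeration
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# exhaustive maxSSS / TSS search over unique observed scores
oracle_max_sss <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  ss <- sapply(cand, function(t) mean(pos >= t) + mean(neg < t))
  list(threshold = cand[which.max(ss)], tss = max(ss) - 1)
}

# quick small landscape + multi-scale features for model-level tests
quick_world <- function(seed = 1, rows = 48, cols = 48, n_pres = 120,
                        n_bg = 500, radii = c(1, 3, 5, 7, 9)) {
  tr <- synthetic_truth(seed = seed)
  st <- generate_landscape(rows, cols, 1000, tr)
  suit <- true_suitability(st, tr)
  occ <- sample_occurrences(suit, n_pres, seed = seed + 500,
                            elevation = st$layers$elevation)
  pa <- sample_pseudo_absences(st$layers$elevation, n_bg,
                               cell_from_xy(st$layers$elevation,
                                            occ$x, occ$y)$cell,
                               1, seed = seed)
  classes <- list(landcover = landcover_codes()[c("forest", "cropland")])
  list(truth = tr, stack = st, suitability = suit, occ = occ, pa = pa,
       classes = classes)
}

# features for the three generating drivers at their true radii
quick_features <- function(world) {
  vars <- data.frame(
    name = c("forest_r7", "tem_r6", "tri_r8"),
    base = c("landcover_forest", "tem_warmmon", "tri"),
    layer = c("landcover", "tem_warmmon", "tri"),
    class_code = c(1, NA, NA), radius_km = c(7, 6, 8))
  fg <- compute_feature_grids(world$stack, vars)
  pf <- features_at(fg, world$occ$x, world$occ$y)
  bf <- features_at(fg, world$pa[[1]]$points$x, world$pa[[1]]$points$y)
  list(vars = vars, grids = fg,
       presence = pf[complete.cases(pf), , drop = FALSE],
       background = bf[complete.cases(bf), , drop = FALSE])
}

# fixed-coefficient linear scorer used to test importance / response curves
linear_scorer <- function(coefs) {
  structure(list(coefs = coefs), class = "linear_scorer")
}
predict.linear_scorer <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, names(object$coefs), drop = FALSE])
  plogis(as.numeric(X %*% object$coefs))
}
registerS3method("predict", "linear_scorer", predict.linear_scorer,
                 envir = asNamespace("stats"))

make_binary <- function(vals, nr, label = "x", period = "p") {
  structure(list(grid = grid2d(matrix(vals, nr), cell_size = 1000),
                 threshold_used = 0.5, scenario_label = label,
                 period_label = period),
            class = "binary_map")
}
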