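#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation: the probability that a random presence
#' score exceeds a random background score, ties counting one half.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_presence, scores_background) {
  p <- scores_presence[!is.na(scores_presence)]
  b <- scores_background[!is.na(scores_background)]
  if (!length(p) || !length(b)) stop("both score vectors must be non-empty")
  r <- rank(c(p, b))
  (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
    (length(p) * length(b))
}

#' True Skill Statistic
#'
#' `tss_at()` evaluates sensitivity + specificity - 1 at one threshold
#' (scores at or above the threshold are classified presence, matching the
#' inclusive binarization rule). `tss_max()` maximises over all unique
#' observed scores, ties broken toward the smallest maximising threshold.
#'
#' @inheritParams auc
#' @param threshold classification threshold.
#' @return `tss_at`: TSS in `[-1, 1]`; `tss_max`: list `tss`, `threshold`.
#' @export
tss_at <- function(scores_presence, scores_background, threshold) {
  sens <- mean(scores_presence >= threshold)
  spec <- mean(scores_background < threshold)
  sens + spec - 1
}

#' @rdname tss_at
#' @export
tss_max <- function(scores_presence, scores_background) {
  cand <- sort(unique(c(scores_presence, scores_background)))
  tss <- vapply(cand, function(t) tss_at(scores_presence, scores_background, t),
                0)
  best <- which.max(tss)   # which.max returns the first (smallest) maximiser
  list(tss = tss[best], threshold = cand[best])
}

#' Threshold maximising sensitivity + specificity
#'
#' The maxSSS binarization threshold: the unique observed score value at
#' which sensitivity + specificity is largest (smallest such value on
#' ties). Used to turn continuous suitability into binary habitat maps.
#'
#' @inheritParams auc
#' @return threshold value.
#' @export
max_sss_threshold <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("both score vectors must be non-empty")
  tss_max(scores_presence, scores_background)$threshold
}

#' Continuous Boyce index
#'
#' Spearman rank correlation between the predicted-to-expected presence
#' ratio (P/E) in overlapping suitability classes and the class midpoint.
#' Classes are `n_bins` moving windows of width
#' `window_fraction * (max - min)` of the landscape scores, with centres
#' evenly spaced across the score range. Windows with no landscape mass are
#' dropped; fewer than 3 usable classes yields `NA` with a warning.
#'
#' @param scores_presence scores at presence points.
#' @param scores_landscape scores over the (sampled) study landscape.
#' @param n_bins number of moving classes (default 10).
#' @param window_fraction window width as a fraction of the score range
#'   (default 0.1).
#' @return Boyce index in `[-1, 1]`, or `NA` if undefined.
#' @export
boyce_index <- function(scores_presence, scores_landscape, n_bins = 10,
                        window_fraction = 0.1) {
  p <- scores_presence[is.finite(scores_presence)]
  l <- scores_landscape[is.finite(scores_landscape)]
  if (!length(p) || !length(l)) stop("both score vectors must be non-empty")
  mn <- min(l); mx <- max(l)
  if (mx <= mn) { warning("landscape scores are constant; Boyce undefined")
                  return(NA_real_) }
  W <- window_fraction * (mx - mn)
  centers <- seq(mn + W / 2, mx - W / 2, length.out = n_bins)
  P <- vapply(centers, function(ct) mean(p >= ct - W / 2 & p <= ct + W / 2), 0)
  E <- vapply(centers, function(ct) mean(l >= ct - W / 2 & l <= ct + W / 2), 0)
  keep <- E > 0
  if (sum(keep) < 3L) { warning("fewer than 3 non-empty suitability classes")
                        return(NA_real_) }
  f <- P[keep] / E[keep]
  suppressWarnings(stats::cor(f, centers[keep], method = "spearman"))
}
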