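#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test (Welch-Satterthwaite degrees of freedom),
#' appropriate for the grossly unequal sample sizes of presence versus
#' background comparisons. Degenerate inputs where both samples are
#' constant are handled explicitly: equal constants give `t = 0, p = 1`,
#' different constants give `t = Inf` (signed) and `p = 0`.
#'
#' @param sample_a,sample_b numeric vectors with >= 2 finite values each.
#' @return list with elements `t` and `p`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Select each variable's characteristic scale
#'
#' For every variable and candidate radius, compares the focal value at
#' presence points against the value at background points with a Welch
#' t-test. Radii with `p < alpha` are candidates; the characteristic scale
#' is the candidate with the smallest p-value (ties broken toward the
#' smaller radius). Variables with no significant radius are flagged
#' excluded.
#'
#' @param multiscale_layers list of `multiscale_layer` objects from
#'   [build_multiscale_stack()].
#' @param presences data.frame with `x`, `y` of presence points.
#' @param background data.frame with `x`, `y` of background points (e.g.
#'   one pseudo-absence set).
#' @param alpha significance cutoff (default 0.05).
#' @return a `scale_profiles` object: list of per-variable profiles, each
#'   with `variable`, `tests` (data.frame radius_km/t/p), `chosen_radius_km`
#'   (or `NA`), `chosen_p` (or `NA`), `excluded` (logical).
#' @export
select_characteristic_scales <- function(multiscale_layers, presences,
                                         background, alpha = 0.05) {
  vars <- unique(vapply(multiscale_layers, function(l) l$base_name, ""))
  profiles <- lapply(vars, function(v) {
    ls <- multiscale_layers[vapply(multiscale_layers,
                                   function(l) l$base_name == v, TRUE)]
    radii <- vapply(ls, function(l) l$radius_km, 0)
    ord <- order(radii)
    ls <- ls[ord]; radii <- radii[ord]
    tests <- do.call(rbind, lapply(ls, function(l) {
      pa <- extract_at(l$grid, presences$x, presences$y)
      bg <- extract_at(l$grid, background$x, background$y)
      pa <- pa[is.finite(pa)]; bg <- bg[is.finite(bg)]
      res <- if (length(pa) < 2L || length(bg) < 2L) list(t = NA_real_, p = 1)
             else welch_t_test(pa, bg)
      data.frame(radius_km = l$radius_km, t = res$t, p = res$p)
    }))
    rownames(tests) <- NULL
    sig <- which(tests$p < alpha)
    if (length(sig)) {
      best <- sig[which.min(tests$p[sig])]   # which.min: first = smaller radius
      list(variable = v, tests = tests,
           chosen_radius_km = tests$radius_km[best],
           chosen_p = tests$p[best], excluded = FALSE)
    } else {
      list(variable = v, tests = tests, chosen_radius_km = NA_real_,
           chosen_p = NA_real_, excluded = TRUE)
    }
  })
  names(profiles) <- vars
  structure(profiles, class = "scale_profiles")
}

#' @export
print.scale_profiles <- function(x, ...) {
  print(scale_profile_table(x))
  invisible(x)
}

#' Tabulate scale profiles
#'
#' One row per variable: chosen scale, its t and p, and the exclusion flag
#' (the per-variable analog of a scaling-results table).
#'
#' @param profiles a `scale_profiles` object.
#' @return data.frame with columns `variable`, `chosen_radius_km`,
#'   `t`, `p`, `excluded`.
#' @export
scale_profile_table <- function(profiles) {
  do.call(rbind, lapply(unclass(profiles), function(p) {
    tt <- if (!p$excluded)
      p$tests$t[match(p$chosen_radius_km, p$tests$radius_km)] else NA_real_
    data.frame(variable = p$variable, chosen_radius_km = p$chosen_radius_km,
               t = tt, p = p$chosen_p, excluded = p$excluded,
               row.names = NULL)
  }))
}

#' Screen collinear variables
#'
#' Greedy retention pass over the variables at their chosen scales, sorted
#' by ascending characteristic-scale p-value: a candidate is kept iff its
#' absolute Pearson correlation with every already-kept variable is at or
#' below the threshold; otherwise it is dropped, citing the retained
#' variable it collides with. Correlations are computed on a seeded random
#' sample of unmasked cells shared by all layers.
#'
#' @param chosen_layers named list of `grid2d`, one per variable at its
#'   chosen radius.
#' @param profiles `scale_profiles` (supplies the p-value ordering).
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @param max_cells cap on the number of cells sampled (default 50000).
#' @param seed RNG seed for the cell sample.
#' @return a `screen_result`: list with `retained` (character),
#'   `dropped` (data.frame `variable`, `against`, `r`), and `cor_matrix`.
#' @export
correlation_screen <- function(chosen_layers, profiles, threshold = 0.7,
                               max_cells = 50000, seed = 1L) {
  vars <- names(chosen_layers)
  if (length(vars) < 2L)
    return(structure(list(retained = vars,
                          dropped = data.frame(variable = character(0),
                                               against = character(0),
                                               r = numeric(0)),
                          cor_matrix = NULL),
                     class = "screen_result"))
  ok <- Reduce(`&`, lapply(chosen_layers, function(g) !is.na(g$values)))
  cells <- which(ok)
  if (length(cells) > max_cells)
    cells <- with_seed(seed, sample(cells, max_cells))
  M <- vapply(chosen_layers, function(g) g$values[cells],
              numeric(length(cells)))
  cm <- suppressWarnings(stats::cor(M))
  cm[is.na(cm)] <- 0
  pvals <- vapply(vars, function(v) {
    p <- unclass(profiles)[[v]]$chosen_p
    if (is.null(p) || is.na(p)) 1 else p
  }, 0)
  ord <- vars[order(pvals, seq_along(vars))]
  retained <- character(0)
  dropped <- data.frame(variable = character(0), against = character(0),
                        r = numeric(0))
  for (v in ord) {
    conflict <- retained[abs(cm[v, retained]) > threshold]
    if (length(conflict)) {
      worst <- conflict[which.max(abs(cm[v, conflict]))]
      dropped <- rbind(dropped, data.frame(variable = v, against = worst,
                                           r = cm[v, worst]))
    } else retained <- c(retained, v)
  }
  structure(list(retained = retained, dropped = dropped, cor_matrix = cm),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("dropped:\n"); print(x$dropped)
  }
  invisible(x)
}

#' Full per-radius scaling table
#'
#' Long-format analog of the scaling supplement: one row per variable and
#' radius with t, p, and whether that radius was chosen.
#'
#' @param profiles a `scale_profiles` object.
#' @param screen optional `screen_result` adding a `retained` column.
#' @return data.frame.
#' @export
scaling_table <- function(profiles, screen = NULL) {
  tab <- do.call(rbind, lapply(unclass(profiles), function(p) {
    data.frame(variable = p$variable, p$tests,
               chosen = !p$excluded & p$tests$radius_km == p$chosen_radius_km,
               row.names = NULL)
  }))
  if (!is.null(screen)) tab$retained <- tab$variable %in% screen$retained
  rownames(tab) <- NULL
  tab
}
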