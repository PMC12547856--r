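# 15N-enrichment extraction and pulse-chase turnover kinetics. The
# measured quantity per organelle is the summed-count ratio
# 12C15N / 12C14N over the instance mask (sum-then-divide: the ratio of
# summed counts equals the count-weighted mean of pixel ratios and is far
# more stable than averaging per-pixel ratios at low counts). Enrichment
# declines over the chase as labeled protein is replaced:
# E(t) = E_nat + (E0 - E_nat) * 2^(-t / t_half).

#' Per-ROI enrichment from corrected ion images
#'
#' Ratio = sum(cn15) / sum(cn14) over each instance's pixels; masks must be
#' in the SIMS frame and the images already dead-time/drift corrected
#' (NA pixels, e.g. outside drift coverage, are excluded from the sums).
#' ROIs with zero 12C14N counts are excluded with a warning.
#'
#' @param rois [roi_set()] in SIMS coordinates.
#' @param cn14,cn15 accumulated count matrices of the ROI frame shape.
#' @param chase_time optional chase time (h) stamped on the measurements.
#' @return data frame: `roi_id`, `class_id`, `class`, `chase_time`,
#'   `cn14_counts`, `cn15_counts`, `ratio`, `n_pixels`.
#' @export
roi_enrichment <- function(rois, cn14, cn15, chase_time = NA_real_) {
  stopifnot(inherits(rois, "roi_set"))
  if (!all(dim(cn14) == rois$image_shape) || !all(dim(cn15) == rois$image_shape)) {
    stop("roi_enrichment: image shape does not match the ROI frame")
  }
  n <- length(rois)
  out <- data.frame(
    roi_id = rois$table$id, class_id = rois$table$class_id,
    class = rois$table$class, chase_time = rep(chase_time, n),
    cn14_counts = NA_real_, cn15_counts = NA_real_,
    ratio = NA_real_, n_pixels = NA_integer_
  )
  for (i in seq_len(n)) {
    idx <- rois$pixels[[i]]
    v14 <- cn14[idx]; v15 <- cn15[idx]
    ok <- !is.na(v14) & !is.na(v15)
    s14 <- sum(v14[ok]); s15 <- sum(v15[ok])
    out$cn14_counts[i] <- s14
    out$cn15_counts[i] <- s15
    out$n_pixels[i] <- sum(ok)
    out$ratio[i] <- if (s14 > 0) s15 / s14 else NA_real_
  }
  bad <- is.na(out$ratio)
  if (any(bad)) {
    warning("roi_enrichment: ", sum(bad),
            " ROI(s) with zero 12C14N counts excluded")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Enrichment at manually clicked points
#'
#' Multipoint selection: counts are summed over a disk of the given radius
#' centered at each point (radius 0 = the single pixel), mirroring
#' click-tool coordinate lists exported by image viewers.
#'
#' @param points data frame with `x`, `y` (SIMS pixel coordinates) and
#'   optionally `class`.
#' @param cn14,cn15 accumulated count matrices.
#' @param radius disk radius in px (default 2).
#' @param chase_time optional chase time stamp.
#' @return data frame as for [roi_enrichment()].
#' @export
multipoint_enrichment <- function(points, cn14, cn15, radius = 2,
                                  chase_time = NA_real_) {
  stopifnot(all(c("x", "y") %in% names(points)))
  sh <- dim(cn14)
  if (any(points$x < 1 | points$x > sh[2] | points$y < 1 | points$y > sh[1])) {
    stop("multipoint_enrichment: point out of bounds")
  }
  classes <- if ("class" %in% names(points)) points$class else NA_character_
  n <- nrow(points)
  out <- data.frame(
    roi_id = seq_len(n), class_id = NA_integer_,
    class = rep_len(classes, n), chase_time = rep(chase_time, n),
    cn14_counts = NA_real_, cn15_counts = NA_real_,
    ratio = NA_real_, n_pixels = NA_integer_
  )
  for (i in seq_len(n)) {
    m <- disk_mask(radius, shape = sh, center = c(points$y[i], points$x[i]))
    v14 <- cn14[m]; v15 <- cn15[m]
    ok <- !is.na(v14) & !is.na(v15)
    s14 <- sum(v14[ok])
    out$cn14_counts[i] <- s14
    out$cn15_counts[i] <- sum(v15[ok])
    out$n_pixels[i] <- sum(ok)
    out$ratio[i] <- if (s14 > 0) out$cn15_counts[i] / s14 else NA_real_
  }
  out
}

#' Fit the first-order decay model to an enrichment series
#'
#' Nonlinear least squares of
#' `ratio ~ E_nat + (E0 - E_nat) * 2^(-t / t_half)` over replicate
#' measurements. With `fix_baseline` (default) `E_nat` is held at the
#' supplied value (the control-group measurement, or natural abundance
#' 0.0037); otherwise it is a third free parameter. Start values come from
#' a log-linear fit of the baseline-subtracted per-time means, so
#' noiseless model data converge to the truth at optimizer tolerance.
#'
#' @param series data frame with `chase_time` (h) and `ratio` columns
#'   (replicates allowed); at least 3 distinct chase times (4 for the
#'   free-baseline fit).
#' @param fix_baseline hold `E_nat` fixed (default TRUE).
#' @param e_nat baseline value (default 0.0037).
#' @param weights optional per-row fit weights (e.g. 1/SEM^2).
#' @return object of class `decay_fit`: `t_half`, `t_half_sem`, `e0`,
#'   `e0_sem`, `e_nat`, `baseline_fixed`, `rss`, `n_points`, `fitted`.
#' @export
fit_decay <- function(series, fix_baseline = TRUE, e_nat = 0.0037,
                      weights = NULL) {
  stopifnot(all(c("chase_time", "ratio") %in% names(series)))
  series <- series[is.finite(series$chase_time) & is.finite(series$ratio), ]
  t <- series$chase_time
  y <- series$ratio
  n_times <- length(unique(t))
  need <- if (fix_baseline) 3L else 4L
  if (n_times < need) {
    stop("fit_decay: need at least ", need, " distinct chase times, got ", n_times)
  }
  if (any(y < 0)) stop("fit_decay: negative enrichment ratios")
  # start values from a log-linear fit on baseline-subtracted means
  mu <- tapply(y, t, mean)
  tt <- as.numeric(names(mu))
  excess <- as.numeric(mu) - e_nat
  spread <- stats::sd(y)
  if (max(excess) <= max(1e-12, 2 * spread / sqrt(max(1, length(y) / n_times)))
      && max(excess) < 1e-4) {
    stop("fit_decay: no decay signal (enrichment indistinguishable from the ",
         "baseline E_nat = ", e_nat, "); cannot estimate a half-life")
  }
  pos <- excess > 0
  if (sum(pos) < 2) stop("fit_decay: too few time points above baseline")
  lf <- stats::lm(log(excess[pos]) ~ tt[pos])
  slope <- stats::coef(lf)[2]
  if (!is.finite(slope) || slope >= 0) {
    # no decay trend; fall back to a coarse guess from the range
    slope <- -log(2) / max(tt[tt > 0], 1)
  }
  T0 <- unname(-log(2) / slope)
  E00 <- unname(exp(stats::coef(lf)[1]) + e_nat)
  dat <- data.frame(t = t, y = y)
  ctrl <- stats::nls.control(maxiter = 200, minFactor = 1e-12, scaleOffset = 1)
  if (fix_baseline) {
    fit <- stats::nls(y ~ e_nat + (E0 - e_nat) * 2^(-t / thalf),
                      data = dat, start = list(E0 = E00, thalf = T0),
                      weights = weights, control = ctrl)
  } else {
    fit <- stats::nls(y ~ Enat + (E0 - Enat) * 2^(-t / thalf),
                      data = dat,
                      start = list(E0 = E00, thalf = T0, Enat = e_nat),
                      weights = weights, control = ctrl)
  }
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, length(co), length(co),
                                                              dimnames = list(names(co), names(co))))
  if (co[["thalf"]] <= 0) stop("fit_decay: fitted half-life is not positive")
  structure(list(
    t_half = co[["thalf"]],
    t_half_sem = sqrt(vc["thalf", "thalf"]),
    e0 = co[["E0"]],
    e0_sem = sqrt(vc["E0", "E0"]),
    e_nat = if (fix_baseline) e_nat else co[["Enat"]],
    baseline_fixed = fix_baseline,
    rss = sum(stats::residuals(fit)^2),
    n_points = nrow(dat),
    fitted = fit
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> t1/2 = %.4g +/- %.2g h, E0 = %.4g, E_nat = %.4g (%s), n = %d, RSS = %.3g\n",
              x$t_half, x$t_half_sem, x$e0, x$e_nat,
              if (x$baseline_fixed) "fixed" else "fitted", x$n_points, x$rss))
  invisible(x)
}

#' Fit decay per class
#'
#' @param measurements long-format data frame with `class`, `chase_time`,
#'   `ratio` (as produced by [roi_enrichment()] across chase times).
#' @param ... passed to [fit_decay()].
#' @return data frame with one row per class: `class`, `t_half`,
#'   `t_half_sem`, `e0`, `rss`, `n_points` (classes whose fit fails are
#'   dropped with a warning).
#' @export
fit_decay_by_class <- function(measurements, ...) {
  out <- list()
  for (cl in unique(measurements$class)) {
    sub <- measurements[measurements$class == cl, ]
    f <- tryCatch(fit_decay(sub, ...), error = function(e) {
      warning("fit_decay_by_class: class ", cl, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(f)) {
      out[[length(out) + 1L]] <- data.frame(
        class = cl, t_half = f$t_half, t_half_sem = f$t_half_sem,
        e0 = f$e0, rss = f$rss, n_points = f$n_points
      )
    }
  }
  if (length(out) == 0) return(data.frame(class = character(), t_half = numeric(),
                                          t_half_sem = numeric(), e0 = numeric(),
                                          rss = numeric(), n_points = integer()))
  do.call(rbind, out)
}

#' Significance stars for a p value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p p value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Independent two-sample comparison of turnover values
#'
#' Two-sample t-test on per-ROI (or per-cell) values; Welch by default
#' (robust to unequal group variances), classical equal-variance available
#' via `welch = FALSE`.
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param welch use the Welch correction (default TRUE).
#' @return list with `t`, `df`, `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b, welch = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_groups: each group needs at least 2 observations")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, stars = significance_stars(ht$p.value),
       mean_a = mean(a), mean_b = mean(b))
}
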