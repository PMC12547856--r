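# Multi-plane ion-count stacks and their corrections. An acquisition
# rasters the same field several times (planes); before summation each
# plane must be dead-time corrected (counting detectors are blind for a
# fixed interval after each ion, deflating high count rates nonlinearly)
# and aligned for stage/beam drift.

#' Construct an ion stack
#'
#' @param planes list of 2-D nonnegative count matrices, all the same
#'   shape. Non-integer counts are allowed (dead-time-corrected data).
#' @param species ion species label, e.g. "12C14N".
#' @param dwell_time dwell time per pixel in seconds (> 0; default 5 ms).
#' @param dead_time detector dead time in seconds (>= 0; default 44 ns,
#'   typical for the instrument class -- configurable because vendors
#'   differ).
#' @param pixel_size pixel size in nm (metadata only).
#' @param meta free-form metadata list.
#' @return object of class `ion_stack`.
#' @export
ion_stack <- function(planes, species = "12C14N", dwell_time = 5e-3,
                      dead_time = 44e-9, pixel_size = 78, meta = list()) {
  stopifnot(length(planes) >= 1, dwell_time > 0, dead_time >= 0)
  sh <- dim(planes[[1]])
  for (p in planes) {
    if (!all(dim(p) == sh)) stop("ion_stack: planes differ in shape")
    if (any(p < 0)) stop("ion_stack: negative counts")
  }
  structure(list(planes = planes, species = species,
                 dwell_time = dwell_time, dead_time = dead_time,
                 pixel_size = pixel_size, meta = meta),
            class = "ion_stack")
}

#' @export
print.ion_stack <- function(x, ...) {
  sh <- dim(x$planes[[1]])
  cat("<ion_stack> ", x$species, ": ", length(x$planes), " plane(s) of ",
      sh[1], "x", sh[2], ", dwell ", format(x$dwell_time), " s, dead time ",
      format(x$dead_time), " s\n", sep = "")
  invisible(x)
}

#' Dead-time correction of observed counts
#'
#' Per pixel and plane, `N_true = N_obs / (1 - N_obs * dead_time /
#' dwell_time)` (non-paralyzable detector model). The correction is
#' monotone, leaves zero counts at zero, is the identity when
#' `dead_time = 0`, and exactly inverts the deflation
#' `N_obs = N / (1 + N * dead_time / dwell_time)` applied by the synthetic
#' generator.
#'
#' @param stack an [ion_stack()]; each pixel must satisfy
#'   `N_obs * dead_time / dwell_time < 1` (below saturation).
#' @return corrected [ion_stack()] (counts may be non-integer).
#' @export
dead_time_correct <- function(stack) {
  stopifnot(inherits(stack, "ion_stack"))
  if (stack$dead_time == 0) return(stack)
  k <- stack$dead_time / stack$dwell_time
  planes <- lapply(seq_along(stack$planes), function(i) {
    p <- stack$planes[[i]]
    denom <- 1 - p * k
    if (any(denom <= 0)) {
      bad <- which(denom <= 0)[1]
      stop("dead_time_correct: pixel ", bad, " of plane ", i,
           " is saturated (N_obs = ", p[bad], ", dead_time/dwell = ",
           format(k), ")")
    }
    p / denom
  })
  out <- stack
  out$planes <- planes
  out$meta$dead_time_corrected <- TRUE
  out
}

#' Estimate per-plane drift against a reference plane
#'
#' Integer (dx, dy) pixel shifts maximizing the circular cross-correlation
#' (computed by FFT on mean-subtracted planes) with the reference plane;
#' the convention is that plane content equals the reference shifted by
#' `+dx` columns and `+dy` rows. A flat (zero-variance) plane gets shift
#' (0, 0) with a warning.
#'
#' @param stack an [ion_stack()] with at least 2 planes (a single plane
#'   returns (0,0)).
#' @param reference_plane index of the reference plane (default 1).
#' @return integer matrix `n_planes x 2` with columns `dx`, `dy`; the
#'   reference row is (0, 0).
#' @export
estimate_plane_drift <- function(stack, reference_plane = 1L) {
  stopifnot(inherits(stack, "ion_stack"))
  n <- length(stack$planes)
  if (reference_plane < 1 || reference_plane > n) {
    stop("estimate_plane_drift: invalid reference plane")
  }
  ref <- stack$planes[[reference_plane]]
  H <- nrow(ref); W <- ncol(ref)
  ref0 <- ref - mean(ref)
  Fr <- stats::fft(ref0)
  out <- matrix(0L, n, 2, dimnames = list(NULL, c("dx", "dy")))
  for (p in seq_len(n)) {
    if (p == reference_plane) next
    pl <- stack$planes[[p]]
    if (stats::sd(pl) == 0) {
      warning("estimate_plane_drift: plane ", p, " is flat; assuming no drift")
      next
    }
    cc <- Re(stats::fft(stats::fft(pl - mean(pl)) * Conj(Fr), inverse = TRUE))
    k <- which.max(cc)
    dy <- (k - 1) %% H
    dx <- (k - 1) %/% H
    if (dy > H / 2) dy <- dy - H
    if (dx > W / 2) dx <- dx - W
    out[p, ] <- c(dx, dy)
  }
  out
}

#' Accumulate a drift-corrected stack into one count image
#'
#' Each plane is shifted back by its drift vector and the planes are
#' summed. Pixels not covered by every plane after the inverse shifts are
#' masked (`NA`); on the fully covered region the total equals the sum of
#' the plane counts.
#'
#' @param stack an [ion_stack()].
#' @param drifts `n_planes x 2` (dx, dy) matrix as returned by
#'   [estimate_plane_drift()]; NULL estimates it (or uses zero for a
#'   single plane).
#' @return numeric matrix of summed counts with `NA` outside the common
#'   coverage; the coverage mask is attached as attribute `coverage`.
#' @export
accumulate_planes <- function(stack, drifts = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  n <- length(stack$planes)
  if (is.null(drifts)) {
    drifts <- if (n == 1) matrix(0L, 1, 2) else estimate_plane_drift(stack)
  }
  stopifnot(nrow(drifts) == n)
  sh <- dim(stack$planes[[1]])
  total <- matrix(0, sh[1], sh[2])
  cover <- matrix(TRUE, sh[1], sh[2])
  for (p in seq_len(n)) {
    shifted <- shift_image(stack$planes[[p]], -drifts[p, 1], -drifts[p, 2],
                           fill = NA_real_)
    cover <- cover & !is.na(shifted)
    shifted[is.na(shifted)] <- 0
    total <- total + shifted
  }
  total[!cover] <- NA_real_
  attr(total, "coverage") <- cover
  total
}

#' Dead-time-correct, drift-correct and accumulate both species
#'
#' Standard correction order: the (nonlinear) dead-time correction is
#' applied per plane first, then drift is estimated on the reference
#' species (the high-count 12C14N image) and applied to both species so
#' the ratio stays aligned.
#'
#' @param cn14,cn15 [ion_stack()]s of the two species, same geometry.
#' @param drifts optional known drift matrix; estimated from `cn14` when
#'   NULL.
#' @return list with accumulated `cn14`, `cn15` matrices (NA outside
#'   common coverage) and the `drifts` used.
#' @export
correct_and_accumulate <- function(cn14, cn15, drifts = NULL) {
  cn14c <- dead_time_correct(cn14)
  cn15c <- dead_time_correct(cn15)
  if (is.null(drifts)) {
    drifts <- if (length(cn14c$planes) == 1) matrix(0L, 1, 2) else
      estimate_plane_drift(cn14c)
  }
  a14 <- accumulate_planes(cn14c, drifts)
  a15 <- accumulate_planes(cn15c, drifts)
  joint <- attr(a14, "coverage") & attr(a15, "coverage")
  a14[!joint] <- NA_real_
  a15[!joint] <- NA_real_
  list(cn14 = a14, cn15 = a15, drifts = drifts)
}
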