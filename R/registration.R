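# EM -> SIMS frame registration. A 4-DOF similarity transform (isotropic
# scale, rotation, translation -- no shear, reflection disallowed) maps EM
# pixel coordinates onto the SIMS raster; it is fitted in closed form from
# anchor-point pairs (least squares on the centered cross-covariance) and
# used to warp ROI masks into SIMS coordinates.

#' Construct a similarity transform
#'
#' Maps EM (x, y) points to SIMS points by
#' `p' = s * R(theta) %*% p + t`, with x = column and y = row, theta in
#' radians counterclockwise in the (x, y) plane.
#'
#' @param scale isotropic scale `s > 0`.
#' @param theta rotation in radians.
#' @param tx,ty translation in SIMS pixels.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, theta = 0, tx = 0, ty = 0) {
  stopifnot(scale > 0, is.finite(theta), is.finite(tx), is.finite(ty))
  structure(list(scale = unname(scale), theta = unname(theta),
                 tx = unname(tx), ty = unname(ty)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> s = %.6g, theta = %.4f rad (%.2f deg), t = (%.4g, %.4g)\n",
              x$scale, x$theta, x$theta * 180 / pi, x$tx, x$ty))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param tf a [similarity_transform()].
#' @param xy matrix (or length-2 vector) of (x, y) points.
#' @return matrix of transformed (x, y) points.
#' @export
transform_points <- function(tf, xy) {
  stopifnot(inherits(tf, "similarity_transform"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  ct <- cos(tf$theta); st <- sin(tf$theta)
  cbind(tf$scale * (xy[, 1] * ct - xy[, 2] * st) + tf$tx,
        tf$scale * (xy[, 1] * st + xy[, 2] * ct) + tf$ty)
}

#' Invert a similarity transform
#' @param tf a [similarity_transform()].
#' @return the inverse transform (SIMS -> EM).
#' @export
invert_transform <- function(tf) {
  s <- 1 / tf$scale
  th <- -tf$theta
  ct <- cos(th); st <- sin(th)
  similarity_transform(
    scale = s, theta = th,
    tx = -s * (tf$tx * ct - tf$ty * st),
    ty = -s * (tf$tx * st + tf$ty * ct)
  )
}

#' Compose two similarity transforms
#' @param a,b transforms; the result applies `b` first, then `a`.
#' @return a [similarity_transform()].
#' @export
compose_transforms <- function(a, b) {
  # a(b(p)) = sa R(ta) (sb R(tb) p + tb_vec) + ta_vec
  t_new <- transform_points(a, c(b$tx, b$ty))
  similarity_transform(scale = a$scale * b$scale, theta = a$theta + b$theta,
                       tx = t_new[1], ty = t_new[2])
}

#' Fit a similarity transform from anchor-point pairs
#'
#' Closed-form least squares (Umeyama/Procrustes): both point sets are
#' centered, the rotation comes from the SVD of the cross-covariance with
#' the determinant constrained positive (no reflection), and the scale
#' from the projected variance ratio. Exact (residual ~ 0) whenever the
#' pairs are consistent with a single similarity.
#'
#' @param anchors data frame with columns `em_x`, `em_y`, `sims_x`,
#'   `sims_y`; at least 2 non-coincident pairs.
#' @return list with `transform` (a [similarity_transform()]) and
#'   `rms_residual` (RMS of `|T(em) - sims|` in SIMS px).
#' @export
fit_similarity <- function(anchors) {
  need <- c("em_x", "em_y", "sims_x", "sims_y")
  stopifnot(all(need %in% names(anchors)))
  X <- as.matrix(anchors[, c("em_x", "em_y")])
  Y <- as.matrix(anchors[, c("sims_x", "sims_y")])
  if (nrow(X) < 2) stop("fit_similarity: need at least 2 anchor pairs")
  if (anyDuplicated(X) && nrow(unique(X)) < 2) {
    stop("fit_similarity: EM anchor points are coincident")
  }
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("fit_similarity: anchor coordinates must be finite")
  }
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  vx <- sum(Xc^2)
  if (vx == 0) stop("fit_similarity: EM anchor points are coincident")
  S <- t(Yc) %*% Xc # 2x2 cross-covariance (unnormalized)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(diag(D) * sv$d) / vx
  theta <- atan2(R[2, 1], R[1, 1])
  t_vec <- my - s * as.vector(R %*% mx)
  tf <- similarity_transform(scale = s, theta = theta,
                             tx = t_vec[1], ty = t_vec[2])
  res <- transform_points(tf, X) - Y
  list(transform = tf, rms_residual = sqrt(mean(rowSums(res^2))))
}

#' Warp a mask from the EM frame into the SIMS frame
#'
#' Inverse mapping with nearest-neighbor interpolation, so masks stay
#' binary: every SIMS pixel center is mapped through the inverse transform
#' and takes the value of the nearest EM pixel. Mask area scales by `s^2`
#' up to discretization. A mask falling entirely outside the SIMS frame
#' yields an empty mask with a warning.
#'
#' @param mask logical matrix in EM coordinates.
#' @param tf EM -> SIMS [similarity_transform()].
#' @param sims_shape (H, W) of the SIMS frame.
#' @return logical matrix of shape `sims_shape`.
#' @export
warp_mask <- function(mask, tf, sims_shape) {
  stopifnot(is.matrix(mask), inherits(tf, "similarity_transform"))
  H <- sims_shape[1]; W <- sims_shape[2]
  out <- matrix(FALSE, H, W)
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  # bounding box of the transformed mask, clipped to the SIMS frame
  rc <- idx_to_rc(idx, nrow(mask))
  corners <- cbind(
    x = c(min(rc[, 2]), min(rc[, 2]), max(rc[, 2]), max(rc[, 2])),
    y = c(min(rc[, 1]), max(rc[, 1]), min(rc[, 1]), max(rc[, 1]))
  )
  bb <- transform_points(tf, corners)
  c0 <- max(1L, floor(min(bb[, 1])) - 1L); c1 <- min(W, ceiling(max(bb[, 1])) + 1L)
  r0 <- max(1L, floor(min(bb[, 2])) - 1L); r1 <- min(H, ceiling(max(bb[, 2])) + 1L)
  if (c0 > c1 || r0 > r1) {
    warning("warp_mask: mask falls entirely outside the SIMS frame")
    return(out)
  }
  inv <- invert_transform(tf)
  sx <- rep(c0:c1, each = r1 - r0 + 1L)
  sy <- rep(r0:r1, times = c1 - c0 + 1L)
  em <- transform_points(inv, cbind(sx, sy))
  er <- as.integer(round(em[, 2])); ec <- as.integer(round(em[, 1]))
  j <- rc_to_idx(er, ec, dim(mask))
  hit <- !is.na(j)
  hit[hit] <- mask[j[hit]]
  if (!any(hit)) {
    warning("warp_mask: mask falls entirely outside the SIMS frame")
    return(out)
  }
  out[cbind(sy[hit], sx[hit])] <- TRUE
  out
}

#' Warp an ROI set into the SIMS frame
#'
#' Applies [warp_mask()] to every instance; instances that vanish are
#' dropped with a warning.
#'
#' @param rois [roi_set()] in EM coordinates.
#' @param tf EM -> SIMS transform.
#' @param sims_shape (H, W) of the SIMS frame.
#' @return [roi_set()] in SIMS coordinates.
#' @export
warp_roi_set <- function(rois, tf, sims_shape) {
  pixels <- list(); keep <- logical(length(rois))
  for (i in seq_len(length(rois))) {
    w <- suppressWarnings(warp_mask(roi_mask(rois, i), tf, sims_shape))
    keep[i] <- any(w)
    if (keep[i]) pixels[[sum(keep)]] <- which(w)
  }
  if (!all(keep)) {
    warning("warp_roi_set: ", sum(!keep), " instance(s) fell outside the SIMS frame")
  }
  roi_set(pixels, rois$table$class_id[keep], sims_shape, rois$classes,
          confidence = rois$table$confidence[keep],
          support = rois$table$support[keep],
          id = rois$table$id[keep])
}

#' Warp an intensity image between frames (bilinear)
#'
#' @param image numeric matrix in EM coordinates.
#' @param tf EM -> SIMS transform.
#' @param sims_shape output (H, W).
#' @param fill value outside the source image.
#' @return numeric matrix.
#' @export
warp_image <- function(image, tf, sims_shape, fill = 0) {
  H <- sims_shape[1]; W <- sims_shape[2]
  inv <- invert_transform(tf)
  sx <- rep(seq_len(W), each = H)
  sy <- rep(seq_len(H), times = W)
  em <- transform_points(inv, cbind(sx, sy))
  x <- em[, 1]; y <- em[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  g <- function(r, c) {
    ok <- r >= 1 & r <= nrow(image) & c >= 1 & c <= ncol(image)
    v <- rep(fill, length(r))
    v[ok] <- image[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x0 + 1) +
    (1 - fx) * fy * g(y0 + 1, x0) + fx * fy * g(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

#' Read / write anchor-point CSV
#'
#' Anchor files replace interactive overlay tools: four columns
#' `em_x, em_y, sims_x, sims_y`, one row per anchor pair.
#'
#' @param path CSV file.
#' @return data frame of anchors.
#' @export
read_anchors <- function(path) {
  a <- utils::read.csv(path)
  need <- c("em_x", "em_y", "sims_x", "sims_y")
  if (!all(need %in% names(a))) {
    stop("read_anchors: expected columns ", paste(need, collapse = ", "))
  }
  a
}

#' @rdname read_anchors
#' @param anchors data frame of anchor pairs.
#' @export
write_anchors <- function(anchors, path) {
  utils::write.csv(anchors, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted transform to JSON
#' @param fit result of [fit_similarity()] (or a bare transform).
#' @param path output file.
#' @export
write_transform_json <- function(fit, path) {
  tf <- if (inherits(fit, "similarity_transform")) fit else fit$transform
  x <- list(s = tf$scale, theta_deg = tf$theta * 180 / pi,
            tx = tf$tx, ty = tf$ty, direction = "em_to_sims",
            rms_residual = if (is.list(fit) && !is.null(fit$rms_residual))
              fit$rms_residual else NA_real_)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform JSON written by [write_transform_json()]
#' @param path JSON file.
#' @return a [similarity_transform()].
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(scale = x$s, theta = x$theta_deg * pi / 180,
                       tx = x$tx, ty = x$ty)
}

# centroids of large blobs for automatic anchoring
blob_centroids <- function(mask, min_area) {
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) return(cbind(x = numeric(0), y = numeric(0), area = numeric(0)))
  out <- matrix(0, 0, 3)
  for (g in seq_len(max(lab))) {
    idx <- which(lab == g)
    if (length(idx) < min_area) next
    rc <- idx_to_rc(idx, nrow(mask))
    out <- rbind(out, c(mean(rc[, 2]), mean(rc[, 1]), length(idx)))
  }
  colnames(out) <- c("x", "y", "area")
  out
}

#' Automatic anchor points from nucleolus-like blobs
#'
#' Dense nuclear structures are dark in EM and CN-rich (bright) in the
#' 12C14N image, so they are segmentable in both modalities and usable as
#' registration anchors. Large dark blobs are extracted from the EM image
#' and large bright blobs from the accumulated 12C14N image; with k blobs
#' per modality (k capped at `max_blobs`, largest first) all k!
#' pairings are scored by similarity-fit RMS residual and the best
#' assignment returned as anchors.
#'
#' @param em_image EM image matrix (values in `[0, 1]`).
#' @param sims_cn14 accumulated 12C14N count image (NA allowed).
#' @param min_area_em,min_area_sims minimum blob areas in px.
#' @param max_blobs cap on blobs per modality (default 6; assignment is
#'   enumerated, so keep this small).
#' @return anchors data frame as for [fit_similarity()], with attribute
#'   `rms_residual` of the winning assignment.
#' @export
auto_anchor_nuclei <- function(em_image, sims_cn14,
                               min_area_em = 150, min_area_sims = 25,
                               max_blobs = 6L) {
  # EM: dark blobs well below the background level
  thr_em <- stats::quantile(em_image, 0.001) * 0.5 +
    stats::median(em_image) * 0.5
  em_blobs <- blob_centroids(em_image < thr_em, min_area_em)
  s14 <- sims_cn14
  s14[is.na(s14)] <- stats::median(s14, na.rm = TRUE)
  thr_s <- stats::median(s14) + 0.5 * (max(s14) - stats::median(s14))
  sims_blobs <- blob_centroids(s14 > thr_s, min_area_sims)
  k <- min(nrow(em_blobs), nrow(sims_blobs), max_blobs)
  if (k < 2) {
    stop("auto_anchor_nuclei: found fewer than 2 blob pairs; ",
         "provide manual anchors instead")
  }
  em_blobs <- em_blobs[order(-em_blobs[, "area"])[seq_len(k)], , drop = FALSE]
  sims_blobs <- sims_blobs[order(-sims_blobs[, "area"])[seq_len(k)], , drop = FALSE]
  perms <- all_permutations(k)
  best <- NULL; best_rms <- Inf
  for (pi in seq_len(nrow(perms))) {
    a <- data.frame(em_x = em_blobs[, "x"], em_y = em_blobs[, "y"],
                    sims_x = sims_blobs[perms[pi, ], "x"],
                    sims_y = sims_blobs[perms[pi, ], "y"])
    f <- tryCatch(fit_similarity(a), error = function(e) NULL)
    if (!is.null(f) && f$rms_residual < best_rms && f$transform$scale > 0) {
      best_rms <- f$rms_residual
      best <- a
    }
  }
  if (is.null(best)) stop("auto_anchor_nuclei: no valid blob assignment")
  attr(best, "rms_residual") <- best_rms
  best
}

# all permutations of 1..k as rows (k small)
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- (1:k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}
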