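# Instance containers and multi-pass mask compilation. Offset tiling means
# the same organelle is detected several times (possibly truncated at some
# passes' tile boundaries); detections are linked by mask overlap, kept when
# enough passes agree, and merged by union so pixels truncated in one pass
# are recovered from another. Morphological filtering then removes partial
# or implausible instances (e.g. half vesicles, which lose their circular
# shape at a tile boundary).

#' Construct an ROI set
#'
#' The package's instance-mask container: a table of instances plus a list
#' of pixel-index vectors (linear indices into the image matrix). Masks may
#' overlap across classes but are disjoint within a class after assembly.
#'
#' @param pixels list of integer vectors of linear pixel indices.
#' @param class_id integer vector, 1-based index into `classes`.
#' @param image_shape (H, W).
#' @param classes class name vector.
#' @param confidence per-instance confidence in `[0, 1]`.
#' @param support number of passes contributing to each instance.
#' @param id instance ids (unique).
#' @return object of class `roi_set`.
#' @export
roi_set <- function(pixels, class_id, image_shape,
                    classes = organelle_classes(),
                    confidence = 1, support = 1L,
                    id = seq_along(pixels)) {
  n <- length(pixels)
  stopifnot(length(class_id) == n, !anyDuplicated(id))
  if (n > 0 && (any(class_id < 1) || any(class_id > length(classes)))) {
    stop("roi_set: class_id out of range")
  }
  tab <- data.frame(
    id = as.integer(id),
    class_id = as.integer(class_id),
    class = classes[class_id],
    support = rep_len(as.integer(support), n),
    confidence = rep_len(as.numeric(confidence), n),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, pixels = pixels,
                 image_shape = as.integer(image_shape), classes = classes),
            class = "roi_set")
}

#' @export
length.roi_set <- function(x) nrow(x$table)

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", nrow(x$table), " instances on a ",
      x$image_shape[1], "x", x$image_shape[2], " frame\n", sep = "")
  if (nrow(x$table)) print(table(x$table$class))
  invisible(x)
}

#' @export
as.data.frame.roi_set <- function(x, ...) {
  tab <- x$table
  H <- x$image_shape[1]
  tab$area <- lengths(x$pixels)
  cent <- t(vapply(x$pixels, function(idx) {
    rc <- idx_to_rc(idx, H)
    c(mean(rc[, 1]), mean(rc[, 2]))
  }, numeric(2)))
  tab$centroid_row <- cent[, 1]
  tab$centroid_col <- cent[, 2]
  tab
}

#' Materialize one instance mask as a logical matrix
#'
#' @param rois an [roi_set()].
#' @param i instance position (row in `rois$table`).
#' @return logical matrix.
#' @export
roi_mask <- function(rois, i) {
  idx_to_mask(rois$pixels[[i]], rois$image_shape)
}

# IoU on pixel-index vectors
iou_idx <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) stop("IoU of two empty masks is undefined")
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' Compile detections from multiple offset passes into one ROI set
#'
#' Same-class detections are linked into groups by pairwise mask IoU at or
#' above `iou_link` (transitive closure); groups supported by fewer than
#' `min_support` distinct passes are dropped; each surviving instance is
#' the union of its members' masks. Surviving same-class instances that
#' still overlap are resolved by confidence: the higher-confidence instance
#' claims contested pixels.
#'
#' @param detections list of detections from [run_pass()] (masks in
#'   original-image pixel indices).
#' @param n_passes number of passes run.
#' @param iou_link IoU linking threshold in (0, 1); default 0.5.
#' @param min_support minimum number of distinct passes per instance;
#'   default 2 (a boundary-truncated single-pass fragment is rejected, any
#'   two-pass consensus survives).
#' @param image_shape (H, W) of the original image.
#' @param classes class name vector.
#' @return an [roi_set()]; instance `support` is the distinct-pass count
#'   and `confidence` the maximum member confidence.
#' @export
merge_passes <- function(detections, n_passes, iou_link = 0.5,
                         min_support = 2L, image_shape,
                         classes = organelle_classes()) {
  stopifnot(iou_link > 0, iou_link < 1,
            min_support >= 1, min_support <= n_passes)
  if (length(detections) == 0L) {
    return(roi_set(list(), integer(), image_shape, classes))
  }
  cls <- vapply(detections, function(d) d$class_id, integer(1))
  conf <- vapply(detections, function(d) d$confidence, numeric(1))
  pass <- vapply(detections, function(d) d$pass_index, integer(1))
  pixels <- list(); class_id <- integer(); support <- integer(); confv <- numeric()
  for (ci in sort(unique(cls))) {
    ii <- which(cls == ci)
    n <- length(ii)
    # transitive closure of the IoU-link relation via union-find
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    if (n > 1) {
      for (a in 1:(n - 1)) for (b in (a + 1):n) {
        if (iou_idx(detections[[ii[a]]]$pixels, detections[[ii[b]]]$pixels) >= iou_link) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    for (g in unique(root)) {
      members <- ii[root == g]
      sup <- length(unique(pass[members]))
      if (sup < min_support) next
      merged <- sort(unique(unlist(lapply(detections[members], `[[`, "pixels"))))
      pixels[[length(pixels) + 1L]] <- merged
      class_id <- c(class_id, ci)
      support <- c(support, sup)
      confv <- c(confv, max(conf[members]))
    }
  }
  # same-class overlap: higher confidence claims contested pixels
  # (ties broken by support, then area, so a multi-pass consensus instance
  # always beats its own single-pass fragments)
  if (length(pixels) > 1) {
    for (ci in unique(class_id)) {
      jj <- which(class_id == ci)
      if (length(jj) < 2) next
      jj <- jj[order(confv[jj], support[jj], lengths(pixels[jj]),
                     decreasing = TRUE)]
      claimed <- integer(0)
      for (j in jj) {
        pixels[[j]] <- setdiff(pixels[[j]], claimed)
        claimed <- c(claimed, pixels[[j]])
      }
    }
    keep <- lengths(pixels) > 0L
    pixels <- pixels[keep]; class_id <- class_id[keep]
    support <- support[keep]; confv <- confv[keep]
  }
  roi_set(pixels, class_id, image_shape, classes,
          confidence = confv, support = support)
}

#' Shape descriptors of a connected mask
#'
#' Area (pixel count), chain-code perimeter (see [mask_perimeter()]),
#' circularity `4*pi*A / P^2` (1 for a continuous disk; raster estimates
#' may slightly exceed 1), and solidity (area / convex-hull area).
#'
#' @param mask logical matrix, nonempty and connected.
#' @return list with `area`, `perimeter`, `circularity`, `solidity`.
#' @export
shape_descriptors <- function(mask) {
  if (!any(mask)) stop("shape_descriptors: empty mask")
  area <- sum(mask)
  per <- mask_perimeter(mask)
  rc <- idx_to_rc(which(mask), nrow(mask))
  hull_area <- if (nrow(rc) >= 3) {
    h <- grDevices::chull(rc[, 2], rc[, 1])
    xs <- rc[h, 2]; ys <- rc[h, 1]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  } else 0
  list(
    area = area,
    perimeter = per,
    circularity = 4 * pi * area / per^2,
    solidity = if (hull_area > 0) min(1, area / hull_area) else 1
  )
}

#' Default per-class morphological filter rules
#'
#' Every class gets a minimum area (removes contour noise); circular
#' classes (vesicles, vacuoles) additionally require a minimum circularity
#' so that partially detected instances truncated at tile boundaries are
#' removed.
#'
#' @param min_area minimum instance area in px^2 (default 20).
#' @param min_circularity circularity floor for vesicle/vacuole classes.
#' @return named list of per-class rules.
#' @export
default_filter_rules <- function(min_area = 20, min_circularity = 0.7) {
  rules <- lapply(organelle_classes(), function(cl) {
    r <- list(min_area = min_area)
    if (cl %in% c("vesicles", "vacuoles")) r$min_circularity <- min_circularity
    r
  })
  stats::setNames(rules, organelle_classes())
}

#' Remove implausible instances by per-class morphological rules
#'
#' @param rois an [roi_set()].
#' @param rules named list per class: `min_area`, optional
#'   `min_circularity`, optional `min_solidity`. Classes present in `rules`
#'   must exist in `rois$classes`.
#' @return filtered [roi_set()] with attribute `removal_log`, a data frame
#'   of removed instance ids and the rule each failed.
#' @export
morphological_filter <- function(rois, rules = default_filter_rules()) {
  stopifnot(inherits(rois, "roi_set"))
  unknown <- setdiff(names(rules), rois$classes)
  if (length(unknown)) {
    stop("morphological_filter: unknown class in rules: ",
         paste(unknown, collapse = ", "))
  }
  n <- length(rois)
  keep <- rep(TRUE, n)
  log_id <- integer(); log_rule <- character()
  for (i in seq_len(n)) {
    cl <- rois$table$class[i]
    rule <- rules[[cl]]
    if (is.null(rule)) next
    desc <- NULL
    if (!is.null(rule$min_area) && lengths(rois$pixels[i]) < rule$min_area) {
      keep[i] <- FALSE
      log_id <- c(log_id, rois$table$id[i]); log_rule <- c(log_rule, "min_area")
      next
    }
    if (!is.null(rule$min_circularity) || !is.null(rule$min_solidity)) {
      desc <- shape_descriptors(roi_mask(rois, i))
    }
    if (!is.null(rule$min_circularity) && desc$circularity < rule$min_circularity) {
      keep[i] <- FALSE
      log_id <- c(log_id, rois$table$id[i]); log_rule <- c(log_rule, "min_circularity")
      next
    }
    if (!is.null(rule$min_solidity) && desc$solidity < rule$min_solidity) {
      keep[i] <- FALSE
      log_id <- c(log_id, rois$table$id[i]); log_rule <- c(log_rule, "min_solidity")
    }
  }
  out <- roi_set(rois$pixels[keep], rois$table$class_id[keep],
                 rois$image_shape, rois$classes,
                 confidence = rois$table$confidence[keep],
                 support = rois$table$support[keep],
                 id = rois$table$id[keep])
  attr(out, "removal_log") <- data.frame(id = log_id, rule = log_rule,
                                         stringsAsFactors = FALSE)
  out
}
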