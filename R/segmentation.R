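# Per-tile instance segmentation. The real detector in this workflow is a
# trained neural instance-segmentation network; its weights are neither
# distributable nor needed to validate the pipeline, so the package defines
# a backend contract and ships a deterministic classical backend that
# thresholds the phantom's class intensity bands. Any adapter implementing
# the same contract (predict(tile) -> list of detections) plugs in
# unchanged. Training-data export writes the polygon label text format and
# dataset layout that detector tooling consumes.

#' Construct a detection
#'
#' @param class_id 1-based class index.
#' @param pixels linear pixel indices of the mask.
#' @param shape shape of the frame the indices refer to.
#' @param confidence score in `[0, 1]`.
#' @param tile_index,pass_index provenance (0 when not tiled).
#' @return object of class `detection`.
#' @export
detection <- function(class_id, pixels, shape, confidence,
                      tile_index = 0L, pass_index = 0L) {
  stopifnot(length(pixels) > 0, confidence >= 0, confidence <= 1)
  structure(list(class_id = as.integer(class_id), pixels = as.integer(pixels),
                 shape = as.integer(shape), confidence = as.numeric(confidence),
                 tile_index = as.integer(tile_index),
                 pass_index = as.integer(pass_index)),
            class = "detection")
}

#' Deterministic classical segmentation backend
#'
#' Thresholds each phantom class intensity band, labels connected
#' components (8-connectivity), and assigns the band's class. The
#' component is extracted with a slightly widened window and its
#' confidence is the band purity: the fraction of component pixels inside
#' the nominal band. Components smaller than `min_area` pixels are
#' ignored. The backend is parameter-free on phantom images because the
#' class-to-band mapping is fixed by [phantom_bands()].
#'
#' @param classes class name vector.
#' @param bands band definition as from [phantom_bands()].
#' @param min_area minimum component area in pixels (default 5).
#' @return object of class `segmentation_backend` with fields `name`,
#'   `classes`, and `predict(tile)`.
#' @export
toy_backend <- function(classes = organelle_classes(),
                        bands = phantom_bands(), min_area = 5L) {
  hw <- bands$halfwidth
  hw_extract <- hw * 1.2 # widened so edge pixels count against purity
  predict_fn <- function(tile) {
    out <- list()
    for (ci in seq_along(classes)) {
      ctr <- bands$center[[classes[ci]]]
      mask <- abs(tile - ctr) <= hw_extract
      if (!any(mask)) next
      lab <- label_components(mask, connectivity = 8)
      for (g in seq_len(max(lab))) {
        idx <- which(lab == g)
        if (length(idx) < min_area) next
        purity <- mean(abs(tile[idx] - ctr) <= hw)
        out[[length(out) + 1L]] <- detection(
          class_id = ci, pixels = idx, shape = dim(tile),
          confidence = purity
        )
      }
    }
    out
  }
  structure(list(name = "toy", classes = classes, predict = predict_fn),
            class = "segmentation_backend")
}

#' @export
print.segmentation_backend <- function(x, ...) {
  cat("<segmentation_backend> ", x$name, " (", length(x$classes),
      " classes)\n", sep = "")
  invisible(x)
}

#' Run one segmentation pass over a tiled image
#'
#' Extracts the grid's tiles, predicts each with the backend, and
#' translates every detection mask into original-image coordinates via
#' [to_original_coords()]. Mask pixels falling in the padding are clipped;
#' detections wholly inside the padding are dropped. A backend failure on
#' a tile skips that tile (the failure count is attached as attribute
#' `failures`).
#'
#' @param image numeric matrix.
#' @param grid a [build_tile_grid()] grid built from `dim(image)`.
#' @param backend a [toy_backend()] or any object honoring the backend
#'   contract.
#' @return list of [detection()]s with pixels as linear indices into the
#'   original image.
#' @export
run_pass <- function(image, grid, backend) {
  stopifnot(inherits(grid, "tile_grid"))
  tiles <- extract_tiles(image, grid)
  H <- grid$image_shape[1]; W <- grid$image_shape[2]
  out <- list()
  failures <- 0L
  for (ti in seq_along(tiles)) {
    dets <- tryCatch(backend$predict(tiles[[ti]]), error = function(e) {
      warning("run_pass: backend failed on tile ", ti, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(dets)) { failures <- failures + 1L; next }
    for (d in dets) {
      rc <- idx_to_rc(d$pixels, grid$frame)
      mapped <- to_original_coords(grid, ti, rc)
      keep <- mapped$in_image
      if (!any(keep)) next # wholly inside padding
      idx <- rc_to_idx(mapped$row[keep], mapped$col[keep], c(H, W))
      out[[length(out) + 1L]] <- detection(
        class_id = d$class_id, pixels = idx, shape = c(H, W),
        confidence = d$confidence, tile_index = ti,
        pass_index = grid$pass_index
      )
    }
  }
  attr(out, "failures") <- failures
  out
}

#' Run all offset passes over an image
#'
#' Convenience wrapper: builds the grid of every pass offset (see
#' [pass_offsets()]) and concatenates the per-pass detections.
#'
#' @param image numeric matrix.
#' @param frame tile side (default 640).
#' @param n_passes number of offset passes.
#' @param backend segmentation backend.
#' @return list of detections in original coordinates.
#' @export
run_passes <- function(image, frame = 640L, n_passes = 5L,
                       backend = toy_backend()) {
  offs <- pass_offsets(frame, n_passes)
  out <- list()
  for (k in seq_along(offs)) {
    grid <- build_tile_grid(dim(image), frame, offs[k], pass_index = k)
    out <- c(out, run_pass(image, grid, backend))
  }
  out
}

# drop collinear vertices of a closed polygon given as (row, col) matrix
simplify_polygon <- function(v) {
  n <- nrow(v)
  if (n <= 3) return(v)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- v[if (i == 1) n else i - 1, ]
    q <- v[i, ]
    r <- v[if (i == n) 1 else i + 1, ]
    cross <- (q[1] - p[1]) * (r[2] - q[2]) - (q[2] - p[2]) * (r[1] - q[1])
    keep[i] <- cross != 0
  }
  if (sum(keep) < 3) return(v)
  v[keep, , drop = FALSE]
}

#' Export ground-truth masks as polygon label text
#'
#' One line per instance: the 0-based class id followed by the external
#' contour vertices normalized to `[0, 1]` by image width/height,
#' alternating x (column) then y (row), with collinear vertices dropped.
#' This is the segmentation label text format detector tooling consumes
#' (one `.txt` per image). Instances with fewer than 3 boundary pixels are
#' skipped with a warning. Holes are discarded (external contour only).
#'
#' @param truth an [roi_set()].
#' @param image_shape (H, W); defaults to the set's own shape.
#' @param digits decimals in the normalized coordinates (default 4).
#' @return character vector of label lines (possibly empty).
#' @export
masks_to_labels <- function(truth, image_shape = truth$image_shape,
                            digits = 4L) {
  stopifnot(inherits(truth, "roi_set"))
  H <- image_shape[1]; W <- image_shape[2]
  fmt <- paste0("%.", digits, "f")
  lines <- character(0)
  for (i in seq_len(length(truth))) {
    mask <- roi_mask(truth, i)
    ct <- trace_contour(mask)
    if (nrow(ct) < 3) {
      warning("masks_to_labels: instance ", truth$table$id[i],
              " has fewer than 3 boundary pixels; skipped")
      next
    }
    v <- simplify_polygon(ct)
    x <- (v[, 2] - 1) / W # 0-based pixel index over width
    y <- (v[, 1] - 1) / H
    coords <- sprintf(fmt, as.vector(rbind(x, y)))
    lines <- c(lines, paste(c(truth$table$class_id[i] - 1L, coords),
                            collapse = " "))
  }
  lines
}

#' Rasterize one polygon label line back to a mask
#'
#' Inverse of [masks_to_labels()] for round-trip checks.
#'
#' @param line one label line.
#' @param image_shape (H, W).
#' @return list with `class_id` (1-based) and `mask`.
#' @export
labels_to_mask <- function(line, image_shape) {
  f <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
  cid <- as.integer(f[1]) + 1L
  xy <- matrix(f[-1], ncol = 2, byrow = TRUE)
  # back to 1-based pixel centers
  verts <- cbind(x = xy[, 1] * image_shape[2] + 1, y = xy[, 2] * image_shape[1] + 1)
  list(class_id = cid, mask = rasterize_polygon(verts, image_shape))
}

#' Build a detector training dataset from images and truths
#'
#' Writes the `{train,val,test}/{images,labels}` directory layout plus a
#' dataset configuration YAML (paths, class names, class count). Split
#' assignment is a seeded shuffle, deterministic for a given seed.
#'
#' @param images list of image matrices.
#' @param truths list of matching [roi_set()]s.
#' @param out_dir output directory.
#' @param splits named fractions `c(train, val, test)` summing to 1;
#'   `train` must be positive. Splits of 0 produce no folder.
#' @param seed shuffle seed.
#' @return path of the written dataset YAML.
#' @export
build_dataset <- function(images, truths, out_dir,
                          splits = c(train = 0.7, val = 0.3, test = 0),
                          seed = 1L) {
  stopifnot(length(images) == length(truths))
  if (abs(sum(splits) - 1) > 1e-9) stop("build_dataset: splits must sum to 1")
  if (splits[["train"]] <= 0) stop("build_dataset: train fraction must be > 0")
  n <- length(images)
  if (n < sum(splits > 0)) {
    stop("build_dataset: fewer images (", n, ") than nonzero splits")
  }
  counts <- diff(c(0, round(cumsum(splits) * n)))
  names(counts) <- names(splits)
  ord <- with_seed(seed, sample.int(n))
  assign <- rep(names(splits), counts)[order(ord)] # deterministic given seed
  classes <- truths[[1]]$classes
  for (sp in names(splits)[counts > 0]) {
    dir.create(file.path(out_dir, sp, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, sp, "labels"), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    sp <- assign[i]
    stem <- sprintf("img%03d", i)
    write_gray_png(images[[i]], file.path(out_dir, sp, "images", paste0(stem, ".png")))
    writeLines(masks_to_labels(truths[[i]]),
               file.path(out_dir, sp, "labels", paste0(stem, ".txt")))
  }
  cfg <- list(path = normalizePath(out_dir),
              train = "train/images",
              val = if (counts[["val"]] > 0) "val/images" else NULL,
              test = if (!is.na(counts["test"]) && counts[["test"]] > 0) "test/images" else NULL,
              nc = length(classes),
              names = as.list(classes))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml_path <- file.path(out_dir, "dataset.yaml")
  yaml::write_yaml(cfg, yaml_path)
  yaml_path
}
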