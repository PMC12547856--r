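# Contrast normalization and offset multi-pass tiling. EM mega-images are
# orders of magnitude larger than a fixed-frame segmentation backend's
# input; each pass cuts the (reflect-padded) image into disjoint
# frame-by-frame tiles, and successive passes shift the grid origin by
# frame / n_passes pixels on both axes so structures truncated at one
# pass's tile boundaries are seen whole in another.

#' Match an image's histogram to a reference image
#'
#' Monotone quantile mapping: each pixel is replaced by the reference value
#' at its own empirical quantile, the standard histogram-matching transform.
#' Matching an image to itself is the identity, and the mapping is
#' idempotent (re-matching an already matched image changes no pixel).
#'
#' @param image numeric matrix.
#' @param reference numeric matrix (any shape), nonempty and non-constant.
#' @return matrix of `image`'s shape whose empirical CDF approximates the
#'   reference CDF.
#' @export
match_histogram <- function(image, reference) {
  stopifnot(is.matrix(image), length(image) > 0, length(reference) > 0)
  rng <- range(reference)
  if (rng[1] == rng[2]) {
    stop("match_histogram: reference image is constant; choose a reference with contrast")
  }
  src <- sort(unique(as.vector(image)))
  # empirical CDF of the input evaluated at its unique values
  cnt <- tabulate(match(as.vector(image), src), nbins = length(src))
  src_q <- cumsum(cnt) / length(image)
  ref_sorted <- sort(as.vector(reference))
  ref_q <- seq_along(ref_sorted) / length(ref_sorted)
  mapped <- stats::approx(ref_q, ref_sorted, xout = src_q, rule = 2, ties = "ordered")$y
  out <- mapped[match(as.vector(image), src)]
  matrix(out, nrow(image), ncol(image))
}

#' Grid origin offsets for multi-pass tiling
#'
#' `n_passes` equally spaced offsets within one frame period:
#' `k * frame / n_passes` for `k = 0 .. n_passes - 1`. With the default
#' 640-px frame and 5 passes this is 0, 128, 256, 384, 512.
#'
#' @param frame tile side in pixels (default 640).
#' @param n_passes number of passes (must divide `frame`).
#' @return integer vector of offsets.
#' @export
pass_offsets <- function(frame = 640L, n_passes) {
  stopifnot(n_passes >= 1)
  if (frame %% n_passes != 0) {
    valid <- which(frame %% seq_len(frame) == 0)
    stop("pass_offsets: frame ", frame, " is not divisible by ", n_passes,
         " passes; valid pass counts include ",
         paste(utils::head(valid, 12), collapse = ", "))
  }
  as.integer((seq_len(n_passes) - 1L) * (frame %/% n_passes))
}

#' Build the tile grid of one pass
#'
#' The image is notionally padded with `offset` pixels prepended on top and
#' left and enough appended at bottom/right to make both padded dimensions
#' multiples of `frame`; tiles then partition the padded image exactly.
#'
#' @param image_shape (H, W) of the original image.
#' @param frame tile side in pixels.
#' @param offset grid origin offset (applied to both axes), `< frame`.
#' @param pass_index integer identifying the pass (carried into
#'   detections).
#' @return object of class `tile_grid`: fields `frame`, `offset`,
#'   `pass_index`, `image_shape`, `padded_shape`, `pad_offsets`
#'   (top, left), and `tile_origins` (matrix of 1-based (row, col) origins
#'   in padded coordinates, row-major order).
#' @export
build_tile_grid <- function(image_shape, frame = 640L, offset = 0L,
                            pass_index = 1L) {
  stopifnot(image_shape[1] >= 1, image_shape[2] >= 1,
            frame > 0, offset >= 0, offset < frame)
  padded <- as.integer(frame * ceiling((image_shape + offset) / frame))
  rows <- seq(1L, padded[1], by = frame)
  cols <- seq(1L, padded[2], by = frame)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(
    frame = as.integer(frame), offset = as.integer(offset),
    pass_index = as.integer(pass_index),
    image_shape = as.integer(image_shape),
    padded_shape = padded,
    pad_offsets = c(top = as.integer(offset), left = as.integer(offset)),
    tile_origins = origins
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat("<tile_grid> pass ", x$pass_index, ": ", nrow(x$tile_origins),
      " tiles of ", x$frame, "px, offset ", x$offset, ", padded ",
      x$padded_shape[1], "x", x$padded_shape[2], "\n", sep = "")
  invisible(x)
}

# reflect-pad an image to the grid's padded shape (constant padding would
# create false edges at tile borders that segmentation backends detect)
pad_reflect <- function(image, grid) {
  H <- nrow(image); W <- ncol(image)
  top <- grid$pad_offsets[["top"]]; left <- grid$pad_offsets[["left"]]
  bottom <- grid$padded_shape[1] - H - top
  right <- grid$padded_shape[2] - W - left
  # symmetric reflection (edge pixel repeated), valid for any padding size
  reflect_idx <- function(n, pre, post) {
    i <- seq(1L - pre, n + post)
    if (n == 1L) return(rep(1L, length(i)))
    m <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  image[reflect_idx(H, top, bottom), reflect_idx(W, left, right), drop = FALSE]
}

#' Extract the tiles of a pass
#'
#' @param image numeric matrix with `grid$image_shape`.
#' @param grid a [build_tile_grid()] grid.
#' @return list of `frame x frame` matrices in `tile_origins` order.
#' @export
extract_tiles <- function(image, grid) {
  stopifnot(inherits(grid, "tile_grid"),
            all(dim(image) == grid$image_shape))
  padded <- pad_reflect(image, grid)
  f <- grid$frame
  lapply(seq_len(nrow(grid$tile_origins)), function(i) {
    o <- grid$tile_origins[i, ]
    padded[o[1]:(o[1] + f - 1L), o[2]:(o[2] + f - 1L), drop = FALSE]
  })
}

#' Map tile coordinates back to original-image coordinates
#'
#' Inverse of the tiling map: a point (row, col) inside tile `tile_index`
#' is translated by the tile origin and the pad offsets. Points that land
#' in the padding (outside the original image) are flagged.
#'
#' @param grid a [build_tile_grid()] grid.
#' @param tile_index tile number (1-based, `tile_origins` order).
#' @param points matrix (or vector) of (row, col) 1-based tile
#'   coordinates.
#' @return data frame with `row`, `col` in original-image coordinates and
#'   `in_image` (FALSE where the point lies in padding).
#' @export
to_original_coords <- function(grid, tile_index, points) {
  stopifnot(inherits(grid, "tile_grid"))
  if (tile_index < 1 || tile_index > nrow(grid$tile_origins)) {
    stop("to_original_coords: tile_index ", tile_index, " out of range 1..",
         nrow(grid$tile_origins))
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  o <- grid$tile_origins[tile_index, ]
  r <- points[, 1] + o[1] - 1L - grid$pad_offsets[["top"]]
  c <- points[, 2] + o[2] - 1L - grid$pad_offsets[["left"]]
  data.frame(row = r, col = c,
             in_image = r >= 1 & r <= grid$image_shape[1] &
               c >= 1 & c <= grid$image_shape[2])
}

#' Serialize a tile grid to JSON
#' @param grid a [build_tile_grid()] grid.
#' @param path optional output file; if NULL the JSON string is returned.
#' @export
tile_grid_json <- function(grid, path = NULL) {
  x <- unclass(grid)
  x$tile_origins <- unname(x$tile_origins)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
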