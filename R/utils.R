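# Low-level image utilities shared across modules. Images are plain numeric
# matrices with dim = c(H, W), row 1 = top scan line; masks are logical
# matrices of the same shape; label maps are integer matrices with 0 =
# background. Point sets for registration use (x, y) = (col, row) order.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are deterministic
#' without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Linear pixel indices of a logical mask
#' @keywords internal
mask_to_idx <- function(mask) which(mask)

#' Logical mask from linear pixel indices
#' @keywords internal
idx_to_mask <- function(idx, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[idx] <- TRUE
  m
}

#' Row/column coordinates (1-based) of linear indices
#' @keywords internal
idx_to_rc <- function(idx, H) {
  cbind(row = (idx - 1L) %% H + 1L, col = (idx - 1L) %/% H + 1L)
}

#' Linear indices from row/column coordinates; out-of-bounds -> NA
#' @keywords internal
rc_to_idx <- function(r, c, shape) {
  ok <- r >= 1L & r <= shape[1] & c >= 1L & c <= shape[2]
  out <- rep(NA_integer_, length(r))
  out[ok] <- (c[ok] - 1L) * shape[1] + r[ok]
  out
}

#' Circular disk mask
#'
#' @param radius radius in pixels (0 gives a single pixel).
#' @param shape optional output shape; defaults to the tight bounding box.
#' @param center optional (row, col) center, defaults to the middle.
#' @return logical matrix.
#' @export
disk_mask <- function(radius, shape = NULL, center = NULL) {
  if (is.null(shape)) {
    d <- 2L * ceiling(radius) + 1L
    shape <- c(d, d)
  }
  if (is.null(center)) center <- (shape + 1) / 2
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Filled ellipse mask (rotated)
#' @keywords internal
ellipse_mask <- function(shape, center, a, b, theta = 0) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- r - center[1]
  dx <- c - center[2]
  # rotate into the ellipse's principal frame; a along x', b along y'
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Shift an image by integer pixels
#'
#' Content moves by `+dx` columns (right) and `+dy` rows (down); vacated
#' pixels are filled with `fill`.
#'
#' @param image numeric matrix.
#' @param dx,dy integer shifts (columns, rows).
#' @param fill fill value for uncovered pixels (default 0).
#' @return shifted matrix of the same shape.
#' @keywords internal
shift_image <- function(image, dx, dy, fill = 0) {
  H <- nrow(image); W <- ncol(image)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

#' Label connected components of a binary mask
#'
#' Components are found on the pixel-adjacency graph (8-connectivity by
#' default) using igraph; labels are assigned in raster order of each
#' component's first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  pos <- integer(H * W)
  pos[idx] <- seq_len(n)
  rc <- idx_to_rc(idx, H)
  dirs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) dirs <- c(dirs, list(c(1L, 1L), c(-1L, 1L)))
  ee <- vector("list", length(dirs))
  for (k in seq_along(dirs)) {
    d <- dirs[[k]]
    nr <- rc[, 1] + d[1]; nc <- rc[, 2] + d[2]
    j <- rc_to_idx(nr, nc, c(H, W))
    ok <- !is.na(j)
    ok[ok] <- mask[j[ok]]
    if (any(ok)) ee[[k]] <- cbind(pos[idx[ok]], pos[j[ok]])
  }
  edges <- do.call(rbind, ee)
  if (is.null(edges) || nrow(edges) == 0L) {
    lab[idx] <- seq_len(n)
    return(lab)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel so component ids follow raster order of first occurrence
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relab[memb]
  lab
}

#' Trace the external boundary of a connected mask
#'
#' Moore-neighbor tracing, clockwise, starting from the first foreground
#' pixel in column-major order. Returns the closed sequence of boundary
#' pixel centers (without repeating the start pixel at the end). Assumes a
#' single connected component; on masks whose boundary passes through the
#' start pixel more than once the trace may close early (adequate for the
#' convex-ish organelle instances this package produces).
#'
#' @param mask logical matrix, at least one TRUE pixel.
#' @return integer matrix with columns `row`, `col`.
#' @export
trace_contour <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("trace_contour: empty mask")
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  start_idx <- which(pad)[1]
  r0 <- (start_idx - 1L) %% (H + 2L) + 1L
  c0 <- (start_idx - 1L) %/% (H + 2L) + 1L
  # clockwise Moore neighborhood, index 1 = west
  nbr <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                  0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                ncol = 2, byrow = TRUE)
  back_of <- function(d) {
    for (m in 1:8) if (nbr[m, 1] == d[1] && nbr[m, 2] == d[2]) return(m)
    stop("not a neighbor offset")
  }
  path <- matrix(0L, 4L * (H + W) + 8L, 2L)
  np <- 1L
  path[1L, ] <- c(r0, c0)
  cur <- c(r0, c0)
  backtrack <- 1L # entered from the west
  repeat {
    moved <- FALSE
    for (k in 0:7) {
      j <- ((backtrack - 1L + k) %% 8L) + 1L
      p <- cur + nbr[j, ]
      if (pad[p[1], p[2]]) {
        prev <- cur
        cur <- p
        backtrack <- (back_of(prev - cur) %% 8L) + 1L
        np <- np + 1L
        if (np > nrow(path)) path <- rbind(path, path * 0L)
        path[np, ] <- cur
        moved <- TRUE
        break
      }
    }
    if (!moved) break # isolated pixel
    if (cur[1] == r0 && cur[2] == c0) break
    if (np > 8L * (H + W) + 64L) break # safety stop
  }
  out <- path[seq_len(np), , drop = FALSE]
  if (np > 1L && out[np, 1] == r0 && out[np, 2] == c0) {
    out <- out[-np, , drop = FALSE]
  }
  colnames(out) <- c("row", "col")
  out - 1L # remove padding offset
}

#' Chain-code perimeter of a connected mask
#'
#' Freeman chain length along the traced external boundary: axial steps
#' count 1, diagonal steps sqrt(2). A single pixel counts 4 (its crack
#' boundary).
#'
#' @param mask logical matrix, one connected component.
#' @return perimeter estimate in pixels.
#' @export
mask_perimeter <- function(mask) {
  ct <- trace_contour(mask)
  n <- nrow(ct)
  if (n == 1L) return(4)
  steps <- abs(ct[c(2:n, 1L), , drop = FALSE] - ct)
  sum(ifelse(rowSums(steps) == 2L, sqrt(2), 1))
}

#' Rasterize a polygon onto a pixel grid
#'
#' Crossing-number point-in-polygon test at pixel centers, with boundary
#' pixels (the polygon edges sampled at sub-pixel resolution) included so
#' that thin polygons do not vanish.
#'
#' @param xy numeric matrix of vertices, columns (x, y) in pixel-center
#'   coordinates (1-based columns/rows).
#' @param shape output (H, W).
#' @return logical matrix.
#' @export
rasterize_polygon <- function(xy, shape) {
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  H <- shape[1]; W <- shape[2]
  out <- matrix(FALSE, H, W)
  x <- xy[, 1]; y <- xy[, 2]
  cmin <- max(1L, floor(min(x))); cmax <- min(W, ceiling(max(x)))
  rmin <- max(1L, floor(min(y))); rmax <- min(H, ceiling(max(y)))
  if (cmin > cmax || rmin > rmax) return(out)
  cc <- rep(cmin:cmax, each = rmax - rmin + 1L)
  rr <- rep(rmin:rmax, times = cmax - cmin + 1L)
  inside <- rep(FALSE, length(cc))
  n <- length(x)
  jj <- c(n, seq_len(n - 1L))
  for (i in seq_len(n)) {
    j <- jj[i]
    cross <- ((y[i] > rr) != (y[j] > rr))
    if (any(cross)) {
      xint <- (x[j] - x[i]) * (rr[cross] - y[i]) / (y[j] - y[i]) + x[i]
      inside[cross] <- xor(inside[cross], cc[cross] < xint)
    }
  }
  out[cbind(rr[inside], cc[inside])] <- TRUE
  # paint edges so boundary pixels are retained
  for (i in seq_len(n)) {
    j <- jj[i]
    len <- max(abs(x[i] - x[j]), abs(y[i] - y[j]))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2) + 1L))
    er <- round(y[j] + ts * (y[i] - y[j]))
    ec <- round(x[j] + ts * (x[i] - x[j]))
    ok <- er >= 1 & er <= H & ec >= 1 & ec <= W
    out[cbind(er[ok], ec[ok])] <- TRUE
  }
  out
}

#' Centroid of a mask (row, col)
#' @keywords internal
mask_centroid <- function(mask) {
  rc <- idx_to_rc(which(mask), nrow(mask))
  c(mean(rc[, 1]), mean(rc[, 2]))
}

# FNV-1a 32-bit hash of a character string, as hex; used for config
# fingerprints in the pipeline manifest (no digest dependency). Arithmetic
# is split into 16-bit halves so every intermediate stays exact in doubles.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b) # b < 256 only touches the low half
    hi <- h %/% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
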