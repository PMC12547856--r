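# Plain-text and PNG serialization. Instrument vendors ship proprietary
# containers (Cameca .im, multi-page TIFF); this package ingests and emits
# open equivalents only: 8-bit grayscale PNG for EM images, tab-separated
# integer matrices per plane (+ JSON sidecar) for ion stacks, TSV label
# maps + CSV tables for instance masks.

#' Write a grayscale image as 8-bit PNG
#'
#' @param image numeric matrix; values are clipped to `[0, 1]`.
#' @param path output file.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a grayscale image from PNG
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path PNG file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3])), drop = FALSE], c(1, 2), mean)
  x
}

#' Write an integer matrix as TSV (no headers)
#' @param m integer/numeric matrix.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV
#' @param path file written by [write_matrix_tsv()].
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write an ion stack as per-plane TSV matrices plus a JSON sidecar
#'
#' Files are `<prefix>_plane<k>.tsv` and `<prefix>.json`.
#'
#' @param stack an [ion_stack()].
#' @param prefix path prefix (directory must exist).
#' @export
write_ion_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "ion_stack"))
  for (k in seq_along(stack$planes)) {
    write_matrix_tsv(stack$planes[[k]], sprintf("%s_plane%d.tsv", prefix, k))
  }
  meta <- list(
    species = stack$species,
    n_planes = length(stack$planes),
    shape = dim(stack$planes[[1]]),
    dwell_time = stack$dwell_time,
    dead_time = stack$dead_time,
    pixel_size = stack$pixel_size
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read an ion stack written by [write_ion_stack()]
#' @param prefix path prefix.
#' @return an [ion_stack()].
#' @export
read_ion_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  planes <- lapply(seq_len(meta$n_planes), function(k) {
    read_matrix_tsv(sprintf("%s_plane%d.tsv", prefix, k))
  })
  ion_stack(planes, species = meta$species, dwell_time = meta$dwell_time,
            dead_time = meta$dead_time, pixel_size = meta$pixel_size)
}

#' Serialize an ROI set as a label map (TSV) and an instance table (CSV)
#'
#' The label map holds the instance id per pixel (0 = background); pixels
#' claimed by several instances (possible across classes) carry the id of
#' the higher-confidence instance in the map, while the CSV/ROI object keep
#' the full masks.
#'
#' @param rois an [roi_set()].
#' @param prefix path prefix; writes `<prefix>_labels.tsv`,
#'   `<prefix>_table.csv`.
#' @export
write_roi_set <- function(rois, prefix) {
  stopifnot(inherits(rois, "roi_set"))
  lab <- matrix(0L, rois$image_shape[1], rois$image_shape[2])
  ord <- order(rois$table$confidence) # higher confidence painted last
  for (i in ord) lab[rois$pixels[[i]]] <- rois$table$id[i]
  write_matrix_tsv(lab, paste0(prefix, "_labels.tsv"))
  tab <- as.data.frame(rois)
  utils::write.csv(tab, paste0(prefix, "_table.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read an ROI set written by [write_roi_set()]
#'
#' Reconstructs instances from the label map; overlap pixels lost to the
#' flat map stay with the winning instance.
#'
#' @param prefix path prefix.
#' @param classes class name vector (defaults to [organelle_classes()]).
#' @return an [roi_set()].
#' @export
read_roi_set <- function(prefix, classes = organelle_classes()) {
  lab <- read_matrix_tsv(paste0(prefix, "_labels.tsv"))
  tab <- utils::read.csv(paste0(prefix, "_table.csv"))
  pixels <- lapply(tab$id, function(id) which(lab == id))
  keep <- lengths(pixels) > 0L
  roi_set(
    pixels = pixels[keep],
    class_id = tab$class_id[keep],
    image_shape = dim(lab),
    classes = classes,
    confidence = tab$confidence[keep],
    support = tab$support[keep],
    id = tab$id[keep]
  )
}
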