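# Shared fixtures. Everything is generated in code; no binary files.

# count list with all classes at zero except those overridden
counts_only <- function(...) {
  z <- list(nucleolus = c(0, 0), mitochondria = c(0, 0), ER = c(0, 0),
            Golgi = c(0, 0), vacuoles = c(0, 0), vesicles = c(0, 0))
  utils::modifyList(z, list(...))
}

# a small phantom spec for fast tests
small_spec <- function(image_shape = c(160L, 160L), seed = 1L, ...) {
  phantom_spec(image_shape = image_shape, counts = counts_only(...), seed = seed)
}

# rectangular mask helper (1-based inclusive bounds)
rect_mask <- function(shape, r0, r1, c0, c1) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:r1, c0:c1] <- TRUE
  m
}

# an roi_set from a list of logical masks
rois_from_masks <- function(masks, class_id, shape, confidence = 1,
                            classes = organelle_classes()) {
  roi_set(lapply(masks, which), class_id, shape, classes,
          confidence = confidence)
}

# a detection from a logical mask
det_from_mask <- function(mask, class_id = 6L, confidence = 1,
                          pass_index = 1L, tile_index = 0L) {
  detection(class_id, which(mask), dim(mask), confidence,
            tile_index = tile_index, pass_index = pass_index)
}

# image with vesicle-band disks at given (row, col) centers; no noise
disk_image <- function(shape, centers, radius = 8, class = "vesicles") {
  img <- matrix(0.86, shape[1], shape[2])
  bands <- phantom_bands()
  pix <- list()
  for (i in seq_len(nrow(centers))) {
    m <- disk_mask(radius, shape = shape, center = centers[i, ] + 0.5)
    img[m] <- bands$center[[class]]
    pix[[i]] <- which(m)
  }
  cid <- match(class, organelle_classes())
  list(image = img,
       truth = roi_set(pix, rep(cid, nrow(centers)), shape))
}

# small ion phantom spec used across SIMS/registration/turnover tests
small_ion_spec <- function(sims_shape = c(128L, 128L),
                           em_to_sims = similarity_transform(),
                           ...) {
  ion_phantom_spec(sims_shape = sims_shape, em_to_sims = em_to_sims, ...)
}
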