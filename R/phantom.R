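# Synthetic correlative EM/NanoSIMS phantoms. The generator states a known
# world -- organelle instances with ground-truth masks on an EM-like image,
# and matched ion-count stacks whose in-organelle 15N enrichment decays
# exponentially with known half-lives under a known EM->SIMS similarity
# transform, per-plane drift, and optional dead-time count deflation -- so
# that every downstream stage can be tested without instrument data.

#' The six organelle classes
#'
#' Order fixes the class ids (1-based internally, 0-based in exported label
#' files): nucleolus, mitochondria, ER, Golgi, vacuoles, vesicles.
#'
#' @return character vector of length 6.
#' @export
organelle_classes <- function() {
  c("nucleolus", "mitochondria", "ER", "Golgi", "vacuoles", "vesicles")
}

#' Intensity bands of the phantom classes
#'
#' Each class occupies a disjoint gray-level band on the EM phantom
#' (center +/- halfwidth); the toy segmentation backend thresholds these
#' bands, which makes it parameter-free in tests. Background sits at 0.86,
#' well clear of the highest band.
#'
#' @return list with `center` (named numeric, one per class) and
#'   `halfwidth` (scalar).
#' @export
phantom_bands <- function() {
  list(
    center = stats::setNames(seq(0.10, 0.70, by = 0.12), organelle_classes()),
    halfwidth = 0.05
  )
}

#' Specification of an EM phantom
#'
#' @param image_shape integer (H, W) in pixels.
#' @param counts named list per class of `c(min, max)` instance counts.
#' @param shape named list per class of `list(r_major = c(lo, hi),
#'   r_minor = c(lo, hi))` semi-axis ranges in px; equal ranges give disks.
#' @param background background gray level in `[0, 1]`.
#' @param noise_sd Gaussian noise sd on the background.
#' @param texture_amp uniform texture amplitude inside organelles; must stay
#'   below the band halfwidth so instances remain within their class band.
#' @param seed integer; identical specs with identical seeds generate
#'   byte-identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(640L, 640L),
                         counts = list(
                           nucleolus = c(1, 2), mitochondria = c(4, 8),
                           ER = c(3, 6), Golgi = c(2, 4),
                           vacuoles = c(3, 6), vesicles = c(6, 12)
                         ),
                         shape = list(
                           nucleolus = list(r_major = c(18, 30), r_minor = c(15, 26)),
                           mitochondria = list(r_major = c(12, 22), r_minor = c(4, 7)),
                           ER = list(r_major = c(18, 35), r_minor = c(2, 4)),
                           Golgi = list(r_major = c(14, 24), r_minor = c(3, 6)),
                           vacuoles = list(r_major = c(7, 12), r_minor = c(7, 12)),
                           vesicles = list(r_major = c(4, 8), r_minor = c(4, 8))
                         ),
                         background = 0.86, noise_sd = 0.015,
                         texture_amp = 0.03, seed = 1L) {
  cls <- organelle_classes()
  if (!identical(sort(names(counts)), sort(cls)) ||
      !identical(sort(names(shape)), sort(cls))) {
    stop("phantom_spec: counts and shape must name exactly the six classes: ",
         paste(cls, collapse = ", "))
  }
  for (cl in cls) {
    p <- shape[[cl]]
    if (any(c(p$r_major, p$r_minor) <= 0)) {
      stop("phantom_spec: shape parameters must be positive (class ", cl, ")")
    }
    if (any(counts[[cl]] < 0) || counts[[cl]][1] > counts[[cl]][2]) {
      stop("phantom_spec: invalid count range for class ", cl)
    }
  }
  bands <- phantom_bands()
  if (texture_amp >= bands$halfwidth) {
    stop("phantom_spec: texture_amp must be below the band halfwidth ",
         bands$halfwidth)
  }
  structure(list(
    image_shape = as.integer(image_shape), counts = counts[cls],
    shape = shape[cls], background = background, noise_sd = noise_sd,
    texture_amp = texture_amp, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# morphological dilation by a square structuring element of radius r
dilate_mask <- function(mask, r = 1L) {
  out <- mask
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    out <- out | shift_image(mask, dx, dy, fill = FALSE)
  }
  out
}

#' Generate an EM phantom image with ground-truth organelle instances
#'
#' Instances are rasterized rotated ellipses (disks for vesicle/vacuole
#' classes) placed by rejection sampling with a 2-px exclusion margin, so
#' masks are connected and mutually disjoint. Each class paints a distinct
#' intensity band (see [phantom_bands()]) with uniform texture; Gaussian
#' noise covers the background.
#'
#' @param spec a [phantom_spec()].
#' @param max_tries placement attempts per instance before the generator
#'   declares the image too small.
#' @return list with `image` (numeric matrix in `[0, 1]`) and `truth`
#'   (an [roi_set()]).
#' @export
make_em_phantom <- function(spec, max_tries = 300L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    H <- spec$image_shape[1]; W <- spec$image_shape[2]
    bands <- phantom_bands()
    image <- matrix(spec$background + stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    occ <- matrix(FALSE, H, W)
    pixels <- list(); class_id <- integer()
    cls <- organelle_classes()
    for (ci in seq_along(cls)) {
      cl <- cls[ci]
      rng <- spec$counts[[cl]]
      n <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      shp <- spec$shape[[cl]]
      for (k in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          a <- stats::runif(1, shp$r_major[1], shp$r_major[2])
          b <- stats::runif(1, shp$r_minor[1], shp$r_minor[2])
          b <- min(a, b)
          theta <- stats::runif(1, 0, pi)
          m <- ceiling(a) + 2L
          if (2L * m + 1L >= min(H, W)) {
            stop("make_em_phantom: image ", H, "x", W,
                 " too small to place an instance of class ", cl)
          }
          ctr <- c(stats::runif(1, m + 1, H - m), stats::runif(1, m + 1, W - m))
          cand <- ellipse_mask(c(H, W), ctr, a, b, theta)
          if (!any(cand & occ)) {
            idx <- which(cand)
            image[idx] <- bands$center[[cl]] +
              stats::runif(length(idx), -spec$texture_amp, spec$texture_amp)
            occ <- occ | dilate_mask(cand, 2L)
            pixels[[length(pixels) + 1L]] <- idx
            class_id <- c(class_id, ci)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("make_em_phantom: failed to place instance ", k, " of class ",
               cl, " after ", max_tries, " tries; image too small or too full")
        }
      }
    }
    truth <- roi_set(pixels, class_id, image_shape = c(H, W),
                     classes = cls, confidence = 1, support = 1L)
    list(image = image, truth = truth)
  })
}

#' First-order pulse-chase decay of isotopic enrichment
#'
#' `E(t) = E_nat + (E0 - E_nat) * 2^(-t / t_half)`: enrichment falls from
#' the initial labeled level `E0` toward the natural-abundance baseline
#' `E_nat` with half-life `t_half` (hours). This parameterization makes
#' `t_half` the half-life of the above-baseline excess directly.
#'
#' @param t chase time(s), hours.
#' @param t_half half-life, hours (> 0).
#' @param e0 initial enrichment ratio.
#' @param e_nat baseline (natural-abundance) ratio; default 0.0037, the
#'   natural 15N/14N abundance.
#' @return enrichment ratio(s).
#' @export
enrichment_decay <- function(t, t_half, e0, e_nat = 0.0037) {
  stopifnot(t_half > 0)
  e_nat + (e0 - e_nat) * 2^(-t / t_half)
}

#' Specification of matched ion-count phantom stacks
#'
#' States the isotopic world: per-class half-lives, pulse enrichment,
#' baseline, counting statistics, plane drift, dead time, and the EM->SIMS
#' similarity transform.
#'
#' @param chase_times chase time points in hours, nonnegative, strictly
#'   increasing. Default `c(0, 12, 24, 48, 96)` (48-h 15N-leucine pulse,
#'   chase between 0 and 96 h).
#' @param t_half named numeric, half-life in hours per class present.
#' @param e0 initial enrichment ratio; default 0.05.
#' @param e_nat natural-abundance baseline ratio; default 0.0037.
#' @param mean_cn14 expected 12C14N counts per pixel per plane in
#'   background; default 50.
#' @param cn14_density named per-class multipliers of `mean_cn14` inside
#'   organelles (protein-dense structures emit more CN-); default elevates
#'   the nucleolus so it is visible in both modalities.
#' @param n_planes number of scan planes (instrument acquires 4-5).
#' @param drift integer matrix `n_planes x 2` of per-plane (dx, dy) pixel
#'   shifts; default zero for plane 1 and +/-1 px for later planes.
#' @param em_to_sims a [similarity_transform()] mapping EM pixel
#'   coordinates to SIMS pixel coordinates.
#' @param sims_shape (H, W) of the SIMS raster; default `c(256L, 256L)`
#'   (the instrument's typical raster).
#' @param dead_time detector dead time in seconds (default 44 ns).
#' @param dwell_time dwell time per pixel in seconds (default 5 ms).
#' @param seed integer.
#' @return object of class `ion_phantom_spec`.
#' @export
ion_phantom_spec <- function(chase_times = c(0, 12, 24, 48, 96),
                             t_half = c(nucleolus = 16.4, mitochondria = 21.5,
                                        ER = 19.2, Golgi = 16.4,
                                        vacuoles = 20.0, vesicles = 20.2),
                             e0 = 0.05, e_nat = 0.0037,
                             mean_cn14 = 50, cn14_density = NULL,
                             n_planes = 4L, drift = NULL,
                             em_to_sims = similarity_transform(),
                             sims_shape = c(256L, 256L),
                             dead_time = 44e-9, dwell_time = 5e-3,
                             seed = 1L) {
  if (any(t_half <= 0)) stop("ion_phantom_spec: half-lives must be positive")
  if (!(e_nat >= 0 && e_nat < e0 && e0 < 1)) {
    stop("ion_phantom_spec: need 0 <= e_nat < e0 < 1")
  }
  if (any(chase_times < 0) || is.unsorted(chase_times, strictly = TRUE)) {
    stop("ion_phantom_spec: chase_times must be nonnegative and strictly increasing")
  }
  n_planes <- as.integer(n_planes)
  if (n_planes < 1L) stop("ion_phantom_spec: n_planes must be >= 1")
  if (is.null(drift)) {
    drift <- cbind(dx = c(0L, rep_len(c(1L, -1L, 0L), n_planes - 1L)),
                   dy = c(0L, rep_len(c(0L, 1L, -1L), n_planes - 1L)))
  }
  drift <- matrix(as.integer(drift), ncol = 2)
  if (nrow(drift) != n_planes) stop("ion_phantom_spec: drift must have one (dx, dy) row per plane")
  if (is.null(cn14_density)) {
    cn14_density <- c(nucleolus = 2.0, mitochondria = 1.4, ER = 1.2,
                      Golgi = 1.3, vacuoles = 0.8, vesicles = 1.3)
  }
  structure(list(
    chase_times = chase_times, t_half = t_half, e0 = e0, e_nat = e_nat,
    mean_cn14 = mean_cn14, cn14_density = cn14_density,
    n_planes = n_planes, drift = drift, em_to_sims = em_to_sims,
    sims_shape = as.integer(sims_shape), dead_time = dead_time,
    dwell_time = dwell_time, seed = as.integer(seed)
  ), class = "ion_phantom_spec")
}

#' Generate matched 12C14N / 12C15N ion-count stacks for one chase time
#'
#' Every SIMS pixel is mapped through the inverse of `spec$em_to_sims` and
#' looked up in the ground-truth class map: inside an organelle of class
#' `c` the expected 15N/14N ratio is
#' `E_nat + (E0 - E_nat) * 2^(-t / T_c)`, outside it is `E_nat`. Counts
#' are Poisson-sampled per plane (disable with `poisson = FALSE` to get
#' expected values), each plane is shifted by its drift vector, and when
#' `dead_time > 0` observed counts are deflated by
#' `N_obs = N / (1 + N * dead_time / dwell_time)` -- the exact inverse of
#' [dead_time_correct()].
#'
#' @param spec an [ion_phantom_spec()].
#' @param truth ground-truth [roi_set()] in the EM frame.
#' @param chase_time chase time in hours.
#' @param poisson logical; FALSE yields noiseless expected counts.
#' @return list with `cn14` and `cn15` [ion_stack()] objects; each carries
#'   `meta` (true drift, transform parameters, chase time, seed).
#' @export
make_ion_stack <- function(spec, truth, chase_time, poisson = TRUE) {
  stopifnot(inherits(spec, "ion_phantom_spec"), inherits(truth, "roi_set"))
  sh <- spec$sims_shape
  if (any(abs(spec$drift) >= min(sh))) {
    stop("make_ion_stack: plane drift exceeds the image size")
  }
  H <- sh[1]; W <- sh[2]
  # class map in the EM frame
  em_shape <- truth$image_shape
  class_map <- matrix(0L, em_shape[1], em_shape[2])
  for (i in seq_along(truth$pixels)) {
    class_map[truth$pixels[[i]]] <- truth$table$class_id[i]
  }
  # inverse-map each SIMS pixel center to EM coordinates
  inv <- invert_transform(spec$em_to_sims)
  sx <- rep(seq_len(W), each = H)
  sy <- rep(seq_len(H), times = W)
  em_xy <- transform_points(inv, cbind(sx, sy))
  er <- round(em_xy[, 2]); ec <- round(em_xy[, 1])
  j <- rc_to_idx(as.integer(er), as.integer(ec), em_shape)
  cls <- integer(H * W)
  ok <- !is.na(j)
  cls[ok] <- class_map[j[ok]]
  cls <- matrix(cls, H, W)

  classes <- truth$classes
  ratio <- matrix(spec$e_nat, H, W)
  dens <- matrix(1, H, W)
  for (ci in sort(unique(cls[cls > 0L]))) {
    cl <- classes[ci]
    th <- spec$t_half[[cl]]
    if (is.null(th) || is.na(th)) {
      stop("make_ion_stack: no half-life configured for class ", cl)
    }
    sel <- cls == ci
    ratio[sel] <- enrichment_decay(chase_time, th, spec$e0, spec$e_nat)
    d <- spec$cn14_density[[cl]]
    if (!is.null(d) && !is.na(d)) dens[sel] <- d
  }
  lam14 <- spec$mean_cn14 * dens
  lam15 <- ratio * lam14

  seed_eff <- (abs(spec$seed) * 1009L + as.integer(round(chase_time * 8))) %% 2147483647L
  deflate <- function(n) {
    if (spec$dead_time <= 0) return(n)
    n / (1 + n * spec$dead_time / spec$dwell_time)
  }
  with_seed(seed_eff, {
    mk_planes <- function(lam) {
      lapply(seq_len(spec$n_planes), function(p) {
        shifted <- shift_image(lam, spec$drift[p, 1], spec$drift[p, 2], fill = 0)
        counts <- if (poisson) {
          matrix(stats::rpois(H * W, shifted), H, W)
        } else shifted
        deflate(counts)
      })
    }
    planes14 <- mk_planes(lam14)
    planes15 <- mk_planes(lam15)
    meta <- list(drift = spec$drift, transform = unclass(spec$em_to_sims),
                 chase_time = chase_time, seed = seed_eff, poisson = poisson)
    list(
      cn14 = ion_stack(planes14, species = "12C14N",
                       dwell_time = spec$dwell_time, dead_time = spec$dead_time,
                       meta = meta),
      cn15 = ion_stack(planes15, species = "12C15N",
                       dwell_time = spec$dwell_time, dead_time = spec$dead_time,
                       meta = meta)
    )
  })
}

#' Write an EM phantom (image + truth) to a directory
#'
#' Emits `em.png` (8-bit grayscale), `truth_labels.tsv` (instance-id label
#' map), and `truth_table.csv` (id, class, area, centroid).
#'
#' @param phantom list from [make_em_phantom()].
#' @param dir output directory (created if missing).
#' @export
write_em_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gray_png(phantom$image, file.path(dir, "em.png"))
  write_roi_set(phantom$truth, file.path(dir, "truth"))
  invisible(dir)
}
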