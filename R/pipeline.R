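# End-to-end orchestration: preprocess -> segment (all passes) ->
# assemble -> filter -> register -> correct -> quantify -> fit -> compare,
# either fully in memory on generated phantoms (run_phantom_study) or
# file-based from a YAML config over a study directory (run_pipeline),
# with a reproducibility manifest.

#' Simulate and analyze a pulse-chase phantom study in memory
#'
#' For every chase time: generate an EM phantom, segment it with the toy
#' backend over offset passes, compile and filter the instance masks,
#' recover the EM->SIMS transform from anchor points sampled through the
#' true transform, generate matched ion stacks (Poisson counts, drift,
#' dead time), dead-time/drift-correct and accumulate them, warp the
#' assembled ROIs into the SIMS frame and extract per-ROI enrichment.
#' Finally fit the decay model per class.
#'
#' @param seed study seed; all randomness derives from it.
#' @param em_spec a [phantom_spec()] template (its seed is re-derived per
#'   chase time).
#' @param ion_spec an [ion_phantom_spec()].
#' @param frame,n_passes tiling parameters.
#' @param iou_link,min_support merge parameters (see [merge_passes()]).
#' @param rules morphological filter rules.
#' @param fix_baseline,e_nat passed to [fit_decay()].
#' @param poisson disable for noiseless expected counts.
#' @param n_anchors anchor pairs sampled for registration (default 4).
#' @return list with `measurements` (long data frame), `fits`
#'   (per-class data frame), `transform` (fitted EM->SIMS transform of the
#'   last frame), and `truth_recall` (per chase time, fraction of truth
#'   instances recovered at IoU 0.5).
#' @export
run_phantom_study <- function(seed = 1L,
                              em_spec = phantom_spec(image_shape = c(256L, 256L)),
                              ion_spec = ion_phantom_spec(sims_shape = c(192L, 192L),
                                                          em_to_sims = similarity_transform(scale = 0.6, theta = 0.1, tx = 12, ty = 6)),
                              frame = 128L, n_passes = 2L,
                              iou_link = 0.5, min_support = 2L,
                              rules = default_filter_rules(),
                              fix_baseline = TRUE, e_nat = ion_spec$e_nat,
                              poisson = TRUE, n_anchors = 4L) {
  backend <- toy_backend()
  meas <- list()
  recall <- numeric(0)
  tf_fit <- NULL
  for (ti in seq_along(ion_spec$chase_times)) {
    t_chase <- ion_spec$chase_times[ti]
    pspec <- em_spec
    pspec$seed <- (abs(seed) * 211L + ti) %% 2147483647L
    ph <- make_em_phantom(pspec)
    dets <- run_passes(ph$image, frame, n_passes, backend)
    rois <- merge_passes(dets, n_passes, iou_link, min_support,
                         image_shape = dim(ph$image))
    rois <- morphological_filter(rois, rules)
    m <- match_instances(ph$truth, rois, iou_threshold = 0.5)
    recall <- c(recall, precision_recall_f1(m)[["recall"]])
    # registration from anchors sampled through the true transform
    H <- nrow(ph$image); W <- ncol(ph$image)
    em_pts <- cbind(x = c(0.15, 0.85, 0.15, 0.85)[seq_len(n_anchors)] * W,
                    y = c(0.15, 0.15, 0.85, 0.85)[seq_len(n_anchors)] * H)
    sims_pts <- transform_points(ion_spec$em_to_sims, em_pts)
    anchors <- data.frame(em_x = em_pts[, 1], em_y = em_pts[, 2],
                          sims_x = sims_pts[, 1], sims_y = sims_pts[, 2])
    fit_tf <- fit_similarity(anchors)
    tf_fit <- fit_tf$transform
    ion <- make_ion_stack(ion_spec, ph$truth, t_chase, poisson = poisson)
    corr <- correct_and_accumulate(ion$cn14, ion$cn15)
    warped <- suppressWarnings(warp_roi_set(rois, tf_fit, ion_spec$sims_shape))
    meas[[ti]] <- roi_enrichment(warped, corr$cn14, corr$cn15,
                                 chase_time = t_chase)
  }
  measurements <- do.call(rbind, meas)
  fits <- fit_decay_by_class(measurements, fix_baseline = fix_baseline,
                             e_nat = e_nat)
  list(measurements = measurements, fits = fits, transform = tf_fit,
       truth_recall = stats::setNames(recall, ion_spec$chase_times))
}

#' Write a phantom study to disk
#'
#' One directory per chase time (`t000`, `t012`, ...), each holding
#' `em.png`, the ground-truth ROI files, per-species ion-stack TSV planes
#' with JSON sidecars, and an `anchors.csv` sampled through the true
#' transform; plus `chase_times.csv` (image_id, chase_time_h, group) and
#' `study.json` (global metadata) at the root.
#'
#' @param out_dir study directory (created).
#' @param em_spec,ion_spec phantom specifications.
#' @param group group label recorded in the metadata.
#' @param seed study seed.
#' @param poisson disable for noiseless counts.
#' @param shared_phantom if TRUE every chase time reuses the same EM
#'   phantom (the same cell field re-imaged), so histogram matching to the
#'   study's own reference is exactly the identity; if FALSE (default) each
#'   chase time is an independent cell field.
#' @return `out_dir`, invisibly.
#' @export
simulate_study <- function(out_dir,
                           em_spec = phantom_spec(image_shape = c(256L, 256L)),
                           ion_spec = ion_phantom_spec(sims_shape = c(192L, 192L),
                                                       em_to_sims = similarity_transform(scale = 0.6, theta = 0.1, tx = 12, ty = 6)),
                           group = "phantom", seed = 1L, poisson = TRUE,
                           shared_phantom = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ti in seq_along(ion_spec$chase_times)) {
    t_chase <- ion_spec$chase_times[ti]
    id <- sprintf("t%03d", round(t_chase))
    d <- file.path(out_dir, id)
    dir.create(d, showWarnings = FALSE)
    pspec <- em_spec
    k <- if (shared_phantom) 1L else ti
    pspec$seed <- (abs(seed) * 211L + k) %% 2147483647L
    ph <- make_em_phantom(pspec)
    write_em_phantom(ph, d)
    ion <- make_ion_stack(ion_spec, ph$truth, t_chase, poisson = poisson)
    write_ion_stack(ion$cn14, file.path(d, "cn14"))
    write_ion_stack(ion$cn15, file.path(d, "cn15"))
    H <- nrow(ph$image); W <- ncol(ph$image)
    em_pts <- cbind(x = c(0.15, 0.85, 0.15, 0.85) * W,
                    y = c(0.15, 0.15, 0.85, 0.85) * H)
    sims_pts <- transform_points(ion_spec$em_to_sims, em_pts)
    write_anchors(data.frame(em_x = em_pts[, 1], em_y = em_pts[, 2],
                             sims_x = sims_pts[, 1], sims_y = sims_pts[, 2]),
                  file.path(d, "anchors.csv"))
    jsonlite::write_json(list(chase_time = t_chase, seed = pspec$seed,
                              drift = ion_spec$drift,
                              transform = unclass(ion_spec$em_to_sims)),
                         file.path(d, "meta.json"), auto_unbox = TRUE, digits = NA)
    rows[[ti]] <- data.frame(image_id = id, chase_time_h = t_chase, group = group)
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "chase_times.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_times = length(ion_spec$chase_times),
                            e0 = ion_spec$e0, e_nat = ion_spec$e_nat,
                            t_half = as.list(ion_spec$t_half)),
                       file.path(out_dir, "study.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Default pipeline configuration
#'
#' @param study_dir directory written by [simulate_study()] (or laid out
#'   the same way).
#' @return named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(study_dir) {
  list(
    study_dir = study_dir,
    preprocess = "match", # "match" (histogram matching) or "none"
    reference_image = NULL, # path; NULL = first image of the study
    frame = 128L,
    n_passes = 2L,
    backend = "toy",
    merge = list(iou_link = 0.5, min_support = 2L),
    filter_rules = default_filter_rules(),
    registration = list(mode = "anchors"), # or "auto"
    baseline = 0.0037,
    fix_baseline = TRUE,
    seed = 1L
  )
}

#' Read and validate a pipeline YAML config
#'
#' @param path YAML file with the fields of
#'   [default_pipeline_config()]; missing fields take defaults.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$study_dir)) stop("pipeline config: study_dir is required")
  cfg <- utils::modifyList(default_pipeline_config(raw$study_dir), raw)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (!dir.exists(cfg$study_dir)) {
    stop("pipeline config: study_dir does not exist: ", cfg$study_dir)
  }
  if (!file.exists(file.path(cfg$study_dir, "chase_times.csv"))) {
    stop("pipeline config: chase_times.csv missing from ", cfg$study_dir)
  }
  cfg$frame <- as.integer(cfg$frame)
  cfg$n_passes <- as.integer(cfg$n_passes)
  if (cfg$frame %% cfg$n_passes != 0) {
    stop("pipeline config: frame must be divisible by n_passes")
  }
  if (!is.null(cfg$reference_image) && !file.exists(cfg$reference_image)) {
    stop("pipeline config: reference image not found: ", cfg$reference_image)
  }
  if (!cfg$preprocess %in% c("match", "none")) {
    stop("pipeline config: preprocess must be 'match' or 'none'")
  }
  if (!cfg$backend %in% "toy") {
    stop("pipeline config: unknown backend '", cfg$backend,
         "' (adapters must be passed programmatically)")
  }
  cfg
}

#' Run the full analysis pipeline over a study directory
#'
#' Executes preprocess (histogram matching to the reference image) ->
#' segmentation over all offset passes -> mask assembly -> morphological
#' filtering -> registration (anchor CSVs, or automatic nucleus anchors)
#' -> dead-time/drift correction and accumulation -> per-ROI enrichment
#' -> per-class decay fits, writing every intermediate artifact and a
#' manifest (config hash, package/R versions, seeds, offsets, per-stage
#' timings) under `out_dir`. A stage failure stops with the stage name.
#' With `resume = TRUE`, per-image ROI artifacts already on disk are
#' reused instead of recomputed.
#'
#' @param config config list (see [default_pipeline_config()]) or path to
#'   a YAML file.
#' @param out_dir results directory (created).
#' @param resume reuse existing per-image artifacts (default FALSE).
#' @return list with `measurements`, `fits`, `manifest` (invisibly also
#'   written to `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
  else validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "; artifacts so far are under ", out_dir, call. = FALSE)
    })
    timings[[name]] <<- round(tic() - t0, 3)
    r
  }
  meta <- utils::read.csv(file.path(cfg$study_dir, "chase_times.csv"))
  backend <- toy_backend()
  offsets <- pass_offsets(cfg$frame, cfg$n_passes)

  ref <- stage("preprocess_reference", {
    if (cfg$preprocess == "none") NULL else {
      p <- cfg$reference_image
      if (is.null(p)) p <- file.path(cfg$study_dir, meta$image_id[1], "em.png")
      read_gray_png(p)
    }
  })

  measurements <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$image_id[i]
    d <- file.path(cfg$study_dir, id)
    img <- read_gray_png(file.path(d, "em.png"))
    if (!is.null(ref)) {
      img <- stage(paste0("preprocess:", id), match_histogram(img, ref))
    }
    roi_prefix <- file.path(out_dir, paste0(id, "_rois"))
    if (resume && file.exists(paste0(roi_prefix, "_table.csv"))) {
      rois <- read_roi_set(roi_prefix)
    } else {
      dets <- stage(paste0("segment:", id), {
        out <- list()
        for (k in seq_along(offsets)) {
          grid <- build_tile_grid(dim(img), cfg$frame, offsets[k], pass_index = k)
          out <- c(out, run_pass(img, grid, backend))
        }
        out
      })
      rois <- stage(paste0("assemble:", id), {
        r <- merge_passes(dets, cfg$n_passes, cfg$merge$iou_link,
                          cfg$merge$min_support, image_shape = dim(img))
        morphological_filter(r, cfg$filter_rules)
      })
      write_roi_set(rois, roi_prefix)
    }
    cn14 <- read_ion_stack(file.path(d, "cn14"))
    cn15 <- read_ion_stack(file.path(d, "cn15"))
    corr <- stage(paste0("sims_correct:", id), correct_and_accumulate(cn14, cn15))
    tf <- stage(paste0("register:", id), {
      if (identical(cfg$registration$mode, "auto")) {
        anchors <- auto_anchor_nuclei(img, corr$cn14)
      } else {
        anchors <- read_anchors(file.path(d, "anchors.csv"))
      }
      f <- fit_similarity(anchors)
      write_transform_json(f, file.path(out_dir, paste0(id, "_transform.json")))
      f$transform
    })
    measurements[[i]] <- stage(paste0("quantify:", id), {
      warped <- suppressWarnings(warp_roi_set(rois, tf, dim(corr$cn14)))
      roi_enrichment(warped, corr$cn14, corr$cn15,
                     chase_time = meta$chase_time_h[i])
    })
    write_matrix_tsv(round(corr$cn14, 4),
                     file.path(out_dir, paste0(id, "_cn14_acc.tsv")))
  }
  measurements <- do.call(rbind, measurements)
  utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  fits <- stage("fit", fit_decay_by_class(measurements,
                                          fix_baseline = cfg$fix_baseline,
                                          e_nat = cfg$baseline))
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)

  comparison <- NULL
  if (length(unique(meta$group)) == 2) {
    comparison <- stage("compare", {
      gs <- split(measurements$ratio,
                  meta$group[match(measurements$chase_time, meta$chase_time_h)])
      compare_groups(gs[[1]], gs[[2]])
    })
  }

  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  manifest <- list(
    config = cfg, config_hash = fnv1a_hash(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("simscorr")),
    r_version = R.version.string,
    seed = cfg$seed, frame = cfg$frame, n_passes = cfg$n_passes,
    offsets = offsets, timings = timings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(measurements = measurements, fits = fits,
                 comparison = comparison, manifest = manifest))
}
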