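# Similarity transforms: closed-form fit, mask warping, auto anchors.

test_that("identity anchors fit the identity transform", {
  pts <- data.frame(em_x = c(10, 50, 30), em_y = c(10, 20, 60),
                    sims_x = c(10, 50, 30), sims_y = c(10, 20, 60))
  f <- fit_similarity(pts)
  expect_equal(f$transform$scale, 1, tolerance = 1e-12)
  expect_equal(f$transform$theta, 0, tolerance = 1e-12)
  expect_equal(c(f$transform$tx, f$transform$ty), c(0, 0), tolerance = 1e-12)
  expect_lt(f$rms_residual, 1e-9)
})

test_that("constructed similarity transforms are recovered exactly", {
  tf <- similarity_transform(scale = 2, theta = 30 * pi / 180, tx = 5, ty = -3)
  em <- cbind(x = c(10, 80, 30), y = c(20, 40, 90))
  sm <- transform_points(tf, em)
  f <- fit_similarity(data.frame(em_x = em[, 1], em_y = em[, 2],
                                 sims_x = sm[, 1], sims_y = sm[, 2]))
  expect_equal(f$transform$scale, 2, tolerance = 1e-9)
  expect_equal(f$transform$theta, 30 * pi / 180, tolerance = 1e-9)
  expect_equal(c(f$transform$tx, f$transform$ty), c(5, -3), tolerance = 1e-9)
  expect_lt(f$rms_residual, 1e-6)
})

test_that("fit recovers random transforms from random points (property)", {
  set.seed(9)
  for (i in 1:25) {
    tf <- similarity_transform(scale = runif(1, 0.5, 3),
                               theta = runif(1, -pi, pi),
                               tx = runif(1, -50, 50), ty = runif(1, -50, 50))
    n <- sample(3:8, 1)
    em <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    sm <- transform_points(tf, em)
    f <- fit_similarity(data.frame(em_x = em[, 1], em_y = em[, 2],
                                   sims_x = sm[, 1], sims_y = sm[, 2]))
    expect_equal(f$transform$scale, tf$scale, tolerance = 1e-6)
    expect_equal(f$transform$theta, tf$theta, tolerance = 1e-6)
    expect_lt(f$rms_residual, 1e-6)
  }
})

test_that("perturbed anchors give a positive residual near the truth", {
  tf <- similarity_transform(1.5, 0.3, 10, 20)
  em <- cbind(c(10, 90, 20, 70), c(15, 25, 80, 85))
  sm <- transform_points(tf, em)
  sm[4, ] <- sm[4, ] + c(1, 1)
  anchors <- data.frame(em_x = em[, 1], em_y = em[, 2],
                        sims_x = sm[, 1], sims_y = sm[, 2])
  f <- fit_similarity(anchors)
  expect_gt(f$rms_residual, 0.1)
  expect_equal(f$transform$scale, 1.5, tolerance = 0.05)
  # residual invariant under anchor-order permutation
  f2 <- fit_similarity(anchors[c(3, 1, 4, 2), ])
  expect_equal(f$rms_residual, f2$rms_residual, tolerance = 1e-12)
  # degenerate inputs
  expect_error(fit_similarity(anchors[1, , drop = FALSE]), "at least 2")
  same <- data.frame(em_x = c(5, 5), em_y = c(5, 5),
                     sims_x = c(1, 2), sims_y = c(1, 2))
  expect_error(fit_similarity(same), "coincident")
})

test_that("compose and invert behave as a group", {
  a <- similarity_transform(1.7, 0.4, 3, -2)
  b <- similarity_transform(0.6, -1.1, -8, 5)
  p <- cbind(c(3, 40, 17), c(25, 8, 60))
  expect_equal(transform_points(compose_transforms(a, b), p),
               transform_points(a, transform_points(b, p)), tolerance = 1e-12)
  id <- compose_transforms(a, invert_transform(a))
  expect_equal(id$scale, 1, tolerance = 1e-9)
  expect_equal(id$theta, 0, tolerance = 1e-9)
  expect_equal(c(id$tx, id$ty), c(0, 0), tolerance = 1e-9)
})

test_that("warp_mask scales areas by s^2 and round-trips", {
  sq <- rect_mask(c(100L, 100L), 41, 60, 41, 60) # 400 px
  # identity -> identical mask
  expect_identical(warp_mask(sq, similarity_transform(), c(100L, 100L)), sq)
  # s = 0.5 -> ~100 px (within 5%)
  w <- warp_mask(sq, similarity_transform(scale = 0.5), c(100L, 100L))
  expect_lt(abs(sum(w) - 100) / 100, 0.05)
  # warp there and back -> IoU >= 0.9 for instances >= 100 px
  tf <- similarity_transform(1.3, 0.5, 8, -5)
  there <- warp_mask(sq, tf, c(200L, 200L))
  expect_lt(abs(sum(there) - 400 * 1.3^2) / (400 * 1.3^2), 0.05)
  back <- warp_mask(there, invert_transform(tf), c(100L, 100L))
  expect_gte(mask_iou(sq, back), 0.9)
  # entirely outside -> empty with warning
  expect_warning(out <- warp_mask(sq, similarity_transform(tx = 500), c(100L, 100L)),
                 "outside")
  expect_false(any(out))
})

test_that("warped truth matches the ion-image ROI footprint", {
  ph <- make_em_phantom(small_spec(seed = 18, nucleolus = c(2, 2),
                                   mitochondria = c(3, 3)))
  tf <- similarity_transform(scale = 0.7, theta = 0.15, tx = 5, ty = 3)
  spec <- small_ion_spec(sims_shape = c(144L, 144L), em_to_sims = tf,
                         n_planes = 1L, drift = matrix(0L, 1, 2), dead_time = 0)
  ion <- make_ion_stack(spec, ph$truth, 0, poisson = FALSE)
  ratio <- ion$cn15$planes[[1]] / ion$cn14$planes[[1]]
  footprint <- ratio > spec$e_nat + 1e-9 # pixels the generator labeled
  warped <- warp_roi_set(ph$truth, tf, spec$sims_shape)
  union <- matrix(FALSE, 144, 144)
  for (p in warped$pixels) union[p] <- TRUE
  expect_gte(mask_iou(footprint, union), 0.9)
})

test_that("automatic nucleus anchors recover the transform", {
  ph <- make_em_phantom(small_spec(image_shape = c(256L, 256L), seed = 11,
                                   nucleolus = c(3, 3)))
  tf <- similarity_transform(scale = 0.5, theta = 0.2, tx = 10, ty = -4)
  spec <- small_ion_spec(sims_shape = c(160L, 160L), em_to_sims = tf, seed = 5)
  ion <- make_ion_stack(spec, ph$truth, 24, poisson = TRUE)
  corr <- correct_and_accumulate(ion$cn14, ion$cn15)
  anchors <- auto_anchor_nuclei(ph$image, corr$cn14)
  f <- fit_similarity(anchors)
  expect_lt(abs(f$transform$scale - tf$scale) / tf$scale, 0.02)
  # mapped positions within 2 px of the true mapping across the frame
  test_pts <- cbind(x = c(50, 200, 120), y = c(60, 90, 220))
  err <- sqrt(rowSums((transform_points(f$transform, test_pts) -
                         transform_points(tf, test_pts))^2))
  expect_lt(max(err), 2)
})

test_that("auto anchors error with fewer than 2 blob pairs", {
  ph <- make_em_phantom(small_spec(image_shape = c(128L, 128L), seed = 3,
                                   nucleolus = c(1, 1)))
  spec <- small_ion_spec(sims_shape = c(96L, 96L),
                         em_to_sims = similarity_transform(0.7))
  ion <- make_ion_stack(spec, ph$truth, 0)
  corr <- correct_and_accumulate(ion$cn14, ion$cn15)
  expect_error(auto_anchor_nuclei(ph$image, corr$cn14), "manual anchors")
})

test_that("identical modalities give the identity transform", {
  ph <- make_em_phantom(small_spec(image_shape = c(256L, 256L), seed = 11,
                                   nucleolus = c(3, 3)))
  # invert the EM image so blobs are bright, as in a CN- count image
  f <- fit_similarity(auto_anchor_nuclei(ph$image, 1 - ph$image))
  expect_equal(f$transform$scale, 1, tolerance = 1e-6)
  expect_equal(f$transform$theta, 0, tolerance = 1e-6)
  expect_equal(c(f$transform$tx, f$transform$ty), c(0, 0), tolerance = 1e-4)
})

test_that("anchors and transforms round-trip through CSV / JSON", {
  d <- withr::local_tempdir()
  anchors <- data.frame(em_x = c(1, 2, 3), em_y = c(4, 5, 6),
                        sims_x = c(7, 8, 9), sims_y = c(1, 3, 5))
  write_anchors(anchors, file.path(d, "a.csv"))
  expect_equal(read_anchors(file.path(d, "a.csv")), anchors)
  tf <- similarity_transform(1.25, 0.3, -4, 7)
  write_transform_json(tf, file.path(d, "t.json"))
  back <- read_transform_json(file.path(d, "t.json"))
  expect_equal(back$scale, 1.25, tolerance = 1e-12)
  expect_equal(back$theta, 0.3, tolerance = 1e-12)
})
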