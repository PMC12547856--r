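# Synthetic EM/ion phantom generator.

test_that("empty spec yields a blank background image and an empty truth", {
  sp <- small_spec(seed = 3)
  ph <- make_em_phantom(sp)
  expect_equal(length(ph$truth), 0L)
  expect_equal(dim(ph$image), c(160L, 160L))
  # background only: all pixels within a few sd of the background level
  expect_true(all(abs(ph$image - sp$background) < 6 * sp$noise_sd))
})

test_that("same spec and seed produce identical phantoms", {
  sp <- small_spec(seed = 42, vesicles = c(4, 4), mitochondria = c(2, 2))
  a <- make_em_phantom(sp)
  b <- make_em_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$pixels, b$truth$pixels)
  expect_identical(a$truth$table, b$truth$table)
  # and does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(make_em_phantom(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("requested vesicles are circular, disjoint, connected instances", {
  ph <- make_em_phantom(small_spec(seed = 7, vesicles = c(5, 5)))
  expect_equal(length(ph$truth), 5L)
  expect_true(all(ph$truth$table$class == "vesicles"))
  all_pix <- unlist(ph$truth$pixels)
  expect_false(anyDuplicated(all_pix) > 0) # mutually disjoint
  for (i in 1:5) {
    m <- roi_mask(ph$truth, i)
    expect_equal(max(label_components(m)), 1L) # connected
    expect_gte(shape_descriptors(m)$circularity, 0.85)
  }
})

test_that("classes occupy their intensity bands", {
  ph <- make_em_phantom(small_spec(seed = 5, mitochondria = c(3, 3),
                                   vesicles = c(3, 3)))
  bands <- phantom_bands()
  for (i in seq_len(length(ph$truth))) {
    cl <- ph$truth$table$class[i]
    v <- ph$image[ph$truth$pixels[[i]]]
    expect_true(all(abs(v - bands$center[[cl]]) <= bands$halfwidth),
                info = cl)
  }
})

test_that("impossible placement raises an explicit error", {
  sp <- phantom_spec(image_shape = c(40L, 40L),
                     counts = counts_only(nucleolus = c(4, 4)),
                     seed = 1)
  expect_error(make_em_phantom(sp), "too small|failed to place")
})

test_that("phantom_spec validates its invariants", {
  expect_error(phantom_spec(counts = list(vesicles = c(1, 1))), "six classes")
  bad_shape <- phantom_spec()$shape
  bad_shape$ER$r_minor <- c(-1, 2)
  expect_error(phantom_spec(shape = bad_shape), "positive")
  expect_error(phantom_spec(texture_amp = 0.2), "halfwidth")
})

test_that("ion_phantom_spec validates its invariants", {
  expect_error(ion_phantom_spec(t_half = c(vesicles = -1)), "positive")
  expect_error(ion_phantom_spec(e0 = 0.002, e_nat = 0.0037), "e_nat < e0")
  expect_error(ion_phantom_spec(chase_times = c(0, 12, 12)), "increasing")
  expect_error(ion_phantom_spec(n_planes = 0), ">= 1")
})

test_that("noiseless stacks realize the stated decay model exactly", {
  ph <- make_em_phantom(small_spec(seed = 2, mitochondria = c(3, 3)))
  spec <- small_ion_spec(sims_shape = c(160L, 160L), n_planes = 1L,
                         drift = matrix(0L, 1, 2), dead_time = 0)
  # t = 0: in-ROI ratio is exactly E0
  ion <- make_ion_stack(spec, ph$truth, 0, poisson = FALSE)
  r <- ion$cn15$planes[[1]] / ion$cn14$planes[[1]]
  in_roi <- unlist(ph$truth$pixels) # identity transform, same shape
  expect_equal(unique(round(r[in_roi], 12)), spec$e0)
  expect_equal(unique(round(r[-in_roi], 12)), spec$e_nat)
  # t = T_c: in-ROI ratio is halfway between E0 and E_nat
  spec2 <- small_ion_spec(sims_shape = c(160L, 160L), n_planes = 1L,
                          drift = matrix(0L, 1, 2), dead_time = 0,
                          t_half = c(mitochondria = 21.5))
  ion2 <- make_ion_stack(spec2, ph$truth, 21.5, poisson = FALSE)
  r2 <- ion2$cn15$planes[[1]] / ion2$cn14$planes[[1]]
  expect_equal(unique(round(r2[in_roi], 12)),
               spec2$e_nat + (spec2$e0 - spec2$e_nat) / 2)
})

test_that("E0 = E_nat gives a flat ratio everywhere", {
  ph <- make_em_phantom(small_spec(seed = 2, vesicles = c(2, 2)))
  spec <- small_ion_spec(sims_shape = c(160L, 160L), n_planes = 1L,
                         drift = matrix(0L, 1, 2), dead_time = 0,
                         e0 = 0.0037 + 1e-12, e_nat = 0.0037)
  ion <- make_ion_stack(spec, ph$truth, 5, poisson = FALSE)
  r <- ion$cn15$planes[[1]] / ion$cn14$planes[[1]]
  expect_true(all(abs(r - spec$e_nat) < 1e-9))
})

test_that("count conservation: zero drift, no noise => sum equals n_planes x plane", {
  ph <- make_em_phantom(small_spec(seed = 4, Golgi = c(2, 2)))
  spec <- small_ion_spec(sims_shape = c(160L, 160L), n_planes = 4L,
                         drift = matrix(0L, 4, 2), dead_time = 0)
  ion <- make_ion_stack(spec, ph$truth, 12, poisson = FALSE)
  acc <- accumulate_planes(ion$cn14, matrix(0L, 4, 2))
  expect_equal(unclass(acc), 4 * ion$cn14$planes[[1]],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Poisson means recover expectation within 4 standard errors", {
  # one large nucleolus: >= 1e4 pixels in the SIMS frame
  sp <- phantom_spec(image_shape = c(200L, 200L),
                     counts = counts_only(nucleolus = c(1, 1)),
                     shape = utils::modifyList(phantom_spec()$shape,
                                               list(nucleolus = list(r_major = c(60, 60), r_minor = c(60, 60)))),
                     seed = 9)
  ph <- make_em_phantom(sp)
  spec <- small_ion_spec(sims_shape = c(200L, 200L), n_planes = 1L,
                         drift = matrix(0L, 1, 2), dead_time = 0, seed = 21)
  ion <- make_ion_stack(spec, ph$truth, 0, poisson = TRUE)
  idx <- ph$truth$pixels[[1]]
  expect_gte(length(idx), 1e4)
  lam <- spec$mean_cn14 * spec$cn14_density[["nucleolus"]]
  obs <- mean(ion$cn14$planes[[1]][idx])
  se <- sqrt(lam / length(idx))
  expect_lt(abs(obs - lam), 4 * se)
})

test_that("ion stacks are deterministic and reject oversize drift", {
  ph <- make_em_phantom(small_spec(seed = 2, vesicles = c(2, 2)))
  spec <- small_ion_spec(sims_shape = c(96L, 96L), seed = 5)
  a <- make_ion_stack(spec, ph$truth, 12)
  b <- make_ion_stack(spec, ph$truth, 12)
  expect_identical(a$cn14$planes, b$cn14$planes)
  expect_identical(a$cn15$planes, b$cn15$planes)
  spec_bad <- small_ion_spec(sims_shape = c(96L, 96L), n_planes = 2L,
                             drift = rbind(c(0L, 0L), c(200L, 0L)))
  expect_error(make_ion_stack(spec_bad, ph$truth, 0), "drift")
})

test_that("dead-time deflation is applied so that correction inverts it", {
  ph <- make_em_phantom(small_spec(seed = 2, mitochondria = c(2, 2)))
  spec0 <- small_ion_spec(sims_shape = c(120L, 120L), dead_time = 0,
                          n_planes = 2L, drift = matrix(0L, 2, 2), seed = 8)
  specd <- small_ion_spec(sims_shape = c(120L, 120L), dead_time = 44e-9,
                          n_planes = 2L, drift = matrix(0L, 2, 2), seed = 8)
  raw <- make_ion_stack(spec0, ph$truth, 0)
  defl <- make_ion_stack(specd, ph$truth, 0)
  # same seed => same Poisson draw; correction recovers the raw counts
  rec <- dead_time_correct(defl$cn14)
  expect_equal(rec$planes, raw$cn14$planes, tolerance = 1e-12)
  expect_true(all(defl$cn14$planes[[1]] <= raw$cn14$planes[[1]]))
})

test_that("phantom writer emits PNG + label TSV + instance CSV", {
  d <- withr::local_tempdir()
  ph <- make_em_phantom(small_spec(seed = 6, vesicles = c(3, 3)))
  write_em_phantom(ph, d)
  expect_true(file.exists(file.path(d, "em.png")))
  back <- read_roi_set(file.path(d, "truth"))
  expect_equal(length(back), 3L)
  expect_setequal(unlist(back$pixels), unlist(ph$truth$pixels))
  img <- read_gray_png(file.path(d, "em.png"))
  expect_equal(dim(img), dim(ph$image))
  expect_lt(max(abs(img - ph$image)), 1 / 255) # 8-bit quantization only
})
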