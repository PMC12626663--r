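test_that("median filter matches a naive neighbourhood median", {
  set.seed(4)
  img <- matrix(rnorm(15 * 11), 15, 11)
  ref <- img
  for (i in 1:15) for (j in 1:11) {
    ii <- pmin(pmax((i - 1):(i + 1), 1), 15)
    jj <- pmin(pmax((j - 1):(j + 1), 1), 11)
    ref[i, j] <- median(img[ii, jj])
  }
  expect_equal(median_filter3(img), ref, tolerance = 1e-14)
})

test_that("despiking restores isolated dead and saturated pixels", {
  img <- matrix(100, 20, 20)
  img[7, 7] <- 0        # dead pixel
  img[13, 4] <- 65535   # saturated pixel
  expect_equal(median_filter3(img), matrix(100, 20, 20))
  # constant image is a fixed point of the whole chain
  expect_equal(despike_and_smooth(matrix(7, 16, 16)), matrix(7, 16, 16),
               tolerance = 1e-12)
})

test_that("smoothing reduces Poisson pixel variance and keeps nonnegativity", {
  set.seed(6)
  img <- matrix(rpois(96 * 96, 100), 96, 96)
  out <- despike_and_smooth(img)
  expect_lt(var(as.vector(out)), var(as.vector(img)))
  expect_true(all(out >= 0))
  expect_identical(dim(out), dim(img))
})

flat_refs <- function(G = 80, n = 32, ids = c("c1", "c2"), rv = c(c1 = 4, c2 = 8)) {
  structure(list(
    background_images = setNames(lapply(ids, function(i) matrix(10, n, n)), ids),
    calibration_images = setNames(lapply(ids, function(i) matrix(10 + G, n, n)), ids),
    reference_values = rv, dark_offset = 0), class = "reference_set")
}

test_that("calibration model on noise-free flat frames recovers scale exactly", {
  refs <- flat_refs(G = 80)
  model <- fit_calibration(refs)
  for (id in c("c1", "c2")) {
    expect_equal(model$flatfield[[id]], matrix(1, 32, 32), tolerance = 1e-10)
    expect_equal(model$scale[[id]], refs$reference_values[[id]] / 80,
                 tolerance = 1e-10)
  }
  # doubling the excess halves the scale factor
  model2 <- fit_calibration(flat_refs(G = 160))
  expect_equal(model2$scale[["c1"]], model$scale[["c1"]] / 2, tolerance = 1e-10)
})

test_that("channels whose calibration frame adds nothing are rejected by name", {
  refs <- flat_refs()
  refs$calibration_images[["c2"]] <- refs$background_images[["c2"]]
  expect_error(fit_calibration(refs), "uncalibratable channel c2")
})

test_that("calibrating the calibration frame itself returns reference units", {
  # defining property of the scale factor: the block equal to the calibration
  # frame maps to a spatial mean equal to the reference value
  refs <- flat_refs(G = 120, ids = c("c1", "c2", "c3"),
                    rv = c(c1 = 4, c2 = 8, c3 = 2))
  ch <- tiny_channels()
  refs$background_images <- setNames(refs$background_images[1:3], ch$channel_id)
  refs$calibration_images <- setNames(refs$calibration_images[1:3], ch$channel_id)
  names(refs$reference_values) <- ch$channel_id
  model <- fit_calibration(refs)
  block <- data_block("s", "p", "G", ch, refs$calibration_images,
                      matrix(0, 32, 32))
  out <- calibrate_block(block, model)
  for (id in ch$channel_id) {
    expect_equal(mean(out$images[[id]]), refs$reference_values[[id]],
                 tolerance = 1e-8)
  }
  # a block equal to the water frame calibrates to ~0
  block0 <- data_block("s", "p", "G", ch, refs$background_images,
                       matrix(0, 32, 32))
  out0 <- calibrate_block(block0, model)
  expect_lt(max(abs(unlist(out0$images))), 1e-8)
  # calibrating twice is an error, not a no-op
  expect_error(calibrate_block(out, model), "already calibrated")
})

test_that("calibration is linear above background (before the clamp)", {
  refs <- flat_refs(G = 100, ids = c("c1", "c2", "c3"))
  ch <- tiny_channels()
  refs$background_images <- setNames(refs$background_images, ch$channel_id)
  refs$calibration_images <- setNames(refs$calibration_images, ch$channel_id)
  refs$reference_values <- setNames(c(4, 8, 2), ch$channel_id)
  model <- fit_calibration(refs)
  # planar (locally monotone) images: the 3x3 median is exactly the identity
  # there, so the remaining chain (Gaussian, subtract, divide, scale) must be
  # exactly affine; intensities stay far above background so the clamp is idle
  plane <- function(a, b, c) {
    outer(seq_len(32), seq_len(32), function(y, x) a * y + b * x + c)
  }
  mk <- function(a, b, c) {
    imgs <- setNames(lapply(1:3, function(i) plane(a * i, b, c)),
                     ch$channel_id)
    data_block("s", "p", "G", ch, imgs, matrix(0, 32, 32))
  }
  I <- mk(2, 3, 300); J <- mk(1, -2, 700)
  alpha <- 0.3
  mix <- I
  for (id in ch$channel_id) {
    mix$images[[id]] <- alpha * I$images[[id]] + (1 - alpha) * J$images[[id]]
  }
  cI <- calibrate_block(I, model); cJ <- calibrate_block(J, model)
  cM <- calibrate_block(mix, model)
  # interior only: replicate-padded border neighbourhoods make the median
  # non-affine at the frame edge
  keep <- 6:27
  for (id in ch$channel_id) {
    expect_equal(cM$images[[id]][keep, keep],
                 (alpha * cI$images[[id]] + (1 - alpha) * cJ$images[[id]])[keep, keep],
                 tolerance = 1e-10)
  }
})

test_that("flat-field correction removes the illumination gradient for cells", {
  # two identical cells, field center vs corner: calibrated means agree within
  # 5%; uncorrected raw means differ by more than 15%
  ch <- tiny_channels()
  fl <- list("NADH-like" = default_fluorophores()[["NADH-like"]])
  am <- matrix(1, 1, 1, dimnames = list("G0", names(fl)))
  cfg <- cohort_config(groups = "G0", patients_per_group = 1,
                       cells_per_patient = c(2, 2), fluorophores = fl,
                       abundance_means = am, illumination_gradient = 0.4,
                       background_level = 20, dead_pixel_rate = 0,
                       saturated_pixel_rate = 0, patient_effect_sd = 0,
                       abundance_cv = 0, texture_sd = 0, field_px = 128,
                       cell_radius_px = c(9, 9), seed = 5)
  set.seed(5)
  refs <- render_reference_set(cfg, ch)
  model <- fit_calibration(refs)
  # hand-placed cells: center and corner
  illum <- illumination_field(128, 128, 0.4)
  resp <- channel_response_vector(fl[[1]], ch)
  label <- matrix(0L, 128, 128)
  yy <- matrix(1:128, 128, 128); xx <- t(yy)
  label[(yy - 64)^2 + (xx - 64)^2 <= 81] <- 1L
  label[(yy - 14)^2 + (xx - 14)^2 <= 81] <- 2L
  set.seed(55)
  imgs <- setNames(lapply(ch$channel_id, function(id) {
    expected <- illum * (ifelse(label > 0, cfg$photon_gain * resp[[id]], 0) + 20)
    matrix(rpois(128 * 128, expected), 128, 128)
  }), ch$channel_id)
  block <- data_block("s", "p", "G0", ch, imgs, matrix(0, 128, 128))
  cal <- calibrate_block(block, model)
  id <- ch$channel_id[1]  # strongest NADH channel
  raw_center <- mean(block$images[[id]][label == 1])
  raw_corner <- mean(block$images[[id]][label == 2])
  cal_center <- mean(cal$images[[id]][label == 1])
  cal_corner <- mean(cal$images[[id]][label == 2])
  expect_gt(abs(raw_center - raw_corner) / raw_center, 0.15)
  expect_lt(abs(cal_center - cal_corner) / cal_center, 0.05)
})

test_that("calibration models round-trip through the JSON + TIFF bundle", {
  refs <- flat_refs(G = 90)
  model <- fit_calibration(refs)
  dir <- withr::local_tempdir()
  write_calibration_model(model, dir)
  back <- read_calibration_model(dir)
  expect_equal(back$scale, model$scale, tolerance = 1e-6)
  for (id in names(model$flatfield)) {
    expect_equal(back$flatfield[[id]], model$flatfield[[id]], tolerance = 1e-6)
    expect_equal(back$background[[id]], model$background[[id]], tolerance = 1e-6)
  }
})
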