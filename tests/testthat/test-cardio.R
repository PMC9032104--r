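# Heartbeat detection, kymographs, perimeters, contraction.

test_that("extract_trace averages the ROI and spans the recording", {
  stack <- frame_stack(array(7, dim = c(10, 12, 60)), fps = 20)
  tr <- extract_trace(stack, c(2, 1, 8, 9))
  expect_true(all(tr$v == 7))
  expect_equal(length(tr$v), 60)
  expect_equal(max(tr$t), 59 / 20)
  expect_error(extract_trace(stack, c(0, 0, 20, 5)), "out of bounds")
  expect_error(extract_trace(stack, c(3, 3, 3, 6)), "empty")
})

test_that("detect_beats counts a pure sinusoid correctly", {
  t <- seq(0, 30 - 1/60, by = 1/60)
  tr <- intensity_trace(t, sin(2 * pi * 2 * t))  # 2 Hz for 30 s
  pk <- detect_beats(tr)
  expect_equal(length(pk$indices), 60)
  # flat trace: zero peaks, not an error
  expect_equal(length(detect_beats(intensity_trace(t, rep(1, length(t))))$indices), 0)
})

test_that("detect_beats tolerates 10% amplitude noise within one beat", {
  t <- seq(0, 30 - 1/60, by = 1/60)
  clean <- sin(2 * pi * 2 * t)
  noisy <- clean + withr::with_seed(42, rnorm(length(t), sd = 0.1))
  pk <- detect_beats(intensity_trace(t, noisy))
  expect_lte(abs(length(pk$indices) - 60), 1)
})

test_that("detect_beats is invariant to affine intensity rescaling", {
  t <- seq(0, 10 - 1/50, by = 1/50)
  v <- sin(2 * pi * 1.7 * t) + 0.3 * sin(2 * pi * 0.2 * t)
  a <- detect_beats(intensity_trace(t, v))
  b <- detect_beats(intensity_trace(t, 250 * v + 1000))
  expect_identical(a$indices, b$indices)
})

test_that("compute_bpm applies the general 60/duration rule", {
  expect_equal(compute_bpm(75, 30)$bpm, 150)   # 30 s recording: count doubled
  expect_equal(compute_bpm(0, 30)$bpm, 0)
  expect_equal(compute_bpm(120, 60)$bpm, 120)
  expect_error(compute_bpm(10, 0), "positive")
  # linearity: halving the duration doubles the bpm for the same count
  expect_equal(compute_bpm(40, 15)$bpm, 2 * compute_bpm(40, 30)$bpm)
})

test_that("kymograph columns track frames and agree with extract_trace", {
  sim <- simulate_heart_video(heart_sim_params(
    bpm_true = 120, fps = 30, duration = 6, noise_sd = 0, seed = 1,
    frame_size = c(64, 96), atrium_perims = c(70, 50),
    ventricle_perims = c(80, 60)))
  roi <- sim$truth$heart_roi
  ky <- build_kymograph(sim$stack, roi)
  expect_equal(ncol(ky$matrix), dim(sim$stack$frames)[3])
  tr <- extract_trace(sim$stack, roi)
  expect_equal(ky$raw_trace, unname(tr$v), tolerance = 1e-12)
  # dominant frequency of the column-mean series equals the true beat rate
  expect_equal(fft_peak_hz(ky$raw_trace, sim$stack$fps), 120 / 60,
               tolerance = 1e-6)
  # static frames give identical columns
  static <- frame_stack(array(rep(matrix(runif(64 * 96), 64, 96), 5),
                              dim = c(64, 96, 5)), fps = 10)
  ky2 <- build_kymograph(static, c(10, 10, 60, 40))
  expect_true(all(abs(ky2$matrix - ky2$matrix[, 1]) < 1e-12))
})

test_that("perimeter estimator matches analytic oracles within 2%", {
  grid <- function(h, w) list(x = matrix(rep(1:w, each = h), h, w),
                              y = matrix(rep(1:h, w), h, w))
  g <- grid(160, 160)
  aa_ellipse <- function(a, b) {
    e <- sqrt(((g$x - 80) / a)^2 + ((g$y - 80) / b)^2)
    cov <- 0.5 - (e - 1) * b / 1.5
    cov[cov < 0] <- 0; cov[cov > 1] <- 1
    cov
  }
  # ellipse a=50, b=30 against the Ramanujan oracle
  expect_equal(measure_chamber_perimeter(aa_ellipse(50, 30), threshold = 0.5),
               ellipse_perimeter(50, 30), tolerance = 0.02)
  # circle r=40 against 2*pi*r
  expect_equal(measure_chamber_perimeter(aa_ellipse(40, 40), threshold = 0.5),
               2 * pi * 40, tolerance = 0.02)
  # 100 x 100 square
  sq <- matrix(0, 160, 160); sq[31:130, 31:130] <- 1
  expect_equal(measure_chamber_perimeter(sq, threshold = 0.5), 400,
               tolerance = 0.02)
  # physical units via pixel_size
  expect_equal(measure_chamber_perimeter(aa_ellipse(40, 40), threshold = 0.5,
                                         pixel_size = 0.01),
               2 * pi * 40 * 0.01, tolerance = 0.02)
})

test_that("perimeter measurement rejects ambiguous segmentations", {
  two <- matrix(0, 60, 60)
  two[10:20, 10:20] <- 1; two[40:50, 40:50] <- 1
  expect_error(measure_chamber_perimeter(two, threshold = 0.5), "2 candidate")
  expect_error(measure_chamber_perimeter(matrix(0, 30, 30), threshold = 0.5),
               "no chamber")
})

test_that("compute_contraction reproduces the perimeter formula", {
  expect_equal(compute_contraction(chamber_measurement("atrium", 100, 80))$percent, 20)
  expect_equal(compute_contraction(chamber_measurement("atrium", 50, 50))$percent, 0)
  reps <- rbind(chamber_measurement("ventricle", 100, 80, 1),
                chamber_measurement("ventricle", 120, 90, 2),
                chamber_measurement("ventricle", 110, 88, 3))
  expect_equal(compute_contraction(reps)$percent, mean(c(20, 25, 20)),
               tolerance = 1e-12)
  # Cs > Cd is flagged, not silently swallowed
  expect_warning(r <- compute_contraction(chamber_measurement("atrium", 80, 100)),
                 "negative contraction")
  expect_equal(r$percent, -25)
  expect_error(compute_contraction(rbind(chamber_measurement("atrium", 1, 1),
                                         chamber_measurement("ventricle", 1, 1))),
               "same chamber")
})

test_that("video-based contraction recovers the generator truth", {
  sim <- simulate_heart_video(heart_sim_params(
    bpm_true = 120, fps = 30, duration = 5, noise_sd = 0, seed = 2,
    frame_size = c(64, 96), atrium_perims = c(70, 50),
    ventricle_perims = c(80, 60)))
  ct <- contraction_from_video(sim$stack,
                               list(atrium = sim$truth$chambers$atrium$roi,
                                    ventricle = sim$truth$chambers$ventricle$roi))
  expect_equal(ct$atrium$percent, sim$truth$chambers$atrium$contraction_pct,
               tolerance = 0.03)
  expect_equal(ct$ventricle$percent, sim$truth$chambers$ventricle$contraction_pct,
               tolerance = 0.03)
  expect_equal(ct$atrium$n_replicates, 3)
  # area-based variant moves in the same direction
  cta <- contraction_from_video(sim$stack,
                                list(ventricle = sim$truth$chambers$ventricle$roi),
                                use_area = TRUE)
  expect_gt(cta$ventricle$percent, ct$ventricle$percent)  # area ~ perimeter^2
})
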