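# Generators: determinism, ground-truth contracts, invariants.

test_that("heart video has the expected frame count and noiseless periodicity", {
  p <- heart_sim_params(bpm_true = 120, fps = 60, duration = 30, noise_sd = 0, seed = 1)
  sim <- simulate_heart_video(p)
  expect_equal(dim(sim$stack$frames)[3], 1800)  # 120 bpm x 0.5 min = 60 cycles
  tr <- extract_trace(sim$stack, sim$truth$heart_roi)
  period <- 60 * 60 / 120  # fps * 60 / bpm samples
  expect_equal(tr$v[seq_len(1800 - period)], tr$v[(period + 1):1800],
               tolerance = 1e-12)
})

test_that("heart video generation is deterministic under a fixed seed", {
  p <- heart_sim_params(bpm_true = 150, fps = 30, duration = 4, noise_sd = 0.05,
                        seed = 7, frame_size = c(64, 96),
                        atrium_perims = c(70, 50), ventricle_perims = c(80, 60))
  a <- simulate_heart_video(p)
  b <- simulate_heart_video(p)
  expect_identical(a$stack$frames, b$stack$frames)
  # global RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_heart_video(p))
  expect_identical(before, .Random.seed)
})

test_that("sub-Nyquist frame rates are rejected with an explicit message", {
  expect_error(heart_sim_params(bpm_true = 240, fps = 7), "Nyquist")
  expect_error(heart_sim_params(atrium_perims = c(90, 120)), "diastolic > systolic")
})

test_that("trajectory path length matches the target to 1e-6 relative", {
  p <- swim_sim_params(n_larvae = 4, duration = 20, fps = 10,
                       target_distance = c(0, 0.7, 2, 5), seed = 11)
  sim <- simulate_trajectories(p)
  lens <- vapply(sim$trajectories, path_length, numeric(1), unit = "cm")
  expect_equal(lens[1], 0)
  expect_true(all(abs(lens[-1] / c(0.7, 2, 5) - 1) < 1e-6))
  # zero-distance walk never moves
  expect_true(all(sim$trajectories[[1]]$x == sim$trajectories[[1]]$x[1]))
  # confinement to the arena
  r_max <- max(vapply(sim$trajectories, function(tr) max(sqrt(tr$x^2 + tr$y^2)),
                      numeric(1)))
  expect_lte(r_max, p$arena_diameter / 2)
  # determinism
  sim2 <- simulate_trajectories(p)
  expect_identical(sim$trajectories, sim2$trajectories)
})

test_that("unreachable target distances are rejected", {
  # 1 m in two samples inside a 50 mm dish cannot fit
  p <- swim_sim_params(n_larvae = 1, duration = 0.2, fps = 10,
                       target_distance = 100, seed = 1)
  expect_error(simulate_trajectories(p), "unreachable")
})

test_that("birefringence image mean matches the analytic ground truth", {
  clean <- simulate_birefringence_image(0, noise_sd = 0, seed = 1)
  r <- quantify_birefringence(clean$image, clean$truth$trunk_roi,
                              clean$truth$background_roi)
  expect_equal(r$trunk_mean, clean$truth$trunk_mean, tolerance = 1e-12)

  # full lesion at attenuation 0.5 halves the trunk mean
  full <- simulate_birefringence_image(1, attenuation = 0.5, noise_sd = 0, seed = 1)
  expect_equal(full$truth$lesion_fraction, 1)
  rf <- quantify_birefringence(full$image, full$truth$trunk_roi,
                               full$truth$background_roi)
  expect_equal(rf$trunk_mean, 0.5 * clean$truth$trunk_mean, tolerance = 1e-12)

  # monotone attenuation with lesion fraction (noise off)
  fr <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(fr, function(f) {
    s <- simulate_birefringence_image(f, noise_sd = 0, seed = 3)
    quantify_birefringence(s$image, s$truth$trunk_roi, s$truth$background_roi)$trunk_mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("mortality generator hits p = 1/2 at the true LC50 and is reproducible", {
  prm <- mortality_sim_params(c(10, 20, 30, 45, 70), n_per_dose = 20,
                              beta0 = -2 * log10(30), beta1 = 2, seed = 5)
  sim <- simulate_mortality(prm)
  expect_equal(sim$truth$lc50, 30, tolerance = 1e-12)
  expect_equal(sim$truth$p[3], 0.5, tolerance = 1e-12)  # logit 0 at LC50
  expect_true(all(sim$data$n_dead >= 0 & sim$data$n_dead <= 20))
  expect_identical(simulate_mortality(prm)$data, sim$data)

  # near-infinite slope gives all-or-nothing mortality around the LC50
  step <- simulate_mortality(mortality_sim_params(
    c(10, 20, 29, 31, 45, 70), 20, beta0 = -1e6 * log10(30), beta1 = 1e6, seed = 1))
  expect_identical(step$data$n_dead, c(0L, 0L, 0L, 20L, 20L, 20L))
})

test_that("Ct tables follow the amplification-efficiency model exactly", {
  # efficiency 1: doubling the template lowers Ct by exactly one cycle
  sim <- simulate_ct_table(qpcr_sim_params(c(100, 200), efficiency_true = 1,
                                           ct_at_unit = 35, noise_sd = 0))
  expect_equal(diff(sim$data$ct), -1, tolerance = 1e-12)
  # 5-fold dilution spacing at efficiency 1 is log2(5)
  dil <- simulate_ct_table(qpcr_sim_params(1000 * 5^-(0:4), efficiency_true = 1,
                                           ct_at_unit = 35, noise_sd = 0))
  expect_equal(unique(round(diff(dil$data$ct), 10)), log(5, 2),
               tolerance = 1e-10)
  # seeded noise reproducible
  a <- simulate_ct_table(qpcr_sim_params(c(10, 20), noise_sd = 0.3, seed = 9))
  b <- simulate_ct_table(qpcr_sim_params(c(10, 20), noise_sd = 0.3, seed = 9))
  expect_identical(a$data, b$data)
})

test_that("touch assay ground truth is classifiable without error", {
  cls <- rep(c("no_response", "response_without_escaping",
               "short_distance", "long_distance"), each = 5)
  assay <- simulate_touch_assay(cls, seed = 2)
  got <- vapply(seq_len(nrow(assay)), function(i)
    as.character(classify_touch_response(assay$distance_mm[i],
                                         assay$undulation[i])), character(1))
  expect_identical(got, as.character(assay$class_true))
})

test_that("ground-truth sidecars round-trip through JSON", {
  sim <- simulate_birefringence_image(0.3, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$trunk_mean, sim$truth$trunk_mean, tolerance = 1e-12)
  expect_equal(back$lesion_fraction, sim$truth$lesion_fraction)
})
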