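# Synthetic-data generators with analytic ground truth. These stand in for
# the raw laboratory recordings (heart videos, swim recordings,
# polarized-light images, dose-mortality counts, qPCR plates) so that every
# downstream stage of the pipeline can be exercised against known truth.

#' Parameters for the synthetic heart video generator
#'
#' The beating heart is modelled as two anti-aliased ellipses (atrium and
#' ventricle) whose Ramanujan perimeters oscillate sinusoidally between the
#' stated diastolic and systolic values at `bpm_true`, with a configurable
#' phase offset between the chambers, over a uniform background.
#'
#' @param bpm_true True heart rate in beats per minute.
#' @param fps Acquisition rate, frames per second. Must satisfy the Nyquist
#'   bound `fps >= 2 * bpm_true / 60` for beat counting.
#' @param duration Recording length in seconds (30 s mirrors the assay this
#'   generator emulates).
#' @param atrium_perims,ventricle_perims Length-2 vectors
#'   `(diastolic, systolic)` chamber perimeter in pixels; diastolic must
#'   exceed systolic.
#' @param phase_offset Fraction of a cycle in `[0, 1)` by which the
#'   ventricle lags the atrium.
#' @param noise_sd Additive Gaussian pixel-noise standard deviation, on the
#'   `[0, 1]` intensity scale.
#' @param seed RNG seed (the generator never touches global RNG state).
#' @param frame_size Frame dimensions `c(height, width)` in pixels.
#' @return A validated `heart_sim_params` list.
#' @export
heart_sim_params <- function(bpm_true = 150, fps = 60, duration = 30,
                             atrium_perims = c(120, 90),
                             ventricle_perims = c(140, 100),
                             phase_offset = 0.15, noise_sd = 0, seed = 1,
                             frame_size = c(96, 128)) {
  stopifnot(bpm_true > 0, duration > 0, noise_sd >= 0,
            phase_offset >= 0, phase_offset < 1,
            length(atrium_perims) == 2, length(ventricle_perims) == 2)
  if (fps < 2 * bpm_true / 60)
    stop(sprintf("fps = %g is below the Nyquist bound 2 * bpm/60 = %g; beats cannot be counted",
                 fps, 2 * bpm_true / 60))
  for (p in list(atrium = atrium_perims, ventricle = ventricle_perims))
    if (!(p[1] > p[2] && p[2] > 0))
      stop("chamber perimeters must satisfy diastolic > systolic > 0")
  structure(list(bpm_true = bpm_true, fps = fps, duration = duration,
                 atrium_perims = atrium_perims,
                 ventricle_perims = ventricle_perims,
                 phase_offset = phase_offset, noise_sd = noise_sd,
                 seed = seed, frame_size = as.integer(frame_size)),
            class = "heart_sim_params")
}

# Chamber geometry shared by the renderer and the ground-truth record.
heart_geometry <- function(params) {
  h <- params$frame_size[1]; w <- params$frame_size[2]
  # recordings start mid-cycle (0.3 of a period past diastole), as real
  # footage does; the ventricle additionally lags by the phase offset
  geo <- list(
    atrium = list(center = c(x = round(0.30 * w), y = round(h / 2)),
                  ratio = 0.80, perims = params$atrium_perims,
                  phase = 0.3, fg = 0.65),
    ventricle = list(center = c(x = round(0.70 * w), y = round(h / 2)),
                     ratio = 0.75, perims = params$ventricle_perims,
                     phase = 0.3 + params$phase_offset, fg = 0.85)
  )
  mid <- floor((geo$atrium$center[["x"]] + geo$ventricle$center[["x"]]) / 2)
  for (nm in names(geo)) {
    g <- geo[[nm]]
    a_max <- ellipse_axis_for_perimeter(g$perims[1], g$ratio)
    if (2 * a_max + 8 > w / 2 || 2 * a_max * g$ratio + 8 > h)
      stop("chamber too large for frame_size; enlarge the frame or shrink perimeters")
    margin <- ceiling(a_max) + 4
    x0 <- max(0, g$center[["x"]] - margin); x1 <- min(w, g$center[["x"]] + margin)
    if (nm == "atrium") x1 <- min(x1, mid) else x0 <- max(x0, mid)
    y0 <- max(0, g$center[["y"]] - margin); y1 <- min(h, g$center[["y"]] + margin)
    geo[[nm]]$a_max <- a_max
    geo[[nm]]$roi <- as_roi(c(x0, y0, x1, y1), dim = c(h, w))
  }
  xs <- range(geo$atrium$roi[c("x0", "x1")], geo$ventricle$roi[c("x0", "x1")])
  ys <- range(geo$atrium$roi[c("y0", "y1")], geo$ventricle$roi[c("y0", "y1")])
  geo$heart_roi <- as_roi(c(xs[1], ys[1], xs[2], ys[2]), dim = c(h, w))
  geo
}

# Anti-aliased ellipse coverage on a pixel grid; the half-max level set is
# exactly the ellipse with semi-axes (a, b), so thresholding at half maximum
# recovers the analytic outline.
render_ellipse_cov <- function(X, Y, cx, cy, a, b, edge = 1.5) {
  e <- sqrt(((X - cx) / a)^2 + ((Y - cy) / b)^2)
  cov <- 0.5 - (e - 1) * b / edge
  clamp(cov, 0, 1)
}

#' Simulate a brightfield video of a beating two-chambered heart
#'
#' @param params A [heart_sim_params()] object.
#' @return A list with `stack` (a [frame_stack()]) and `truth`, a record of
#'   the generating parameters: true bpm, per-chamber diastolic/systolic
#'   perimeters and ROIs, and the whole-heart ROI used for intensity traces.
#' @export
simulate_heart_video <- function(params) {
  stopifnot(inherits(params, "heart_sim_params"))
  h <- params$frame_size[1]; w <- params$frame_size[2]
  nf <- round(params$duration * params$fps)
  geo <- heart_geometry(params)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  bg <- 0.15
  f_beat <- params$bpm_true / 60
  tt <- (seq_len(nf) - 1) / params$fps

  frames <- array(bg, dim = c(h, w, nf))
  for (k in seq_len(nf)) {
    frame <- matrix(bg, h, w)
    for (nm in c("atrium", "ventricle")) {
      g <- geo[[nm]]
      # perimeter oscillates Cs..Cd; cos term = 1 at diastole
      P <- g$perims[2] + (g$perims[1] - g$perims[2]) *
        (1 + cos(2 * pi * (f_beat * tt[k] - g$phase))) / 2
      a <- ellipse_axis_for_perimeter(P, g$ratio)
      cov <- render_ellipse_cov(X, Y, g$center[["x"]], g$center[["y"]], a, a * g$ratio)
      frame <- frame + (g$fg - bg) * cov
    }
    frames[, , k] <- frame
  }
  if (params$noise_sd > 0) {
    frames <- frames + with_rng(params$seed,
      array(stats::rnorm(length(frames), sd = params$noise_sd), dim = dim(frames)))
  }
  truth <- list(
    bpm_true = params$bpm_true, fps = params$fps, duration = params$duration,
    n_frames = nf, noise_sd = params$noise_sd, seed = params$seed,
    heart_roi = geo$heart_roi,
    chambers = list(
      atrium = list(Cd = params$atrium_perims[1], Cs = params$atrium_perims[2],
                    contraction_pct = 100 * diff(rev(params$atrium_perims)) / params$atrium_perims[1],
                    roi = geo$atrium$roi),
      ventricle = list(Cd = params$ventricle_perims[1], Cs = params$ventricle_perims[2],
                       contraction_pct = 100 * diff(rev(params$ventricle_perims)) / params$ventricle_perims[1],
                       roi = geo$ventricle$roi)
    )
  )
  list(stack = frame_stack(frames, fps = params$fps), truth = truth)
}

#' Parameters for the synthetic swim-trajectory generator
#'
#' @param n_larvae Number of larvae.
#' @param duration Recording length in seconds.
#' @param fps Sampling rate of the trajectory, frames per second.
#' @param target_distance Path length each larva must travel, in cm; scalar
#'   (recycled) or one value per larva.
#' @param arena_diameter Dish diameter in mm (a 50 mm Petri dish by default).
#' @param seed RNG seed.
#' @return A validated `swim_sim_params` list.
#' @export
swim_sim_params <- function(n_larvae = 20, duration = 600, fps = 60,
                            target_distance = 2.5, arena_diameter = 50,
                            seed = 1) {
  stopifnot(n_larvae >= 1, duration > 0, fps > 0, arena_diameter > 0,
            all(target_distance >= 0))
  target_distance <- rep_len(target_distance, n_larvae)
  structure(list(n_larvae = as.integer(n_larvae), duration = duration,
                 fps = fps, target_distance = target_distance,
                 arena_diameter = arena_diameter, seed = seed),
            class = "swim_sim_params")
}

# One correlated random walk confined to a disc. Step lengths are a
# burst/glide mixture rescaled so their sum equals target_mm exactly;
# confinement flips the heading (or aims at the centre) without altering any
# step length, so the polyline length equals target_mm to machine precision.
simulate_one_trajectory <- function(n_steps, target_mm, radius_mm) {
  tiny <- 1e-12
  if (target_mm <= tiny) {
    return(cbind(x = rep(0, n_steps + 1), y = rep(0, n_steps + 1)))
  }
  burst <- stats::runif(n_steps) < 0.2
  len <- ifelse(burst, stats::rexp(n_steps, rate = 1 / 3), stats::rexp(n_steps, rate = 2))
  len <- len * (target_mm / sum(len))
  if (max(len) > radius_mm)
    stop("target_distance unreachable inside the arena at this step count")
  theta <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(n_steps - 1, sd = 0.6)))
  x <- y <- numeric(n_steps + 1)
  for (k in seq_len(n_steps)) {
    nx <- x[k] + len[k] * cos(theta[k]); ny <- y[k] + len[k] * sin(theta[k])
    if (nx^2 + ny^2 > radius_mm^2) {
      theta[k:n_steps] <- theta[k:n_steps] + pi
      nx <- x[k] + len[k] * cos(theta[k]); ny <- y[k] + len[k] * sin(theta[k])
      if (nx^2 + ny^2 > radius_mm^2) {
        phi <- atan2(-y[k], -x[k])
        d <- theta[k] - phi
        theta[k:n_steps] <- theta[k:n_steps] - d
        nx <- x[k] + len[k] * cos(phi); ny <- y[k] + len[k] * sin(phi)
      }
    }
    x[k + 1] <- nx; y[k + 1] <- ny
  }
  cbind(x = x, y = y)
}

#' Simulate larval swim trajectories with exact path lengths
#'
#' Correlated random walks with a burst/glide step-length mixture, confined
#' to the arena and rescaled so each trajectory's polyline length equals its
#' target distance to within floating-point precision.
#'
#' @param params A [swim_sim_params()] object.
#' @return A list with `trajectories` (a list of [trajectory()] data frames,
#'   coordinates in mm) and `truth` (per-larva target distances in cm and
#'   the displacement bin they fall in).
#' @export
simulate_trajectories <- function(params) {
  stopifnot(inherits(params, "swim_sim_params"))
  n_steps <- max(1L, round(params$duration * params$fps))
  radius <- params$arena_diameter / 2 - 1  # 1 mm wall margin
  t_s <- (0:n_steps) / params$fps
  trajs <- with_rng(params$seed, lapply(seq_len(params$n_larvae), function(i) {
    xy <- simulate_one_trajectory(n_steps, params$target_distance[i] * 10, radius)
    trajectory(t_s, xy[, "x"], xy[, "y"], unit = "mm",
               larva_id = sprintf("larva_%03d", i))
  }))
  truth <- data.frame(
    larva_id = sprintf("larva_%03d", seq_len(params$n_larvae)),
    target_distance_cm = params$target_distance,
    bin = bin_displacement(params$target_distance),
    stringsAsFactors = FALSE
  )
  list(trajectories = trajs, truth = truth)
}

#' Simulate a polarized-light birefringence image of the trunk musculature
#'
#' A bright striated band (alternating stripe intensities, emulating
#' sarcomeric birefringence) on a dark background. A contiguous lesioned
#' patch covering `lesion_fraction` of the trunk has its intensity
#' multiplied by `attenuation`, emulating myofibril disorganization. The
#' lesion width is snapped to a whole number of stripe periods so the ground
#' truth mean is analytic and exact.
#'
#' @param lesion_fraction Fraction of the trunk that is lesioned, in `[0, 1]`.
#' @param stripe_period Stripe period in px (even; half bright, half dim).
#' @param intensity_hi,intensity_lo Gray levels of the two stripe phases.
#' @param attenuation Multiplicative intensity factor inside the lesion.
#' @param noise_sd Additive Gaussian noise sd; 0 disables noise.
#' @param size Image dimensions `c(height, width)`.
#' @param seed RNG seed (noise and lesion placement).
#' @return A list with `image` (numeric matrix), and `truth` carrying the
#'   analytic trunk mean, the background level, the realized lesion
#'   fraction, and the trunk and background ROIs.
#' @export
simulate_birefringence_image <- function(lesion_fraction, stripe_period = 10,
                                         intensity_hi = 0.9, intensity_lo = 0.35,
                                         attenuation = 0.5, noise_sd = 0,
                                         size = c(100, 240), seed = 1) {
  stopifnot(lesion_fraction >= 0, lesion_fraction <= 1,
            stripe_period >= 2, stripe_period %% 2 == 0,
            intensity_hi > intensity_lo, intensity_lo >= 0,
            attenuation >= 0, attenuation <= 1, noise_sd >= 0)
  h <- size[1]; w <- size[2]
  background <- 0.05
  trunk_rows <- round(0.35 * h):round(0.65 * h)
  n_cols <- (w - 40) - ((w - 40) %% stripe_period)  # whole periods only
  trunk_cols <- 20 + seq_len(n_cols)
  img <- matrix(background, h, w)
  phase <- ((trunk_cols - trunk_cols[1]) %% stripe_period) < stripe_period / 2
  stripe <- ifelse(phase, intensity_hi, intensity_lo)
  trunk <- matrix(stripe, nrow = length(trunk_rows), ncol = n_cols, byrow = TRUE)

  n_periods <- n_cols / stripe_period
  lesion_periods <- round(lesion_fraction * n_periods)
  f_eff <- lesion_periods / n_periods
  if (lesion_periods > 0) {
    start <- with_rng(seed, sample.int(n_periods - lesion_periods + 1, 1))
    cols <- ((start - 1) * stripe_period + 1):((start - 1 + lesion_periods) * stripe_period)
    trunk[, cols] <- trunk[, cols] * attenuation
  }
  img[trunk_rows, trunk_cols] <- trunk
  if (noise_sd > 0)
    img <- img + with_rng(seed + 1, matrix(stats::rnorm(h * w, sd = noise_sd), h, w))

  stripe_mean <- (intensity_hi + intensity_lo) / 2
  truth <- list(
    trunk_mean = stripe_mean * ((1 - f_eff) + f_eff * attenuation),
    background_mean = background,
    lesion_fraction = f_eff, attenuation = attenuation,
    trunk_roi = as_roi(c(trunk_cols[1] - 1, trunk_rows[1] - 1,
                         trunk_cols[length(trunk_cols)], trunk_rows[length(trunk_rows)]),
                       dim = c(h, w)),
    background_roi = as_roi(c(0, 0, w, round(0.15 * h)), dim = c(h, w))
  )
  list(image = img, truth = truth)
}

#' Parameters for the synthetic dose-mortality generator
#'
#' @param concentrations Tested concentrations in uM (positive, distinct).
#' @param n_per_dose Larvae exposed per dose (20 per well by default,
#'   matching the assay this emulates).
#' @param beta0,beta1 Intercept and slope of the mortality logit on log10
#'   concentration; the true LC50 is `10^(-beta0/beta1)`.
#' @param seed RNG seed.
#' @return A validated `mortality_sim_params` list.
#' @export
mortality_sim_params <- function(concentrations, n_per_dose = 20,
                                 beta0, beta1, seed = 1) {
  stopifnot(all(concentrations > 0), !anyDuplicated(concentrations),
            n_per_dose >= 1, is.finite(beta0), is.finite(beta1))
  structure(list(concentrations = concentrations,
                 n_per_dose = as.integer(n_per_dose),
                 beta0 = beta0, beta1 = beta1, seed = seed),
            class = "mortality_sim_params")
}

#' Simulate a binomial dose-mortality table
#'
#' Deaths at each dose are `Binomial(n_per_dose, p)` with
#' `logit(p) = beta0 + beta1 * log10(concentration)`.
#'
#' @param params A [mortality_sim_params()] object.
#' @return A list with `data` (a dose-mortality data frame with columns
#'   `concentration_uM`, `n_exposed`, `n_dead`) and `truth` (true LC50 in
#'   uM and the per-dose death probabilities).
#' @export
simulate_mortality <- function(params) {
  stopifnot(inherits(params, "mortality_sim_params"))
  p <- stats::plogis(params$beta0 + params$beta1 * log10(params$concentrations))
  dead <- with_rng(params$seed,
                   stats::rbinom(length(p), params$n_per_dose, p))
  list(
    data = data.frame(concentration_uM = params$concentrations,
                      n_exposed = params$n_per_dose, n_dead = dead),
    truth = list(lc50 = 10^(-params$beta0 / params$beta1),
                 beta0 = params$beta0, beta1 = params$beta1, p = p)
  )
}

#' Parameters for the synthetic qPCR Ct generator
#'
#' @param quantities Template amounts per sample (arbitrary copies, > 0).
#' @param efficiency_true Amplification efficiency in `(0, 1]` (1 = perfect
#'   doubling per cycle).
#' @param ct_at_unit Ct for one unit of template.
#' @param noise_sd Gaussian Ct noise sd.
#' @param seed RNG seed.
#' @return A validated `qpcr_sim_params` list.
#' @export
qpcr_sim_params <- function(quantities, efficiency_true = 0.95,
                            ct_at_unit = 35, noise_sd = 0, seed = 1) {
  stopifnot(all(quantities > 0), efficiency_true > 0, efficiency_true <= 1,
            is.finite(ct_at_unit), noise_sd >= 0)
  structure(list(quantities = quantities, efficiency_true = efficiency_true,
                 ct_at_unit = ct_at_unit, noise_sd = noise_sd, seed = seed),
            class = "qpcr_sim_params")
}

#' Simulate a qPCR Ct table
#'
#' `Ct = ct_at_unit - log(quantity, base = 1 + efficiency) + noise`: each
#' (1+E)-fold increase in template advances detection by one cycle.
#'
#' @param params A [qpcr_sim_params()] object.
#' @return A list with `data` (columns `sample`, `quantity_true`, `ct`) and
#'   `truth` (the generating parameters).
#' @export
simulate_ct_table <- function(params) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  q <- params$quantities
  ct <- params$ct_at_unit - log(q) / log(1 + params$efficiency_true)
  if (params$noise_sd > 0)
    ct <- ct + with_rng(params$seed, stats::rnorm(length(q), sd = params$noise_sd))
  nm <- names(q) %||% sprintf("sample_%02d", seq_along(q))
  list(
    data = data.frame(sample = nm, quantity_true = as.numeric(q), ct = ct,
                      stringsAsFactors = FALSE),
    truth = list(efficiency_true = params$efficiency_true,
                 ct_at_unit = params$ct_at_unit, noise_sd = params$noise_sd)
  )
}

#' Simulate a touch-evoked response assay with known classes
#'
#' Draws a post-stimulus travel distance and an undulation flag consistent
#' with each intended response class, so the classifier can be checked
#' against exact ground truth.
#'
#' @param classes Character vector of intended classes, drawn from
#'   `no_response`, `response_without_escaping`, `short_distance`,
#'   `long_distance`; one element per larva.
#' @param seed RNG seed.
#' @return A data frame with `larva_id`, `class_true`, `distance_mm`,
#'   `undulation`.
#' @export
simulate_touch_assay <- function(classes, seed = 1) {
  lv <- touch_response_levels()
  stopifnot(all(classes %in% lv))
  n <- length(classes)
  with_rng(seed, {
    distance <- numeric(n)
    distance[classes == "short_distance"] <-
      stats::runif(sum(classes == "short_distance"), 2, 20)
    distance[classes == "long_distance"] <-
      stats::runif(sum(classes == "long_distance"), 20.5, 60)
    undulation <- classes != "no_response"
    data.frame(larva_id = sprintf("larva_%03d", seq_len(n)),
               class_true = factor(classes, levels = lv),
               distance_mm = distance, undulation = undulation,
               stringsAsFactors = FALSE)
  })
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth A ground-truth list as returned in the `truth` element of
#'   the generators.
#' @param path Output path (conventionally `<artifact>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
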