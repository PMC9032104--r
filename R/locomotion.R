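# Locomotion scoring: spontaneous displacement (distance binning) and
# touch-evoked response classification, plus simple centroid tracking.

#' Construct a larval trajectory
#'
#' @param t Time stamps in seconds, strictly increasing.
#' @param x,y Positions, same length as `t`.
#' @param unit Length unit of `x`/`y` (`"mm"` or `"cm"`).
#' @param larva_id,group Optional identifiers.
#' @return A `trajectory` data frame with columns `t_s`, `x`, `y` and
#'   attributes `unit`, `larva_id`, `group`.
#' @export
trajectory <- function(t, x, y, unit = c("mm", "cm"), larva_id = NA_character_,
                       group = NA_character_) {
  unit <- match.arg(unit)
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(data.frame(t_s = t, x = x, y = y),
            unit = unit, larva_id = larva_id, group = group,
            class = c("trajectory", "data.frame"))
}

traj_unit <- function(traj) attr(traj, "unit") %||% "mm"

#' Total path length of a trajectory
#'
#' Sum of Euclidean segment lengths between consecutive samples; invariant
#' under rigid rotation and translation of the coordinates.
#'
#' @param traj A [trajectory()] (or any data frame with `x`, `y` columns).
#' @param unit Output unit, `"same"` (trajectory unit), `"mm"` or `"cm"`.
#' @return Path length as a scalar.
#' @export
path_length <- function(traj, unit = c("same", "mm", "cm")) {
  unit <- match.arg(unit)
  if (nrow(traj) < 2) stop("path_length needs at least 2 points")
  d <- sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
  from <- traj_unit(traj)
  if (unit == "same" || unit == from) return(d)
  if (from == "mm" && unit == "cm") d / 10 else d * 10
}

displacement_levels <- function()
  c("no_movement", "d_0p5_to_1p5", "d_1p5_to_3", "d_gt_3")

#' Bin travelled distances into the four spontaneous-activity ranges
#'
#' Categories: no movement (up to 0.5 cm), 0.5-1.5 cm, 1.5-3 cm, and more
#' than 3 cm. Boundaries follow the wording of the ranges: `[0, 0.5]`,
#' `(0.5, 1.5]`, `(1.5, 3]`, `(3, Inf)`, so every distance falls in exactly
#' one bin.
#'
#' @param distance_cm Distance(s) travelled in cm, non-negative.
#' @return Factor with levels `no_movement`, `d_0p5_to_1p5`, `d_1p5_to_3`,
#'   `d_gt_3`.
#' @export
bin_displacement <- function(distance_cm) {
  if (any(distance_cm < 0)) stop("distances must be non-negative")
  cut(distance_cm, breaks = c(-Inf, 0.5, 1.5, 3, Inf),
      labels = displacement_levels(), right = TRUE)
}

#' Percentage of larvae per displacement bin, by treatment group
#'
#' @param distances Data frame with columns `group` and `distance_cm` (or a
#'   precomputed factor column `bin`).
#' @return Data frame `group`, `bin`, `n`, `percent`; percentages within a
#'   group sum to 100.
#' @export
group_bin_percentages <- function(distances) {
  d <- as.data.frame(distances)
  stopifnot("group" %in% names(d))
  if (!"bin" %in% names(d)) {
    stopifnot("distance_cm" %in% names(d))
    d$bin <- bin_displacement(d$distance_cm)
  }
  if (any(table(d$group) == 0) || nrow(d) == 0) stop("every group needs at least one larva")
  tab <- table(group = d$group, bin = d$bin)
  out <- as.data.frame(tab, responseName = "n")
  totals <- stats::ave(out$n, out$group, FUN = sum)
  if (any(totals == 0)) stop("empty group in distance table")
  out$percent <- 100 * out$n / totals
  out[order(out$group, out$bin), , drop = FALSE]
}

touch_response_levels <- function()
  c("no_response", "response_without_escaping", "short_distance", "long_distance")

#' Classify a touch-evoked response
#'
#' Classes, from weakest to strongest: `no_response` (no displacement above
#' the jitter floor and no tail undulation), `response_without_escaping`
#' (lateral tail undulation without escape), `short_distance` (escape of no
#' more than 20 mm) and `long_distance` (more than 20 mm).
#'
#' @param distance_mm Post-stimulus distance travelled in mm, or `NULL` if
#'   `traj` is given.
#' @param undulation Logical: was a tail undulation detected? May be `NA`
#'   when the distance exceeds the jitter floor.
#' @param traj Optional [trajectory()] covering the post-stimulus window;
#'   its path length within `window_s` is used as the distance.
#' @param epsilon_mm Jitter floor separating "no displacement" from tracking
#'   noise (default 1 mm).
#' @param window_s Post-stimulus analysis window in seconds (default 5 s).
#' @return Factor of length 1 with the four response levels.
#' @export
classify_touch_response <- function(distance_mm = NULL, undulation = NA,
                                    traj = NULL, epsilon_mm = 1, window_s = 5) {
  if (is.null(distance_mm)) {
    stopifnot(!is.null(traj))
    sub <- traj[traj$t_s <= traj$t_s[1] + window_s, , drop = FALSE]
    distance_mm <- path_length(sub, unit = "mm")
  }
  stopifnot(distance_mm >= 0)
  lv <- touch_response_levels()
  cls <- if (distance_mm > 20) {
    "long_distance"
  } else if (distance_mm > epsilon_mm) {
    "short_distance"
  } else if (isTRUE(undulation)) {
    "response_without_escaping"
  } else {
    if (is.na(undulation))
      warning("undulation signal missing with sub-threshold displacement; resolving as no_response")
    "no_response"
  }
  factor(cls, levels = lv)
}

#' Percentage of larvae per touch-response class, by group and stimulus
#'
#' @param responses Data frame with columns `group`, `class` (factor with
#'   the four response levels) and optionally `stimulus`.
#' @return Data frame of counts and within-group percentages.
#' @export
group_touch_percentages <- function(responses) {
  d <- as.data.frame(responses)
  stopifnot(all(c("group", "class") %in% names(d)))
  d$class <- factor(d$class, levels = touch_response_levels())
  tab <- table(group = d$group, class = d$class)
  out <- as.data.frame(tab, responseName = "n")
  totals <- stats::ave(out$n, out$group, FUN = sum)
  if (any(totals == 0)) stop("empty group in response table")
  out$percent <- 100 * out$n / totals
  out[order(out$group, out$class), , drop = FALSE]
}

#' Track the centroid of a single larva through a video
#'
#' Background subtraction, thresholding, and per-frame centroid of the
#' largest foreground blob. Frames without any blob are linearly
#' interpolated from the neighbours (and reported); recordings with more
#' than `max_missing` of frames missing are rejected.
#'
#' @param stack A [frame_stack()] (pixel_size, if set, is used to convert
#'   to mm; otherwise coordinates are in px and the unit is marked mm
#'   with a warning).
#' @param background Background model: a matrix (same size as a frame) or
#'   `"median"` to use the per-pixel median frame.
#' @param threshold Foreground threshold on |frame - background|; `NULL`
#'   uses half the maximum absolute deviation.
#' @param max_missing Maximum tolerated fraction of blob-less frames.
#' @return A [trajectory()]; attribute `n_interpolated` counts filled gaps.
#' @export
track_centroid <- function(stack, background = "median", threshold = NULL,
                           max_missing = 0.2) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  bg <- if (is.matrix(background)) background
        else apply(stack$frames, c(1, 2), stats::median)
  dev_max <- max(abs(stack$frames - as.vector(bg)))
  if (is.null(threshold)) threshold <- dev_max / 2
  xs <- ys <- rep(NA_real_, nf)
  for (k in seq_len(nf)) {
    fg <- abs(stack$frames[, , k] - bg) >= threshold
    if (!any(fg)) next
    labels <- EBImage::bwlabel(fg)
    sizes <- tabulate(labels[labels > 0])
    blob <- labels == which.max(sizes)
    idx <- which(blob, arr.ind = TRUE)
    ys[k] <- mean(idx[, 1]); xs[k] <- mean(idx[, 2])
  }
  n_missing <- sum(is.na(xs))
  if (n_missing / nf > max_missing)
    stop(sprintf("%.0f%% of frames have no detectable larva (limit %.0f%%)",
                 100 * n_missing / nf, 100 * max_missing))
  tt <- (seq_len(nf) - 1) / stack$fps
  if (n_missing > 0) {
    xs <- stats::approx(tt[!is.na(xs)], xs[!is.na(xs)], xout = tt, rule = 2)$y
    ys <- stats::approx(tt[!is.na(ys)], ys[!is.na(ys)], xout = tt, rule = 2)$y
  }
  scale <- stack$pixel_size
  if (is.null(scale)) {
    warning("pixel_size not set; trajectory coordinates are in px, labelled mm")
    scale <- 1
  }
  out <- trajectory(tt, xs * scale, ys * scale, unit = "mm")
  attr(out, "n_interpolated") <- n_missing
  out
}

#' Read trajectories from a CSV file
#'
#' Expected header: `larva_id, group, t_s, x_mm, y_mm`.
#'
#' @param path CSV path.
#' @return Named list of [trajectory()] objects, one per larva.
#' @export
read_trajectories_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "group", "t_s", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$larva_id), function(s)
    trajectory(s$t_s, s$x_mm, s$y_mm, unit = "mm",
               larva_id = s$larva_id[1], group = s$group[1]))
  out[order(names(out))]
}

#' Write trajectories to a CSV file
#'
#' @param trajs List of [trajectory()] objects (coordinates in mm).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    stopifnot(traj_unit(tr) == "mm")
    data.frame(larva_id = attr(tr, "larva_id") %||% NA_character_,
               group = attr(tr, "group") %||% NA_character_,
               t_s = tr$t_s, x_mm = tr$x, y_mm = tr$y,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
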