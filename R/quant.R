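# Dose-response LC50 estimation and qPCR standard-curve quantification.

#' Fit an LC50 by regressing empirical logits on log10 concentration
#'
#' The headline estimate mirrors the classical graphical method: ordinary
#' least squares of the empirical mortality logits on log10 concentration,
#' with an Anscombe-type continuity correction `p' = (d + 0.5)/(n + 1)`
#' applied only at boundary doses (0% or 100% mortality), where the raw
#' logit is infinite. The LC50 is the concentration at logit 0,
#' `10^(-beta0/beta1)`. A maximum-likelihood logistic (binomial GLM) fit is
#' reported alongside for comparison.
#'
#' @param data Dose-mortality data frame with columns `concentration_uM`,
#'   `n_exposed`, `n_dead` (fractional expected counts are accepted, which
#'   makes noiseless input exactly recoverable).
#' @return An `lc50_fit`: `beta0`, `beta1`, `lc50`, `correction`, plus
#'   `ml` (the GLM coefficients and its LC50).
#' @export
fit_lc50 <- function(data) {
  d <- as.data.frame(data)
  stopifnot(all(c("concentration_uM", "n_exposed", "n_dead") %in% names(d)))
  if (any(d$concentration_uM <= 0)) stop("concentrations must be positive")
  if (any(d$n_dead < 0 | d$n_dead > d$n_exposed))
    stop("n_dead must lie in [0, n_exposed]")
  if (length(unique(d$concentration_uM)) < 3)
    stop("need at least 3 distinct concentrations")
  p <- d$n_dead / d$n_exposed
  boundary <- p == 0 | p == 1
  p[boundary] <- (d$n_dead[boundary] + 0.5) / (d$n_exposed[boundary] + 1)
  if (stats::var(p) == 0)
    stop("mortality does not vary across doses; slope unidentifiable")
  logit <- log(p / (1 - p))
  lx <- log10(d$concentration_uM)
  fit <- stats::lm(logit ~ lx)
  beta0 <- unname(stats::coef(fit)[1]); beta1 <- unname(stats::coef(fit)[2])
  if (beta1 <= 0)
    warning("negative mortality slope: the compound looks protective, not toxic")
  ml <- tryCatch({
    g <- stats::glm(cbind(n_dead, n_exposed - n_dead) ~ lx, data = d,
                    family = stats::binomial())
    cf <- unname(stats::coef(g))
    list(beta0 = cf[1], beta1 = cf[2], lc50 = 10^(-cf[1] / cf[2]))
  }, error = function(e) NULL, warning = function(w) {
    g <- suppressWarnings(stats::glm(cbind(n_dead, n_exposed - n_dead) ~ lx,
                                     data = d, family = stats::binomial()))
    cf <- unname(stats::coef(g))
    list(beta0 = cf[1], beta1 = cf[2], lc50 = 10^(-cf[1] / cf[2]))
  })
  structure(list(beta0 = beta0, beta1 = beta1, lc50 = 10^(-beta0 / beta1),
                 correction = "boundary doses: p' = (d + 0.5)/(n + 1)",
                 r_squared = suppressWarnings(summary(fit)$r.squared), ml = ml),
            class = "lc50_fit")
}

#' @export
print.lc50_fit <- function(x, ...) {
  cat(sprintf("<lc50_fit> LC50 = %.4g uM (empirical logit: b0 = %.4g, b1 = %.4g, R^2 = %.4f)\n",
              x$lc50, x$beta0, x$beta1, x$r_squared))
  if (!is.null(x$ml))
    cat(sprintf("           ML logistic comparison: LC50 = %.4g uM\n", x$ml$lc50))
  invisible(x)
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Least-squares line of Ct on log10 relative quantity. The amplification
#' efficiency is `10^(-1/slope) - 1` (a slope of -3.3219 = -1/log10(2) is
#' perfect doubling, efficiency 100%). Ct replicates at the same quantity
#' are averaged before fitting; their SD is carried as metadata.
#'
#' @param ct_by_dilution Data frame with columns `quantity` (relative
#'   template amount, > 0) and `ct`.
#' @return A `standard_curve`: `slope`, `intercept` (Ct at unit quantity),
#'   `efficiency`, `r_squared`, `replicate_sd`.
#' @export
fit_standard_curve <- function(ct_by_dilution) {
  d <- as.data.frame(ct_by_dilution)
  stopifnot(all(c("quantity", "ct") %in% names(d)))
  if (any(d$quantity <= 0)) stop("quantities must be positive")
  rep_sd <- vapply(split(d$ct, d$quantity), stats::sd, numeric(1))
  agg <- vapply(split(d$ct, d$quantity), mean, numeric(1))
  q <- as.numeric(names(agg))
  if (length(q) < 3) stop("need at least 3 distinct dilution points")
  fit <- stats::lm(agg ~ log10(q))
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop("standard curve slope must be negative (Ct falls as template rises)")
  eff <- 10^(-1 / slope) - 1
  if (eff > 1.1)
    warning(sprintf("efficiency %.3f exceeds 110%%: check the dilution series", eff))
  structure(list(slope = slope, intercept = intercept, efficiency = eff,
                 r_squared = suppressWarnings(summary(fit)$r.squared), replicate_sd = rep_sd),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.3f, efficiency %.1f%%, R^2 = %.4f\n",
              x$slope, x$intercept, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Absolute quantity of a sample from its Ct and a standard curve
#'
#' Inverts the curve: `quantity = 10^((ct - intercept)/slope)`.
#'
#' @param ct Observed Ct value(s), finite.
#' @param curve A [fit_standard_curve()] result.
#' @return Quantity in the curve's (relative) units.
#' @export
quantify_sample <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"), all(is.finite(ct)))
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalize a target-gene quantity to the reference gene and scale to A.U.
#'
#' `normalized = target/reference`; `au = normalized/reference_group_value`,
#' so the designated reference group sits at exactly 1 arbitrary unit.
#'
#' @param target_q Target-gene quantity (e.g. atrogin-1 molecules), > 0.
#' @param reference_q Reference-gene quantity (e.g. rpl13a), > 0.
#' @param reference_group_value The normalized value of the designated
#'   reference group, > 0.
#' @return An `expression_result`: `target_quantity`, `reference_quantity`,
#'   `normalized`, `au`.
#' @export
normalize_expression <- function(target_q, reference_q, reference_group_value) {
  if (any(reference_q <= 0) || any(reference_group_value <= 0))
    stop("reference quantities must be positive")
  if (any(target_q <= 0)) stop("target quantities must be positive")
  normalized <- target_q / reference_q
  structure(list(target_quantity = target_q, reference_quantity = reference_q,
                 normalized = normalized,
                 au = normalized / reference_group_value),
            class = "expression_result")
}
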