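# Figures and significance tables from a results bundle.

utils::globalVariables(c("group", "mean", "sd", "percent", "bin", "class",
                         "group_a", "group_b", "label"))

bar_mean_sd_plot <- function(summary_df, title, ylab) {
  summary_df$group <- factor(summary_df$group, levels = unique(summary_df$group))
  ggplot2::ggplot(summary_df, ggplot2::aes(x = group, y = mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0.3) +
    ggplot2::labs(title = title, x = NULL, y = ylab) +
    ggplot2::theme_classic()
}

stacked_percentage_plot <- function(pct_df, fill_col, title) {
  pct_df$group <- factor(pct_df$group, levels = unique(pct_df$group))
  ggplot2::ggplot(pct_df, ggplot2::aes(x = group, y = percent,
                                       fill = .data[[fill_col]])) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(title = title, x = NULL, y = "% of larvae", fill = NULL) +
    ggplot2::theme_classic()
}

#' Pairwise significance table with asterisks
#'
#' One row per comparison; `label` is `"*"` exactly when `p_value < alpha`.
#'
#' @param pairwise A pairwise result data frame (from [games_howell()],
#'   [pairwise_mann_whitney()] or the qPCR t-tests).
#' @param alpha Significance level (defaults to the table's own).
#' @return Data frame `group_a`, `group_b`, `p_value`, `label`.
#' @export
significance_table <- function(pairwise, alpha = NULL) {
  alpha <- alpha %||% attr(pairwise, "alpha") %||% 0.05
  data.frame(group_a = pairwise$group_a, group_b = pairwise$group_b,
             p_value = pairwise$p_value,
             label = ifelse(!is.na(pairwise$p_value) & pairwise$p_value < alpha,
                            "*", ""),
             stringsAsFactors = FALSE)
}

#' Build figures and significance tables from a results bundle
#'
#' Bar charts with SD error bars for every scalar measure, stacked
#' percentage bars for displacement bins and touch-response classes, the
#' LC50 logit regression line over the empirical logits, and a pairwise
#' significance table per measure. Missing measures are skipped with a
#' warning.
#'
#' @param results A [run_experiment()] bundle.
#' @param out_dir Optional directory; figures are saved as PNG and tables
#'   as CSV when given.
#' @return List with `figures` (ggplot objects) and `tables` (significance
#'   data frames), named by measure.
#' @export
make_report <- function(results, out_dir = NULL) {
  figs <- list(); tabs <- list()
  units <- c(birefringence = "birefringence score (a.u.)",
             heart_rate = "heart rate (bpm)",
             atrial_contraction = "atrial contraction (%)",
             ventricular_contraction = "ventricular contraction (%)",
             displacement = "distance travelled (cm)",
             atrogin1_au = "atrogin-1 expression (A.U.)")
  # group order in every figure follows the config, not alphabetical order
  order_groups <- function(df) {
    lv <- intersect(results$config$groups$name, unique(as.character(df$group)))
    df <- df[order(match(as.character(df$group), lv)), , drop = FALSE]
    df$group <- factor(as.character(df$group), levels = lv)
    df
  }
  for (nm in names(units)) {
    if (is.null(results$summaries[[nm]])) {
      warning("measure '", nm, "' missing from results; figure skipped")
      next
    }
    figs[[nm]] <- bar_mean_sd_plot(order_groups(results$summaries[[nm]]),
                                   nm, units[[nm]])
  }
  if (!is.null(results$percentages$displacement))
    figs$displacement_bins <- stacked_percentage_plot(
      order_groups(results$percentages$displacement), "bin",
      "spontaneous displacement")
  if (!is.null(results$percentages$touch))
    figs$touch_classes <- stacked_percentage_plot(
      order_groups(results$percentages$touch), "class",
      "touch-evoked response")
  if (!is.null(results$lc50)) {
    d <- results$lc50$data
    p <- d$n_dead / d$n_exposed
    b <- p == 0 | p == 1
    p[b] <- (d$n_dead[b] + 0.5) / (d$n_exposed[b] + 1)
    ld <- data.frame(logc = log10(d$concentration_uM), logit = log(p / (1 - p)))
    fit <- results$lc50$fit
    figs$lc50 <- ggplot2::ggplot(ld, ggplot2::aes(x = logc, y = logit)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(intercept = fit$beta0, slope = fit$beta1) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(title = sprintf("LC50 = %.3g uM", fit$lc50),
                    x = "log10 concentration (uM)", y = "logit mortality") +
      ggplot2::theme_classic()
  }
  for (nm in names(results$stats)) {
    pw <- results$stats[[nm]]$pairwise
    if (!is.null(pw)) tabs[[nm]] <- significance_table(pw)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(figs))
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), figs[[nm]],
                      width = 6, height = 4, dpi = 150)
    for (nm in names(tabs))
      utils::write.csv(tabs[[nm]],
                       file.path(out_dir, paste0("significance_", nm, ".csv")),
                       row.names = FALSE)
  }
  list(figures = figs, tables = tabs)
}
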