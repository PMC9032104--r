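# Group-comparison statistics layer: group summaries, Welch ANOVA with
# Games-Howell post-hoc, Kruskal-Wallis with pairwise Mann-Whitney, and
# Student's t-test. Standard tests call the base R implementations; the
# Games-Howell procedure (no base equivalent) is implemented here on top of
# the studentized-range distribution.

check_group_table <- function(table) {
  d <- as.data.frame(table)
  stopifnot(all(c("group", "value") %in% names(d)))
  if (any(!is.finite(d$value))) stop("all values must be finite")
  d$group <- as.character(d$group)
  d
}

#' Per-group means and standard deviations
#'
#' Sample mean and SD (n - 1 denominator) of each group; groups with fewer
#' than two values are excluded with a warning.
#'
#' @param table Data frame with columns `group` and `value`.
#' @return Data frame `group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(table) {
  d <- check_group_table(table)
  ns <- table(d$group)
  small <- names(ns)[ns < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with < 2 values: ", paste(small, collapse = ", "))
    d <- d[!d$group %in% small, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no group with at least 2 values")
  sp <- split(d$value, d$group)
  data.frame(group = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Games-Howell pairwise post-hoc test
#'
#' Pairwise comparisons robust to unequal variances and group sizes: for
#' each pair, `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized-range
#' distribution with `q = t * sqrt(2)` and `k` = total number of groups.
#' The omnibus Welch ANOVA (and, for reference, the classical one-way
#' ANOVA) is attached as an attribute.
#'
#' @param table Data frame with columns `group` and `value`; at least two
#'   groups with two values and positive variance each.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame of pairwise results: `group_a`, `group_b`,
#'   `statistic` (t), `df`, `p_value`, `significant`; attributes
#'   `welch_anova` and `classical_anova` hold the omnibus tests.
#' @export
games_howell <- function(table, alpha = 0.05) {
  d <- check_group_table(table)
  sp <- split(d$value, d$group)
  if (length(sp) < 2) stop("need at least 2 groups")
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 2)) stop("every group needs at least 2 values")
  means <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, stats::var, numeric(1))
  k <- length(sp)
  pairs <- utils::combn(names(sp), 2)
  res <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    va <- vars[[a]] / ns[[a]]; vb <- vars[[b]] / ns[[b]]
    if (vars[[a]] == 0 && vars[[b]] == 0) {
      warning(sprintf("pair %s vs %s has zero variance in both groups; no test", a, b))
      return(data.frame(group_a = a, group_b = b, statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_, significant = NA))
    }
    tstat <- (means[[a]] - means[[b]]) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ns[[a]] - 1) + vb^2 / (ns[[b]] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group_a = a, group_b = b, statistic = tstat, df = df,
               p_value = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fml <- value ~ group
  env <- list2env(list(value = d$value, group = factor(d$group)))
  environment(fml) <- env
  attr(out, "welch_anova") <- tryCatch(stats::oneway.test(fml, var.equal = FALSE),
                                       error = function(e) NULL)
  attr(out, "classical_anova") <- stats::oneway.test(fml, var.equal = TRUE)
  attr(out, "alpha") <- alpha
  out
}

#' Kruskal-Wallis rank-sum test over treatment groups
#'
#' Tie-corrected H referred to a chi-square with k - 1 degrees of freedom
#' (base [stats::kruskal.test()] under the hood). Data where all values are
#' identical yield H = 0, p = 1.
#'
#' @param table Data frame with columns `group` and `value`; at least two
#'   groups with at least one value each.
#' @return List with `statistic` (H), `df`, `p_value`, and the underlying
#'   `htest`.
#' @export
kruskal_wallis <- function(table) {
  d <- check_group_table(table)
  if (length(unique(d$group)) < 2) stop("need at least 2 groups")
  if (length(unique(d$value)) == 1)
    return(list(statistic = 0, df = length(unique(d$group)) - 1L,
                p_value = 1, htest = NULL))
  ht <- stats::kruskal.test(d$value, factor(d$group))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, htest = ht)
}

#' Pairwise Mann-Whitney (Wilcoxon rank-sum) post-hoc tests
#'
#' Two-sided tests for every pair of groups. The exact distribution is used
#' when the smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction. By default no
#' multiplicity adjustment is applied (announced loudly via a message);
#' `p_adjust = "holm"` is available.
#'
#' @param table Data frame with columns `group` and `value`.
#' @param alpha Significance level for the `significant` flag.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()];
#'   default `"none"`.
#' @return Data frame `group_a`, `group_b`, `statistic` (U), `p_value`,
#'   `significant`, `exact`.
#' @export
pairwise_mann_whitney <- function(table, alpha = 0.05, p_adjust = "none") {
  d <- check_group_table(table)
  sp <- split(d$value, d$group)
  if (length(sp) < 2) stop("need at least 2 groups")
  if (any(vapply(sp, length, integer(1)) == 0)) stop("empty group")
  if (identical(p_adjust, "none"))
    message("pairwise Mann-Whitney p-values are NOT adjusted for multiplicity (p_adjust = \"none\")")
  pairs <- utils::combn(names(sp), 2)
  res <- apply(pairs, 2, function(pr) {
    x <- sp[[pr[1]]]; y <- sp[[pr[2]]]
    use_exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = !use_exact))
    data.frame(group_a = pr[1], group_b = pr[2],
               statistic = unname(ht$statistic), p_value = ht$p.value,
               exact = use_exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  out
}

#' Two-sided pooled-variance Student's t-test
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values;
#'   the pooled variance must be positive.
#' @return List with `statistic`, `df`, `p_value`, and the underlying
#'   `htest`.
#' @export
students_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  pooled <- ((length(sample_a) - 1) * stats::var(sample_a) +
             (length(sample_b) - 1) * stats::var(sample_b)) /
            (length(sample_a) + length(sample_b) - 2)
  if (pooled == 0) stop("zero pooled variance: t statistic undefined")
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, htest = ht)
}
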