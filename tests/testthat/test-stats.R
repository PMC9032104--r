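# Statistics layer: summaries, Games-Howell, Kruskal-Wallis, Mann-Whitney,
# Student's t.

test_that("group summaries report sample mean and SD and scale linearly", {
  d <- data.frame(group = "g", value = c(2, 4, 6))
  s <- summarize_groups(d)
  expect_equal(s$mean, 4); expect_equal(s$sd, 2)
  expect_equal(summarize_groups(data.frame(group = "g", value = rep(5, 4)))$sd, 0)
  s3 <- summarize_groups(data.frame(group = "g", value = 3 * c(2, 4, 6)))
  expect_equal(s3$mean, 3 * s$mean); expect_equal(s3$sd, 3 * s$sd)
  expect_warning(summarize_groups(data.frame(group = c("a", "a", "b"),
                                             value = 1:3)), "excluding")
})

test_that("Games-Howell with two groups collapses to the Welch t-test", {
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- rnorm(sample(5:25, 1), sd = runif(1, 0.5, 3))
      b <- rnorm(sample(5:25, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
      gh <- games_howell(data.frame(group = rep(c("a", "b"), c(length(a), length(b))),
                                    value = c(a, b)))
      welch <- t.test(a, b)  # independent Welch oracle
      expect_equal(gh$p_value, welch$p.value, tolerance = 1e-6)
      expect_equal(abs(gh$statistic), abs(unname(welch$statistic)),
                   tolerance = 1e-9)
    }
  })
})

test_that("Games-Howell separates a strongly shifted group", {
  withr::with_seed(5, {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 12),
                    value = c(rnorm(12), rnorm(12), rnorm(12, mean = 10)))
  })
  gh <- games_howell(d)
  expect_true(all(gh$p_value[gh$group_a == "c" | gh$group_b == "c"] < 1e-6))
  expect_gt(gh$p_value[gh$group_a == "a" & gh$group_b == "b"], 0.05)
  expect_s3_class(attr(gh, "welch_anova"), "htest")
})

test_that("Games-Howell approaches Tukey HSD under equal variance and n", {
  # identical residuals per group so sample variances match exactly and the
  # two procedures differ only in their degrees of freedom
  resid <- withr::with_seed(77, scale(rnorm(200))[, 1])
  d <- data.frame(group = rep(c("a", "b", "c"), each = 200),
                  value = c(resid, resid + 0.11, resid + 0.25))
  gh <- games_howell(d)
  tk <- TukeyHSD(aov(value ~ group, data = d))$group
  key <- paste(gh$group_b, gh$group_a, sep = "-")
  expect_equal(gh$p_value, unname(tk[key, "p adj"]), tolerance = 1e-3)
})

test_that("zero-variance pairs are flagged, not fabricated", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                  value = c(1, 1, 1, 2, 2, 2, 1, 2, 3))
  expect_warning(gh <- games_howell(d), "zero variance")
  expect_true(is.na(gh$p_value[gh$group_a == "a" & gh$group_b == "b"]))
  expect_false(anyNA(gh$p_value[gh$group_b == "c"]))
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 2), value = 1:6)
  kw <- kruskal_wallis(d)
  # rank sums 3, 7, 11: H = 12/(6*7) * sum(R^2/n) - 3*7 = 4.5714...
  expect_equal(kw$statistic, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-9)
  # label permutation leaves H unchanged
  d2 <- d; d2$group <- rep(c("c", "a", "b"), each = 2)
  expect_equal(kruskal_wallis(d2)$statistic, kw$statistic)
  # degenerate inputs
  expect_error(kruskal_wallis(data.frame(group = "a", value = 1:4)), "2 groups")
  allsame <- kruskal_wallis(data.frame(group = rep(c("a", "b"), 3),
                                       value = rep(7, 6)))
  expect_equal(allsame$statistic, 0)
  expect_equal(allsame$p_value, 1)
})

test_that("exact Mann-Whitney equals exhaustive enumeration for small groups", {
  mw <- suppressMessages(
    pairwise_mann_whitney(data.frame(group = rep(c("x", "y"), each = 2),
                                     value = c(1, 2, 3, 4))))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)  # 2 of C(4,2)=6 splits
  withr::with_seed(13, {
    for (i in 1:12) {
      na <- sample(2:6, 1); nb <- sample(2:6, 1)
      v <- sample(1000, na + nb)  # distinct => no ties
      x <- v[seq_len(na)]; y <- v[-seq_len(na)]
      got <- suppressMessages(pairwise_mann_whitney(
        data.frame(group = rep(c("x", "y"), c(na, nb)), value = c(x, y))))
      expect_true(got$exact)
      expect_equal(got$p_value, mw_exact_oracle(x, y), tolerance = 1e-12)
    }
  })
})

test_that("tied or large samples use the corrected normal approximation", {
  d <- data.frame(group = rep(c("x", "y"), each = 4),
                  value = c(1, 2, 3, 4, 1, 2, 3, 4))
  mw <- suppressMessages(pairwise_mann_whitney(d))
  expect_false(mw$exact)
  expect_gt(mw$p_value, 0.95)  # identical samples: p ~ 1
  big <- data.frame(group = rep(c("x", "y"), each = 40),
                    value = withr::with_seed(3, c(rnorm(40), rnorm(40, 3))))
  mwb <- suppressMessages(pairwise_mann_whitney(big))
  expect_false(mwb$exact)
  expect_lt(mwb$p_value, 1e-6)
})

test_that("unadjusted pairwise p-values are announced; Holm is available", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 5),
                  value = withr::with_seed(2, rnorm(15)))
  expect_message(pairwise_mann_whitney(d), "NOT adjusted")
  raw <- suppressMessages(pairwise_mann_whitney(d))
  holm <- pairwise_mann_whitney(d, p_adjust = "holm")
  expect_equal(holm$p_value, p.adjust(raw$p_value, "holm"))
})

test_that("Student's t matches the textbook formula and handles degeneracy", {
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(students_t(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))$p_value, 1e-6)
  expect_error(students_t(c(1, 1), c(2, 2)), "zero pooled variance")
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = 0.5)
      got <- students_t(a, b)
      want <- pooled_t_oracle(a, b)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    }
  })
})

test_that("pairwise results are symmetric in group order", {
  d <- data.frame(group = rep(c("a", "b"), each = 6),
                  value = withr::with_seed(9, c(rnorm(6), rnorm(6, 2))))
  d_swapped <- d; d_swapped$group <- rep(c("b", "a"), each = 6)
  gh1 <- games_howell(d); gh2 <- games_howell(d_swapped)
  expect_equal(gh1$p_value, gh2$p_value, tolerance = 1e-12)
  mw1 <- suppressMessages(pairwise_mann_whitney(d))
  mw2 <- suppressMessages(pairwise_mann_whitney(d_swapped))
  expect_equal(mw1$p_value, mw2$p_value, tolerance = 1e-12)
})
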