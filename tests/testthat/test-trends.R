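test_that("anova_tukey agrees with the stats oracle on random fixtures", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:8, 3, replace = TRUE)  # Tukey-Kramer: unequal n legal
    groups <- factor(rep(c("A", "B", "C"), times = n))
    values <- rnorm(sum(n), mean = rep(runif(3, -2, 2), times = n),
                    sd = runif(1, 0.2, 1.5))
    mine <- anova_tukey(values, groups)
    orc <- oracle_anova_tukey(values, groups)
    expect_equal(mine$F, orc$F, tolerance = 1e-8)
    expect_equal(mine$p, orc$p, tolerance = 1e-8)
    expect_equal(mine$tukey_p[names(orc$tukey_p)], orc$tukey_p,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate variance cases take their limiting values", {
  g <- factor(rep(c("A", "B", "C"), each = 3))
  res <- anova_tukey(rep(1, 9), g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_equal(unname(res$tukey_p), c(1, 1, 1))
  # zero within-group variance, unequal means: maximally significant
  res2 <- anova_tukey(rep(c(1, 2, 2), each = 3), g)
  expect_equal(res2$p, 0)
  expect_equal(unname(res2$tukey_p), c(0, 0, 1))
})

test_that("relabeling groups permutes Tukey p-values but not F", {
  set.seed(5)
  v <- rnorm(15, mean = rep(c(0, 1, 3), each = 5))
  g1 <- factor(rep(c("A", "B", "C"), each = 5))
  g2 <- factor(rep(c("C", "B", "A"), each = 5))  # reverse label order
  r1 <- anova_tukey(v, g1)
  r2 <- anova_tukey(v, g2)
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  # AB under g1 compares the same data as BC under g2
  expect_equal(unname(r1$tukey_p["AB"]), unname(r2$tukey_p["BC"]),
               tolerance = 1e-12)
  expect_equal(unname(r1$tukey_p["AC"]), unname(r2$tukey_p["AC"]),
               tolerance = 1e-12)
  expect_error(anova_tukey(1:4, factor(c("A", "A", "B", "C"))),
               "fewer than 2")
})

test_that("strong bell profile is detected and classified", {
  set.seed(9)
  v <- rnorm(15, mean = rep(c(0, 3, 0), each = 5), sd = 0.1)
  g <- factor(rep(c("A", "B", "C"), each = 5))
  res <- anova_tukey(v, g)
  expect_lt(res$p, 1e-6)
  expect_lt(res$tukey_p["AB"], 0.05)
  expect_lt(res$tukey_p["BC"], 0.05)
  cl <- classify_trend(res$means, res$tukey_p)
  expect_equal(cl$trend_type, "bell_both")
  expect_equal(cl$trend_group, "bell")
})

test_that("classification follows the 17-type taxonomy rules", {
  p <- function(ab, bc, ac) {
    stats::setNames(ifelse(c(ab, bc, ac), 1e-3, 0.5), c("AB", "BC", "AC"))
  }
  # nothing significant -> no_change regardless of the mean pattern
  expect_equal(classify_trend(c(0, 3, 0), p(FALSE, FALSE, FALSE))$trend_group,
               "no_change")
  # gradual up: only the outer comparison significant
  cl <- classify_trend(c(0, 0.4, 3), p(FALSE, FALSE, TRUE))
  expect_equal(cl$trend_type, "up_ends")
  expect_equal(cl$trend_group, "up")
  # single-step subtypes
  expect_equal(classify_trend(c(0, -1, -2), p(TRUE, FALSE, FALSE))$trend_type,
               "down_first")
  expect_equal(classify_trend(c(0, -2, -1), p(FALSE, TRUE, TRUE))$trend_type,
               "u_shape_second")
  # AC is ignored once AB or BC is significant
  expect_equal(classify_trend(c(0, 1, 2), p(TRUE, FALSE, TRUE))$trend_type,
               "up_first")
  # tied step difference takes its sign from the outer difference
  expect_equal(classify_trend(c(0, 0, 2), p(FALSE, TRUE, FALSE))$trend_group,
               "up")
  expect_equal(classify_trend(c(2, 0, 0), p(TRUE, FALSE, FALSE))$trend_group,
               "down")
  # all-equal means with a significant test is impossible
  expect_error(classify_trend(c(1, 1, 1), p(TRUE, FALSE, FALSE)),
               "impossible")
})

test_that("taxonomy enumeration is total, reaches 17 types in 5 groups", {
  expect_equal(taxonomy_size(), c(types = 17, groups = 5))
  # brute force: every sign x significance combination maps to exactly
  # one code, and every one of the 17 codes is reached
  mean_sets <- list(c(0, 1, 2), c(0, -1, -2), c(0, 2, 1), c(0, -2, -1))
  seen <- character(0)
  for (m in mean_sets) {
    for (bits in 0:7) {
      sig <- as.logical(bitwAnd(bits, c(1L, 2L, 4L)) > 0)
      pv <- stats::setNames(ifelse(sig, 1e-3, 0.5), c("AB", "BC", "AC"))
      cl <- classify_trend(m, pv)
      expect_length(cl$trend_type, 1)
      expect_true(cl$trend_group %in%
                    c("no_change", "up", "down", "bell", "u_shape"))
      seen <- c(seen, cl$trend_type)
    }
  }
  expect_length(unique(seen), 17)
  directions <- c("up", "down", "bell", "u_shape")
  subtypes <- c("first", "second", "both", "ends")
  expect_setequal(unique(seen),
                  c("no_change", as.vector(outer(directions, subtypes,
                                                 paste, sep = "_"))))
})

test_that("raising alpha never moves a metabolite into no_change", {
  set.seed(33)
  for (i in 1:40) {
    means <- rnorm(3)
    pv <- stats::setNames(runif(3), c("AB", "BC", "AC"))
    was_changed <- classify_trend(means, pv, alpha = 0.02)$trend_group !=
      "no_change"
    if (was_changed) {
      expect_false(classify_trend(means, pv, alpha = 0.2)$trend_group ==
                     "no_change")
    }
  }
})

test_that("bell and u-shape calls respect the middle-extreme invariant", {
  set.seed(77)
  for (i in 1:60) {
    means <- rnorm(3)
    pv <- stats::setNames(runif(3, 0, 0.2), c("AB", "BC", "AC"))
    cl <- classify_trend(means, pv)
    if (cl$trend_group == "bell") {
      expect_gt(means[2], means[1])
      expect_gt(means[2], means[3])
    }
    if (cl$trend_group == "u_shape") {
      expect_lt(means[2], means[1])
      expect_lt(means[2], means[3])
    }
  }
})

test_that("run_trend_analysis validates input and summarizes groups", {
  sim <- planted_table(c("no_change", "bell", "up", "down", "u_shape"),
                       seed = 4)
  l2 <- log_transform(sim$table, 2)
  res <- run_trend_analysis(l2)
  expect_s3_class(res, "trend_analysis")
  expect_equal(nrow(res$calls), 5)
  expect_equal(sum(res$proportions), 1)
  expect_equal(res$calls$trend_group[2:5],
               factor(c("bell", "up", "down", "u_shape"),
                      levels = c("no_change", "up", "down", "bell",
                                 "u_shape")))
  # a 2-group table is rejected: the taxonomy needs 3 timepoints
  two <- make_table(matrix(rnorm(12, 5), 2),
                    groups = rep(c("a", "b"), each = 3), scale = "log2")
  expect_error(run_trend_analysis(two), "3 ordered")
  expect_error(run_trend_analysis(sim$table), "log-transform")
})
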