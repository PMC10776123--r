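test_that("generators are pure functions of spec and seed", {
  specs <- trend_mixture(30)
  a <- generate_abundance(specs, seed = 123)
  b <- generate_abundance(specs, seed = 123)
  expect_identical(a, b)
  c <- generate_abundance(specs, seed = 124)
  expect_false(identical(a$table$values, c$table$values))
  # the global RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_abundance(specs, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)

  s1 <- generate_survival(survival_spec(n = 50, seed = 3))
  s2 <- generate_survival(survival_spec(n = 50, seed = 3))
  expect_identical(s1, s2)
  f1 <- generate_fiber_areas(100, seed = 2)
  expect_identical(f1, generate_fiber_areas(100, seed = 2))
})

test_that("trend mixture uses the published proportions by default", {
  specs <- trend_mixture(1000)
  groups <- vapply(specs, `[[`, character(1), "direction")
  expect_equal(sum(groups == "no_change"), 721)
  expect_equal(sum(groups == "bell"), 128)
  expect_length(specs, 1000)
  expect_error(trend_mixture(10, c(no_change = 0.5)), "sum to 1")
})

test_that("null tables give the nominal ANOVA type-I rate", {
  # 50 tables x 100 null metabolites: fraction of anova_p < 0.05 within
  # 3 binomial s.e. of alpha
  reps <- 50
  n_met <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    specs <- replicate(n_met, trend_spec("no_change"), simplify = FALSE)
    sim <- generate_abundance(specs, seed = 1000 + r)
    res <- run_trend_analysis(log_transform(sim$table, 2))
    hits <- hits + sum(res$calls$anova_p < 0.05)
  }
  frac <- hits / (reps * n_met)
  se <- sqrt(0.05 * 0.95 / (reps * n_met))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("planted bell profiles are recovered with high power", {
  reps <- 50
  ok <- 0
  for (r in seq_len(reps)) {
    sim <- planted_table("bell", seed = 2000 + r)
    res <- run_trend_analysis(log_transform(sim$table, 2))
    ok <- ok + (as.character(res$calls$trend_group) == "bell")
  }
  expect_gte(ok / reps, 0.9)
})

test_that("abundance generator validates its preconditions", {
  specs <- trend_mixture(10)
  expect_error(generate_abundance(specs, n_per_group = 2), "n_per_group")
  expect_error(generate_abundance(specs, groups = c("a", "b")), "3 group")
  expect_error(
    generate_abundance(specs, modules = list(module_spec(20))), "exceed")
  expect_error(module_spec(1), "size")
  expect_error(module_spec(5, loading = 1.2), "loading")
  expect_error(trend_spec("sideways"), "unknown")
  expect_error(trend_spec("up", noise_sd = 0), "noise_sd")
})

test_that("module members correlate at about loading squared", {
  specs <- replicate(40, trend_spec("no_change"), simplify = FALSE)
  sim <- generate_abundance(specs, n_per_group = 40,
                            modules = list(module_spec(20, loading = 0.9)),
                            seed = 6)
  lv <- log2(sim$table$values)
  cm <- cor(t(lv[1:20, ]))
  within_r <- mean(cm[upper.tri(cm)])
  expect_lt(abs(within_r - 0.81), 0.1)
  off <- cor(t(lv))[1:20, 21:40]
  expect_lt(abs(mean(off)), 0.15)
  expect_equal(sim$truth$module, rep(c(1L, NA), each = 20))
})

test_that("survival spec defaults to a continuous hazard at the plateau", {
  sp <- survival_spec(gompertz_a = 0.001, gompertz_b = 0.3,
                      plateau_week = 40)
  expect_equal(sp$plateau_hazard, 0.001 * exp(0.3 * 40))
  # cumulative hazard has no jump in slope beyond float noise
  H <- metaboaging:::cumulative_hazard(sp, c(39.999, 40, 40.001))
  expect_equal(diff(H)[1] / 0.001, diff(H)[2] / 0.001, tolerance = 1e-3)
  expect_error(survival_spec(plateau_week = 0), "plateau_week")
  expect_error(survival_spec(gompertz_a = -1), "gompertz")
  expect_error(survival_spec(onset_week = 50, plateau_week = 45),
               "onset_week")
})

test_that("a huge early hazard kills the whole cohort in week one", {
  sp <- survival_spec(n = 200, gompertz_a = 20, gompertz_b = 0.1,
                      plateau_week = 45, seed = 8)
  cohort <- generate_survival(sp)
  expect_gte(mean(cohort$death_weeks <= 1), 0.99)
})

test_that("closed-form curve of the three-phase cohort locates its
           curvature changes", {
  sp <- three_phase_survival_spec(n = 10000)
  curve <- expected_mortality_curve(sp, 1:120)
  keep <- curve$M < 0.99
  x <- curve$week[keep]; y <- curve$logM[keep]
  # oracle: weeks at which the numerical second differences flip sign
  d2 <- diff(diff(y))
  flips <- x[which(diff(sign(d2)) != 0) + 1]
  expect_length(flips, 2)
  found <- find_inflections(list(x = x, y = y), max_points = 2)
  expect_length(found$inflection_weeks, 2)
  # the onset bend is strongly asymmetric (near-linear then steeply
  # convex); the surface-midpoint estimate carries a small bias toward
  # the convex side, hence the wider band for the first point
  expect_lt(abs(found$inflection_weeks[1] - flips[1]), 3)
  expect_lt(abs(found$inflection_weeks[2] - flips[2]), 2)
})

test_that("the two-piece Gompertz-plateau curve is concave everywhere", {
  # with the Gompertzian rise starting at week 0 the log-slope
  # derivative is b - h/M < 0 for all t, so no inflection exists on the
  # noise-free curve -- the reason a distinct early-life phase is needed
  sp <- survival_spec(n = 10000, gompertz_a = 1e-4, gompertz_b = 0.2,
                      plateau_week = 45)
  curve <- expected_mortality_curve(sp, 1:60)
  d2 <- diff(diff(curve$logM))
  expect_true(all(d2 < 0))
  expect_false(ese_inflection(curve$week, curve$logM)$found)
})

test_that("fiber areas follow the lognormal mixture", {
  areas <- generate_fiber_areas(4000, seed = 5)
  expect_true(all(areas > 0))
  cls <- classify_fibers(areas)
  # majority small: lognormal CDF at 1000 with median 800, sdlog 0.6
  p_small <- plnorm(1000, log(800), 0.6)
  frac <- cls$counts[["small"]] / 4000
  expect_lt(abs(frac - p_small), 3 * sqrt(p_small * (1 - p_small) / 4000))
  expect_identical(generate_fiber_areas(0), numeric(0))
  expect_error(generate_fiber_areas(
    10, data.frame(weight = 1, meanlog = 1, sdlog = -1)), "nonpositive")
  expect_error(generate_fiber_areas(
    10, data.frame(weight = c(0.5, 0.4), meanlog = 1, sdlog = 1)),
    "sum to 1")
})
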