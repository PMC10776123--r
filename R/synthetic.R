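# Synthetic data: abundance matrices with planted trend types and
# correlated modules, Gompertz-plateau survival cohorts, and lognormal
# fiber-area samples.  All generators are pure functions of
# (specification, seed): the global RNG stream is saved and restored.

#' Specification of one planted metabolite trend
#'
#' @param trend_type One of the 5 trend groups (`no_change`, `up`,
#'   `down`, `bell`, `u_shape`) or any of the 17 type codes (the planted
#'   profile depends only on the direction prefix).
#' @param base_log2_mean Baseline log2 abundance (default 10, i.e. raw
#'   intensity about 1024 -- a mid-range LC-MS peak).
#' @param effect_size Planted effect in log2 units (default 2.0, a
#'   four-fold change).
#' @param noise_sd Within-group standard deviation in log2 units
#'   (default 0.3).
#' @return List of class `trend_spec`.
#' @export
trend_spec <- function(trend_type = "no_change", base_log2_mean = 10,
                       effect_size = 2, noise_sd = 0.3) {
  direction <- NULL
  for (g in c("no_change", "u_shape", "up", "down", "bell")) {
    if (startsWith(trend_type, g)) { direction <- g; break }
  }
  if (is.null(direction)) stop2("trend_spec: unknown trend_type ", trend_type)
  if (effect_size < 0) stop2("trend_spec: effect_size >= 0")
  if (noise_sd <= 0) stop2("trend_spec: noise_sd > 0")
  structure(list(trend_type = trend_type, direction = direction,
                 base_log2_mean = base_log2_mean,
                 effect_size = effect_size, noise_sd = noise_sd),
            class = "trend_spec")
}

# planted group-mean offsets (log2) for the three ordered groups
trend_offsets <- function(direction, effect) {
  switch(direction,
         no_change = c(0, 0, 0),
         up = c(0, effect / 2, effect),
         down = c(0, -effect / 2, -effect),
         bell = c(0, effect, 0),
         u_shape = c(0, -effect, 0))
}

#' Mixture of trend specs at given group proportions
#'
#' Default proportions follow the published prevalence of the two
#' reported groups (72.1% no-change, 12.8% bell); the remaining 15.1% is
#' split evenly across up, down and u_shape, a documented free choice.
#'
#' @param n Number of metabolites.
#' @param proportions Named numeric vector over the five trend groups,
#'   summing to 1.
#' @param ... Passed to [trend_spec()] (effect size, noise).
#' @return List of `n` [trend_spec()] objects (deterministic rounding:
#'   largest remainders get the leftover metabolites).
#' @export
trend_mixture <- function(n,
                          proportions = c(no_change = 0.721, bell = 0.128,
                                          up = 0.151 / 3, down = 0.151 / 3,
                                          u_shape = 0.151 / 3),
                          ...) {
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop2("trend_mixture: proportions must sum to 1")
  }
  counts <- floor(n * proportions)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * proportions - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  specs <- list()
  for (g in names(proportions)) {
    specs <- c(specs, replicate(counts[[g]], trend_spec(g, ...),
                                simplify = FALSE))
  }
  specs[seq_len(n)]
}

#' Specification of one correlation module
#'
#' Members share a latent factor: on the log2 scale a member's noise term
#' is `noise_sd * (loading * z + sqrt(1 - loading^2) * eps)` with `z` the
#' module factor, so pairwise within-module correlation is about
#' `loading^2`.
#'
#' @param size Number of member metabolites (>= 2).
#' @param loading Latent-factor loading in (0, 1), default 0.9.
#' @param hub_count Number of hub metabolites attached to this module's
#'   block (see [generate_abundance()]).
#' @return List of class `module_spec`.
#' @export
module_spec <- function(size, loading = 0.9, hub_count = 0L) {
  if (size < 2) stop2("module_spec: size >= 2")
  if (loading <= 0 || loading >= 1) stop2("module_spec: loading in (0,1)")
  if (hub_count < 0) stop2("module_spec: hub_count >= 0")
  structure(list(size = as.integer(size), loading = loading,
                 hub_count = as.integer(hub_count)),
            class = "module_spec")
}

# small pool of lipid shorthand names for demo tables
random_lipid_names <- function(k) {
  classes <- c("TG", "DG", "PC", "PE", "PI", "PS", "PG", "FA", "CER", "CAR")
  cls <- sample(classes, k, replace = TRUE)
  carbons <- ifelse(cls == "CAR", sample(2:22, k, replace = TRUE),
                    sample(30:60, k, replace = TRUE))
  dbs <- sample(0:6, k, replace = TRUE)
  sprintf("%s(%d:%d)", cls, carbons, dbs)
}

#' Generate a synthetic abundance table with planted truth
#'
#' Intensities are `2 ^ (base + group offset + correlated noise)`.
#' Module members occupy metabolites in order of the `modules` list,
#' starting at the first metabolite; hubs are appended as extra
#' metabolites.  Because an edge rule of r > 0.7 makes loading on several
#' orthogonal factors geometrically impossible (a hub splitting loading
#' `l` over k orthogonal factors correlates at most `l/sqrt(k)` with any
#' member), hubs load on a *common factor* shared (weight `factor_cor`)
#' by the modules of the hub block, which correlates the block's modules
#' below the edge threshold while hubs reach `hub_loading *
#' sqrt(factor_cor) * loading` correlation with every member of the
#' block.
#'
#' @param specs List of [trend_spec()] (one per metabolite), e.g. from
#'   [trend_mixture()].
#' @param groups Three ordered group labels (default 22/37/52 weeks).
#' @param n_per_group Samples per group (>= 3).
#' @param modules List of [module_spec()].
#' @param seed Integer seed.
#' @param hub_count Total number of hub metabolites; default the sum of
#'   the modules' `hub_count` fields.
#' @param hub_block Indices of the modules sharing the hub common factor;
#'   default the first `min(3, length(modules))` modules.
#' @param hub_loading Hub loading on the common factor (default 0.95).
#' @param factor_cor Weight of the common factor inside each block
#'   module's factor (default 0.75).
#' @param lipid_fraction Fraction of metabolites given random lipid
#'   shorthand names (default 0; used by demo pipelines).
#' @return List with `table` (a raw-scale [abundance_table()]) and
#'   `truth` (data frame: `metabolite_id`, `trend_type`, `trend_group`,
#'   `module` (NA for free metabolites), `is_hub`).
#' @export
generate_abundance <- function(specs, groups = c("22wk", "37wk", "52wk"),
                               n_per_group = 7, modules = list(),
                               seed = 1, hub_count = NULL,
                               hub_block = NULL, hub_loading = 0.95,
                               factor_cor = 0.75, lipid_fraction = 0) {
  if (length(groups) != 3) stop2("generate_abundance: need 3 group labels")
  if (n_per_group < 3) {
    stop2("generate_abundance: n_per_group >= 3 (Tukey degrees of freedom)")
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "trend_spec")))
  if (length(modules)) {
    stopifnot(all(vapply(modules, inherits, logical(1), "module_spec")))
  }
  if (is.null(hub_count)) {
    hub_count <- if (length(modules)) {
      sum(vapply(modules, `[[`, integer(1), "hub_count"))
    } else 0L
  }
  if (hub_count > 0 && length(modules) == 0L) {
    stop2("generate_abundance: hubs need modules")
  }
  if (is.null(hub_block) && hub_count > 0) {
    hub_block <- seq_len(min(3L, length(modules)))
  }
  n_met <- length(specs)
  sizes <- vapply(modules, `[[`, integer(1), "size")
  if (sum(sizes) > n_met) {
    stop2("generate_abundance: module sizes exceed metabolite count")
  }
  n_samp <- 3 * n_per_group
  group_f <- factor(rep(groups, each = n_per_group), levels = groups)

  with_seed(seed, {
    # module factors, with a common factor across the hub block
    g_common <- stats::rnorm(n_samp)
    zf <- matrix(stats::rnorm(length(modules) * n_samp),
                 nrow = max(1, length(modules)), ncol = n_samp)
    if (hub_count > 0) {
      for (m in hub_block) {
        zf[m, ] <- sqrt(factor_cor) * g_common +
          sqrt(1 - factor_cor) * zf[m, ]
      }
    }
    eps <- matrix(stats::rnorm(n_met * n_samp), n_met, n_samp)

    module_of <- rep(NA_integer_, n_met)
    if (length(modules)) {
      module_of[seq_len(sum(sizes))] <- rep(seq_along(modules), sizes)
    }
    log2_vals <- matrix(0, n_met, n_samp)
    for (i in seq_len(n_met)) {
      sp <- specs[[i]]
      mu <- sp$base_log2_mean +
        trend_offsets(sp$direction, sp$effect_size)[as.integer(group_f)]
      m <- module_of[i]
      noise <- if (is.na(m)) {
        eps[i, ]
      } else {
        l <- modules[[m]]$loading
        l * zf[m, ] + sqrt(1 - l^2) * eps[i, ]
      }
      log2_vals[i, ] <- mu + sp$noise_sd * noise
    }
    ids <- sprintf("met_%04d", seq_len(n_met))
    truth <- data.frame(
      metabolite_id = ids,
      trend_type = vapply(specs, `[[`, character(1), "trend_type"),
      trend_group = vapply(specs, `[[`, character(1), "direction"),
      module = module_of, is_hub = FALSE, stringsAsFactors = FALSE)

    if (hub_count > 0) {
      base <- stats::median(vapply(specs, `[[`, numeric(1), "base_log2_mean"))
      sd0 <- stats::median(vapply(specs, `[[`, numeric(1), "noise_sd"))
      hub_eps <- matrix(stats::rnorm(hub_count * n_samp), hub_count, n_samp)
      hub_vals <- base + sd0 *
        (hub_loading * matrix(g_common, hub_count, n_samp, byrow = TRUE) +
           sqrt(1 - hub_loading^2) * hub_eps)
      hub_ids <- sprintf("hub_%02d", seq_len(hub_count))
      log2_vals <- rbind(log2_vals, hub_vals)
      ids <- c(ids, hub_ids)
      truth <- rbind(truth, data.frame(
        metabolite_id = hub_ids, trend_type = "no_change",
        trend_group = "no_change", module = NA_integer_, is_hub = TRUE,
        stringsAsFactors = FALSE))
    }

    names_pool <- ids
    if (lipid_fraction > 0) {
      k <- round(lipid_fraction * length(ids))
      pick <- sample(length(ids), k)
      names_pool[pick] <- random_lipid_names(k)
    }
    metabolites <- data.frame(metabolite_id = ids,
                              putative_name = names_pool,
                              confidence = 9, stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = sprintf("S%02d", seq_len(n_samp)),
      group = group_f,
      replicate_index = rep(seq_len(n_per_group), 3))
    tab <- abundance_table(2 ^ log2_vals, metabolites, samples)
    list(table = tab, truth = truth)
  })
}

#' Specification of a Gompertz-plateau survival cohort
#'
#' Piecewise hazard with up to three phases, mirroring the three
#' life-history stages of a short-lived vertebrate cohort:
#' a low constant early-life hazard `early_hazard` until `onset_week`
#' (omitted when `onset_week = 0`, the default), a Gompertzian rise
#' `h(t) = a exp(b (t - onset_week))` until `plateau_week`, and a
#' constant `plateau_hazard` afterwards (mortality deceleration).  The
#' default `plateau_hazard` is the hazard reached at the plateau, i.e.
#' continuous with no jump.
#'
#' A distinct early-life phase matters for inflection analysis: when the
#' Gompertz segment starts at week 0 the log10 cumulative-mortality
#' curve is strictly concave everywhere (the log-slope derivative is
#' `b - h/M`, and `h/M > b` for all t under a pure Gompertz hazard), so
#' it has no inflection at all.  Only a cohort that first accumulates
#' mortality at a low background rate and then hits the Gompertzian
#' acceleration shows the convex-then-concave shape whose two
#' inflections delimit the ageing phase.
#'
#' @param n Cohort size (default 39, a typical life-span study cohort).
#' @param gompertz_a,gompertz_b Gompertz parameters (> 0); `gompertz_a`
#'   is the hazard at `onset_week`.
#' @param plateau_week Week at which the exponential rise stops (> 0).
#' @param plateau_hazard Constant weekly hazard after the plateau
#'   (>= 0); default continuous.
#' @param onset_week Start of the Gompertzian rise (default 0: no
#'   early-life phase, the plain two-piece model).
#' @param early_hazard Constant weekly hazard before `onset_week`
#'   (default 0).
#' @param seed Integer seed used by [generate_survival()].
#' @return List of class `survival_spec`.
#' @export
survival_spec <- function(n = 39, gompertz_a = 1e-4, gompertz_b = 0.2,
                          plateau_week = 45, plateau_hazard = NULL,
                          onset_week = 0, early_hazard = 0,
                          seed = 1) {
  if (gompertz_a <= 0 || gompertz_b <= 0) {
    stop2("survival_spec: gompertz_a and gompertz_b must be > 0")
  }
  if (plateau_week <= 0) stop2("survival_spec: plateau_week > 0")
  if (onset_week < 0 || onset_week >= plateau_week) {
    stop2("survival_spec: need 0 <= onset_week < plateau_week")
  }
  if (early_hazard < 0) stop2("survival_spec: early_hazard >= 0")
  if (is.null(plateau_hazard)) {
    plateau_hazard <- gompertz_a *
      exp(gompertz_b * (plateau_week - onset_week))
  }
  if (plateau_hazard < 0) stop2("survival_spec: plateau_hazard >= 0")
  structure(list(n = as.integer(n), gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, plateau_week = plateau_week,
                 plateau_hazard = plateau_hazard,
                 onset_week = onset_week, early_hazard = early_hazard,
                 seed = as.integer(seed)),
            class = "survival_spec")
}

#' Killifish-like three-phase survival cohort
#'
#' Convenience spec embodying the life-history structure of a
#' short-lived killifish cohort: negligible background mortality until
#' week 35, a steep Gompertzian rise through the ageing phase, and
#' mortality deceleration (constant hazard) from week 45.  The
#' parameters keep the hazard below `b * M` throughout the rise, so the
#' log10 cumulative-mortality curve steepens right up to the plateau and
#' its second (concave) inflection sits at the plateau week.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return A [survival_spec()].
#' @export
three_phase_survival_spec <- function(n = 39, seed = 1) {
  survival_spec(n = n, gompertz_a = 0.002, gompertz_b = 0.35,
                plateau_week = 45, onset_week = 35,
                early_hazard = 0.001, seed = seed)
}

# cumulative hazard of the piecewise early/Gompertz/plateau model
cumulative_hazard <- function(spec, t) {
  a <- spec$gompertz_a; b <- spec$gompertz_b
  t0 <- spec$onset_week; c0 <- spec$early_hazard
  pw <- spec$plateau_week; ph <- spec$plateau_hazard
  H_early <- c0 * pmin(t, t0)
  tg <- pmax(0, pmin(t, pw) - t0)
  H_gomp <- a / b * (exp(b * tg) - 1)
  H_plat <- ph * pmax(0, t - pw)
  H_early + H_gomp + H_plat
}

#' Closed-form expected mortality curve of a survival spec
#'
#' `M(t) = 1 - exp(-H(t))` with `H` the cumulative hazard; the noise-free
#' curve used as the analytic oracle for inflection detection.
#'
#' @param spec A [survival_spec()].
#' @param weeks Evaluation weeks.
#' @return Data frame with `week`, `M`, `logM`.
#' @export
expected_mortality_curve <- function(spec, weeks) {
  stopifnot(inherits(spec, "survival_spec"))
  M <- 1 - exp(-cumulative_hazard(spec, weeks))
  data.frame(week = weeks, M = M,
             logM = ifelse(M > 0, log10(M), NA_real_))
}

#' Simulate per-individual death weeks under a survival spec
#'
#' Discrete weekly sampling: an animal alive at the start of week t dies
#' during it with probability `1 - exp(-(H(t) - H(t-1)))`.  Equivalent
#' inversion: draw E ~ Exp(1) per animal, death at the first integer week
#' with `H(week) >= E`.  With `plateau_hazard = 0` animals that outlive
#' the plateau never die and are censored at `max_week`.
#'
#' @param spec A [survival_spec()].
#' @param max_week Censoring horizon for immortal tails (default 1000).
#' @return A [survival_cohort()].
#' @export
generate_survival <- function(spec, max_week = 1000) {
  stopifnot(inherits(spec, "survival_spec"))
  a <- spec$gompertz_a; b <- spec$gompertz_b
  t0 <- spec$onset_week; c0 <- spec$early_hazard
  pw <- spec$plateau_week; ph <- spec$plateau_hazard
  H0 <- c0 * t0                                   # end of early phase
  Hpw <- H0 + a / b * (exp(b * (pw - t0)) - 1)    # end of Gompertz phase
  with_seed(spec$seed, {
    E <- stats::rexp(spec$n)
    t_death <- numeric(spec$n)
    early <- E <= H0                    # only reachable when c0 > 0
    gomp <- !early & E <= Hpw
    late <- !early & !gomp
    t_death[early] <- E[early] / c0
    t_death[gomp] <- t0 + log(1 + b * (E[gomp] - H0) / a) / b
    t_death[late] <- if (ph > 0) pw + (E[late] - Hpw) / ph else Inf
    week <- ceiling(t_death)
    week[t_death == Inf | week > max_week] <- NA
    survival_cohort(week[!is.na(week)],
                    censored = rep(max_week, sum(is.na(week))),
                    n = spec$n)
  })
}

#' Generate fiber cross-sectional areas from a lognormal mixture
#'
#' @param n Number of fibers (0 gives an empty vector).
#' @param components Data frame with columns `weight`, `meanlog`,
#'   `sdlog`; weights must sum to 1.  The default single component has
#'   median 800 um^2 and sdlog 0.6, a realistic spread for fish trunk
#'   muscle.
#' @param seed Integer seed.
#' @return Numeric vector of positive areas (um^2).
#' @export
generate_fiber_areas <- function(n,
                                 components = data.frame(
                                   weight = 1, meanlog = log(800),
                                   sdlog = 0.6),
                                 seed = 1) {
  components <- as.data.frame(components)
  if (abs(sum(components$weight) - 1) > 1e-8) {
    stop2("generate_fiber_areas: component weights must sum to 1")
  }
  if (any(components$weight < 0) || any(components$sdlog <= 0)) {
    stop2("generate_fiber_areas: nonpositive mixture parameters")
  }
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    comp <- sample.int(nrow(components), n, replace = TRUE,
                       prob = components$weight)
    stats::rlnorm(n, meanlog = components$meanlog[comp],
                  sdlog = components$sdlog[comp])
  })
}
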