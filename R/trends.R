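# Trend-type classification of three-timepoint abundance profiles.
#
# Each metabolite's log2 profile across three ordered age groups (A < B < C)
# is tested by one-way ANOVA plus Tukey HSD, then assigned one of 17 trend
# types in 5 broad groups:
#   - no_change: no pairwise comparison significant;
#   - up / down / bell / u_shape by the sign pattern of
#     (d1, d2) = (mean_B - mean_A, mean_C - mean_B):
#     (+,+) up, (-,-) down, (+,-) bell, (-,+) u_shape;
#   - within each direction, 4 subtypes by which comparisons reach
#     significance: first (A-B only), second (B-C only), both, or
#     ends (only A-C) -- the "gradual" class where neither single step is
#     itself significant.  AC status is ignored once AB or BC is
#     significant, which yields exactly 4 subtypes per direction and a
#     total of 4 x 4 + 1 = 17 types.

TREND_GROUPS <- c("no_change", "up", "down", "bell", "u_shape")

#' One-way ANOVA with Tukey-Kramer HSD for one metabolite
#'
#' Fixed-effects one-way ANOVA (F and p) plus Tukey-Kramer honestly
#' significant difference p-values for all pairwise group comparisons,
#' computed from the studentized range distribution with `k` groups and
#' `N - k` error degrees of freedom.  The Kramer form keeps unequal group
#' sizes legal.  Degenerate input with zero within-group variance reports
#' p = 0 for pairs with unequal means (the limiting behaviour) and p = 1
#' for equal ones.
#'
#' @param values Numeric vector of (log-scale) abundances.
#' @param groups Factor of the same length; every level needs >= 2
#'   observations.
#' @return List with `F`, `p`, `tukey_p` (named vector, e.g. `AB`, `BC`,
#'   `AC` for three groups), `means` (named group means) and `n` (group
#'   sizes).
#' @export
anova_tukey <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop2("anova_tukey: need >= 2 groups")
  n <- tabulate(groups)
  if (any(n < 2)) {
    stop2("anova_tukey: group '", levels(groups)[which(n < 2)[1]],
          "' has fewer than 2 observations")
  }
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      Fv <- 0; p <- 1
    } else {
      Fv <- Inf; p <- 0
    }
    s2 <- 0
  } else {
    s2 <- ssw / df2
    Fv <- (ssb / df1) / s2
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(k, 2)
  lab <- LETTERS[seq_len(k)]
  tukey_p <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- abs(means[j] - means[i])
    if (s2 == 0) return(if (d == 0) 1 else 0)
    se <- sqrt(s2 / 2 * (1 / n[i] + 1 / n[j]))
    stats::ptukey(d / se, nmeans = k, df = df2, lower.tail = FALSE)
  })
  names(tukey_p) <- apply(pairs, 2, function(ij) paste0(lab[ij], collapse = ""))
  list(F = unname(Fv), p = unname(p), tukey_p = tukey_p,
       means = means, n = n)
}

#' Classify one metabolite's trend from means and Tukey p-values
#'
#' See the taxonomy description in [taxonomy_size()].  Exact ties in a
#' step difference (d = 0) take their sign from the outer A-C difference;
#' three exactly equal means together with any significant comparison is
#' an impossible state and raises an error.
#'
#' @param means Numeric length-3 vector of group means in group order
#'   (A, B, C).
#' @param tukey_p Named numeric vector with elements `AB`, `BC`, `AC`.
#' @param alpha Significance level (default 0.05); p < alpha counts as
#'   significant.
#' @return List with `trend_type` (one of 17 codes) and `trend_group`
#'   (one of `no_change`, `up`, `down`, `bell`, `u_shape`).
#' @export
classify_trend <- function(means, tukey_p, alpha = 0.05) {
  stopifnot(length(means) == 3)
  if (!all(c("AB", "BC", "AC") %in% names(tukey_p))) {
    stop2("classify_trend: tukey_p needs elements AB, BC, AC")
  }
  sig <- tukey_p[c("AB", "BC", "AC")] < alpha
  if (!any(sig)) {
    return(list(trend_type = "no_change", trend_group = "no_change"))
  }
  d1 <- means[2] - means[1]
  d2 <- means[3] - means[2]
  dac <- means[3] - means[1]
  if (d1 == 0 && d2 == 0) {
    stop2("classify_trend: all three means equal but a comparison is ",
          "significant -- impossible state")
  }
  s1 <- sign(d1); s2 <- sign(d2)
  if (s1 == 0) s1 <- sign(dac)
  if (s2 == 0) s2 <- sign(dac)
  direction <- if (s1 > 0 && s2 > 0) "up"
    else if (s1 < 0 && s2 < 0) "down"
    else if (s1 > 0 && s2 < 0) "bell"
    else "u_shape"
  subtype <- if (sig["AB"] && sig["BC"]) "both"
    else if (sig["AB"]) "first"
    else if (sig["BC"]) "second"
    else "ends"
  list(trend_type = paste(direction, subtype, sep = "_"),
       trend_group = direction)
}

#' Size of the trend taxonomy, by exhaustive enumeration
#'
#' Enumerates the classifier's codomain over all 4 direction sign
#' patterns x all 8 significance patterns and reports how many distinct
#' trend types and trend groups are reachable (17 and 5).
#'
#' @return Named integer vector `c(types = 17, groups = 5)`.
#' @export
taxonomy_size <- function() {
  mean_sets <- list(up = c(0, 1, 2), down = c(0, -1, -2),
                    bell = c(0, 2, 1), u_shape = c(0, -2, -1))
  types <- character(0)
  groups <- character(0)
  for (m in mean_sets) {
    for (bits in 0:7) {
      sig <- as.logical(bitwAnd(bits, c(1L, 2L, 4L)) > 0)
      p <- ifelse(sig, 1e-3, 0.5)
      names(p) <- c("AB", "BC", "AC")
      cl <- classify_trend(m, p)
      types <- c(types, cl$trend_type)
      groups <- c(groups, cl$trend_group)
    }
  }
  c(types = length(unique(types)), groups = length(unique(groups)))
}

#' Run the trend analysis over a whole abundance table
#'
#' Applies [anova_tukey()] and [classify_trend()] to every metabolite of a
#' log-scale table with exactly three ordered groups.
#'
#' @param table An [abundance_table()] on a log scale (log2 is the
#'   conventional scale for trend analyses; the F and Tukey statistics are
#'   invariant to the log base).
#' @param alpha Significance level, default 0.05.
#' @return Object of class `trend_analysis`: a list with `calls` (data
#'   frame, one row per metabolite: group means, F, p, the three Tukey
#'   p-values, step-difference signs, `trend_type`, `trend_group`),
#'   `proportions` (named fraction per trend group), `alpha` and `groups`.
#' @export
run_trend_analysis <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale == "raw") {
    stop2("run_trend_analysis: log-transform the table first")
  }
  if (nlevels(table$samples$group) != 3) {
    stop2("run_trend_analysis: taxonomy is defined for exactly 3 ordered ",
          "groups, got ", nlevels(table$samples$group))
  }
  if (!(alpha > 0 && alpha < 1)) stop2("run_trend_analysis: alpha in (0,1)")
  groups <- table$samples$group
  ids <- table$metabolites$metabolite_id
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    at <- anova_tukey(table$values[i, ], groups)
    cl <- classify_trend(at$means, at$tukey_p, alpha)
    res[[i]] <- data.frame(
      metabolite_id = ids[i],
      mean_A = at$means[1], mean_B = at$means[2], mean_C = at$means[3],
      anova_F = at$F, anova_p = at$p,
      tukey_AB = at$tukey_p["AB"], tukey_BC = at$tukey_p["BC"],
      tukey_AC = at$tukey_p["AC"],
      sign_d1 = ifelse(at$means[2] >= at$means[1], "+", "-"),
      sign_d2 = ifelse(at$means[3] >= at$means[2], "+", "-"),
      trend_type = cl$trend_type, trend_group = cl$trend_group,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  calls <- do.call(rbind, res)
  calls$trend_group <- factor(calls$trend_group, levels = TREND_GROUPS)
  prop <- prop.table(table(calls$trend_group))
  structure(list(calls = calls,
                 proportions = stats::setNames(as.numeric(prop),
                                               names(prop)),
                 alpha = alpha,
                 groups = levels(groups)),
            class = "trend_analysis")
}

#' @export
print.trend_analysis <- function(x, ...) {
  cat("Trend analysis of", nrow(x$calls), "metabolites across groups",
      paste(x$groups, collapse = " < "), "(alpha =", x$alpha, ")\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' @export
summary.trend_analysis <- function(object, ...) {
  tt <- table(object$calls$trend_type)
  out <- list(proportions = object$proportions,
              type_counts = tt[order(-tt)],
              n = nrow(object$calls))
  class(out) <- "summary.trend_analysis"
  out
}

#' @export
print.summary.trend_analysis <- function(x, ...) {
  cat("Trend group proportions (n =", x$n, "):\n")
  print(round(x$proportions, 3))
  cat("\nTrend type counts:\n")
  print(x$type_counts)
  invisible(x)
}
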