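# Cumulative mortality on a log10 scale and inflection-point detection
# with the extremum surface estimator (ESE).
#
# ESE locates the inflection of noisy planar data from signed areas
# between the data polyline and its chords: for interior index i,
#   a_i = T(1, i) - C(1, i)   and   b_i = T(i, n) - C(i, n),
# where T(p, q) is the trapezoidal integral of the polyline over
# [x_p, x_q] and C(p, q) = (x_q - x_p) (y_p + y_q) / 2 is the chord
# trapezoid.  For convex-then-concave (S-shaped) data the left surface is
# minimized and the right surface maximized; the estimate is the midpoint
# of the two extremal abscissae.  Concave-then-convex data swap the
# extrema.

#' Cumulative mortality series of a cohort
#'
#' `M(t)` = cumulative deaths up to and including week t, divided by the
#' initial cohort size; `logM = log10(M)` where `M > 0` (the log series
#' starts at the first death, earlier weeks have no defined value).
#'
#' @param cohort A [survival_cohort()] (or numeric vector of death
#'   weeks).
#' @param weeks Census weeks; default every integer week from 1 to the
#'   last death.
#' @return Object of class `mortality_series`: data frame columns `week`,
#'   `deaths`, `cum_deaths`, `M`, `logM` plus attribute `n` (cohort
#'   size).
#' @export
cumulative_mortality <- function(cohort, weeks = NULL) {
  if (is.numeric(cohort)) cohort <- survival_cohort(cohort)
  stopifnot(inherits(cohort, "survival_cohort"))
  if (cohort$n == 0) stop2("cumulative_mortality: cohort size 0")
  dw <- cohort$death_weeks
  if (is.null(weeks)) {
    weeks <- seq_len(max(c(dw, 1)))
  }
  weeks <- sort(unique(weeks))
  cum <- vapply(weeks, function(w) sum(dw <= w), numeric(1))
  deaths <- diff(c(0, cum))
  M <- cum / cohort$n
  logM <- ifelse(M > 0, log10(M), NA_real_)
  if (all(is.na(logM))) {
    warning("cumulative_mortality: no deaths; log series is empty",
            call. = FALSE)
  }
  out <- data.frame(week = weeks, deaths = deaths, cum_deaths = cum,
                    M = M, logM = logM)
  attr(out, "n") <- cohort$n
  class(out) <- c("mortality_series", "data.frame")
  out
}

#' @export
print.mortality_series <- function(x, ...) {
  cat("Mortality series: cohort n =", attr(x, "n"), "|",
      max(x$cum_deaths), "deaths over", nrow(x), "census weeks\n")
  print.data.frame(utils::head(x[!is.na(x$logM), ], 10), row.names = FALSE)
  if (sum(!is.na(x$logM)) > 10) cat("...\n")
  invisible(x)
}

# second divided differences of y on a (possibly non-uniform) grid x;
# returns a vector of length n - 2 aligned with interior points
second_differences <- function(x, y) {
  n <- length(x)
  s <- diff(y) / diff(x)
  2 * diff(s) / (x[3:n] - x[1:(n - 2)])
}

# centered 3-point moving average, endpoints kept
smooth3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  out <- y
  out[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  out
}

#' Extremum surface estimator for a single inflection point
#'
#' @param x Strictly increasing numeric abscissae (n >= 5).
#' @param y Ordinates.
#' @return Object of class `inflection_estimate`: list with `found`
#'   (logical), `x_hat` (the estimate, `NA` when no inflection), `j1`,
#'   `j2` (indices of the left and right surface extrema), `orientation`
#'   (`"convex_concave"` or `"concave_convex"`), `x`, `y`.  Data whose
#'   second differences never change sign (purely convex, concave or
#'   linear) report `found = FALSE` rather than an error.
#' @export
ese_inflection <- function(x, y) {
  n <- length(x)
  if (n < 5) stop2("ese_inflection: need >= 5 points, got ", n)
  if (length(y) != n) stop2("ese_inflection: x and y lengths differ")
  if (any(diff(x) <= 0)) stop2("ese_inflection: x must be strictly increasing")
  no_result <- structure(list(found = FALSE, x_hat = NA_real_,
                              j1 = NA_integer_, j2 = NA_integer_,
                              orientation = NA_character_, x = x, y = y),
                         class = "inflection_estimate")
  d2 <- second_differences(x, y)
  tol <- 1e-12 * max(abs(y) + abs(x), 1)
  has_pos <- any(d2 > tol)
  has_neg <- any(d2 < -tol)
  if (!(has_pos && has_neg)) return(no_result)

  # cumulative trapezoid of the polyline from x_1
  ct <- c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  total <- ct[n]
  idx <- 2:(n - 1)
  a <- ct[idx] - (x[idx] - x[1]) * (y[1] + y[idx]) / 2
  b <- (total - ct[idx]) - (x[n] - x[idx]) * (y[idx] + y[n]) / 2

  # orientation from the sign of the total area relative to the full
  # chord; when that is degenerate (symmetric data) fall back to the sign
  # of the dominant left surface
  a_n <- total - (x[n] - x[1]) * (y[1] + y[n]) / 2
  s <- if (abs(a_n) > tol) a_n else a[which.max(abs(a))]
  if (s < 0) {
    orientation <- "convex_concave"
    j1 <- idx[which.min(a)]
    j2 <- idx[which.max(b)]
  } else {
    orientation <- "concave_convex"
    j1 <- idx[which.max(a)]
    j2 <- idx[which.min(b)]
  }
  structure(list(found = TRUE, x_hat = (x[j1] + x[j2]) / 2,
                 j1 = j1, j2 = j2, orientation = orientation,
                 x = x, y = y),
            class = "inflection_estimate")
}

#' @export
print.inflection_estimate <- function(x, ...) {
  if (!x$found) {
    cat("ESE: no inflection (no curvature sign change)\n")
  } else {
    cat("ESE inflection at x =", format(x$x_hat), "(", x$orientation,
        "; surface extrema at x =", format(x$x[x$j1]), "and",
        format(x$x[x$j2]), ")\n")
  }
  invisible(x)
}

# confirm a candidate inflection near index `at`: the windowed means of
# the smoothed second differences must have opposite signs on the two
# sides (a genuine curvature sign change, not a noise wiggle).  Returns
# 0 when unconfirmed, otherwise the magnitude of the mean-curvature jump
# |mean(d2 left) - mean(d2 right)|, which ranks genuine phase
# transitions above noise in flat regions (where both means are ~0) and
# above one-sided curvature (where both means share a sign).
curvature_change_strength <- function(x, y, at) {
  n <- length(x)
  if (n < 5) return(0)
  d2 <- second_differences(x, smooth3(y))
  w <- max(3L, min(8L, n %/% 10L))
  # d2[i] corresponds to interior point i + 1
  ctr <- at - 1L
  left <- max(1, ctr - w):(ctr - 1L)
  right <- (ctr + 1L):min(length(d2), ctr + w)
  if (ctr < 2 || length(left) < 2 || length(right) < 2 ||
      max(right) > length(d2)) {
    return(0)
  }
  ml <- mean(d2[left])
  mr <- mean(d2[right])
  if (sign(ml) * sign(mr) >= 0) return(0)
  abs(ml - mr)
}

#' Locate up to `max_points` inflection points by recursive bisection
#'
#' Runs [ese_inflection()] on the full log-mortality series, splits the
#' series at the estimate and re-runs on each side, recursively.  A
#' candidate is kept only when a sign change of the smoothed (3-point
#' moving average) second differences confirms a genuine curvature change
#' near it.  Up to `max_points` confirmed estimates (the strongest
#' curvature changes) are returned in increasing x order, defining up to
#' `max_points + 1` life-history phases.
#'
#' @param series A [cumulative_mortality()] result, or a data frame /
#'   list with elements `week` (or `x`) and `logM` (or `y`).
#' @param max_points Maximum number of inflections (default 2).
#' @param mode Candidate generation strategy: `"sliding"` (default) runs
#'   the estimator over overlapping windows so that each window brackets
#'   at most one curvature change (the shape the estimator assumes);
#'   `"bisection"` recursively splits the series at each estimate.  Both
#'   apply the same curvature confirmation.
#' @param window Window width in points for the sliding mode; default
#'   `max(11, n %/% 6)`.
#' @return Object of class `inflection_report`: list with `estimates`
#'   (list of [ese_inflection()] results), `inflection_weeks` (numeric),
#'   `phases` (boundaries of the implied phases) and `complete` (`FALSE`
#'   when fewer than `max_points` inflections were confirmed).
#' @export
find_inflections <- function(series, max_points = 2,
                             mode = c("sliding", "bisection"),
                             window = NULL) {
  mode <- match.arg(mode)
  if (inherits(series, "mortality_series")) {
    # analyze from the first death up to 99% cumulative mortality: past
    # that point logM sits within log10(1/0.99) ~ 0.004 of its
    # asymptote and its curvature is counting noise, so late censuses
    # of large cohorts carry no trajectory information
    ok <- !is.na(series$logM)
    sat <- which(series$M >= 0.99)
    if (length(sat) && sat[1] < nrow(series)) {
      ok <- ok & seq_len(nrow(series)) <= sat[1]
    }
    x <- series$week[ok]; y <- series$logM[ok]
  } else {
    x <- if (!is.null(series$week)) series$week else series$x
    y <- if (!is.null(series$logM)) series$logM else series$y
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 5) stop2("find_inflections: need >= 5 usable points")

  candidates <- list()
  consider <- function(lo, hi) {
    # ESE on one segment; keep the estimate only when the surface
    # extrema are in sigmoid order and the curvature confirmation holds
    est <- ese_inflection(x[lo:hi], y[lo:hi])
    if (!est$found) return(FALSE)
    j1g <- est$j1 + lo - 1L
    j2g <- est$j2 + lo - 1L
    # for sigmoid data the left-surface extremum falls on the far side of
    # the inflection (j1 > j2); the opposite order marks a non-sigmoid
    # segment whose estimate is unreliable
    if (j1g <= j2g) return(FALSE)
    at <- which.min(abs(x - est$x_hat))
    strength <- curvature_change_strength(x, y, at)
    if (strength > 0) {
      est$j1 <- j1g; est$j2 <- j2g
      est$x <- x; est$y <- y
      est$strength <- strength
      candidates[[length(candidates) + 1L]] <<- est
    }
    TRUE
  }
  n <- length(x)
  if (mode == "sliding") {
    w <- if (is.null(window)) max(11L, n %/% 6L) else as.integer(window)
    w <- min(max(w, 5L), n)
    stride <- max(1L, w %/% 3L)
    starts <- unique(c(seq(1L, n - w + 1L, by = stride), n - w + 1L))
    for (lo in starts) consider(lo, lo + w - 1L)
    consider(1L, n)  # full series too, for globally sigmoid data
  } else {
    recurse <- function(lo, hi, depth) {
      if (hi - lo + 1 < 5 || depth > 6) return()
      est <- ese_inflection(x[lo:hi], y[lo:hi])
      mid <- (lo + hi) %/% 2L
      if (!est$found) return()
      consider(lo, hi)
      split <- which.min(abs(x[lo:hi] - est$x_hat)) + lo - 1L
      if (split <= lo || split >= hi) split <- mid
      recurse(lo, split, depth + 1L)
      recurse(split, hi, depth + 1L)
    }
    recurse(1L, n, 0L)
  }

  if (length(candidates) == 0L) {
    return(structure(list(estimates = list(), inflection_weeks = numeric(0),
                          phases = range(x), complete = max_points == 0),
                     class = "inflection_report"))
  }
  xh <- vapply(candidates, `[[`, numeric(1), "x_hat")
  st <- vapply(candidates, `[[`, numeric(1), "strength")
  ord <- order(xh)
  xh <- xh[ord]; st <- st[ord]; candidates <- candidates[ord]
  # merge near-duplicate estimates of the same bend (within three grid
  # steps -- adjacent windows re-estimate the same inflection), keeping
  # the stronger candidate of each cluster
  step <- stats::median(diff(x))
  keep <- rep(TRUE, length(xh))
  for (i in seq_along(xh)[-1]) {
    prev <- max(which(keep[seq_len(i - 1)]))
    if (xh[i] - xh[prev] <= 3 * step) {
      if (st[i] > st[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
  }
  candidates <- candidates[keep]; st <- st[keep]
  if (length(candidates) > max_points) {
    sel <- sort(order(st, decreasing = TRUE)[seq_len(max_points)])
    candidates <- candidates[sel]
  }
  weeks <- vapply(candidates, `[[`, numeric(1), "x_hat")
  structure(list(estimates = candidates,
                 inflection_weeks = weeks,
                 phases = c(min(x), weeks, max(x)),
                 complete = length(weeks) >= max_points),
            class = "inflection_report")
}

#' @export
print.inflection_report <- function(x, ...) {
  if (length(x$inflection_weeks) == 0L) {
    cat("No confirmed inflection points\n")
  } else {
    cat("Inflection points at weeks:",
        paste(format(x$inflection_weeks), collapse = ", "), "\n")
    cat("Life-history phases:",
        paste(format(x$phases), collapse = " | "), "\n")
    if (!x$complete) cat("(fewer inflections than requested)\n")
  }
  invisible(x)
}
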