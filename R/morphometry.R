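# Muscle fiber cross-sectional area categories and per-category sampling.
# Boundaries as printed: small < 1000 um^2, medium 1000-2600 um^2
# (inclusive on both ends), large > 2600 um^2.

#' Classify fiber cross-sectional areas into size categories
#'
#' @param areas Numeric vector of areas in um^2 (> 0).
#' @return Object of class `fiber_classification`: list with `fibers`
#'   (data frame `fiber_id`, `area`, `category`) and `counts` (named
#'   small/medium/large).
#' @export
classify_fibers <- function(areas) {
  areas <- as.numeric(areas)
  bad <- which(!(areas > 0))
  if (length(bad)) {
    stop2("classify_fibers: nonpositive area at index ", bad[1])
  }
  category <- factor(ifelse(areas < 1000, "small",
                            ifelse(areas <= 2600, "medium", "large")),
                     levels = c("small", "medium", "large"))
  fibers <- data.frame(fiber_id = seq_along(areas), area = areas,
                       category = category)
  counts <- table(category)
  structure(list(fibers = fibers,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts))),
            class = "fiber_classification")
}

#' @export
print.fiber_classification <- function(x, ...) {
  cat("Fiber classification (n =", nrow(x$fibers), "):",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Randomly sample fibers per size category
#'
#' Uniform sampling without replacement within each category,
#' deterministic given the seed.  A category with fewer fibers than
#' requested contributes all of them and is flagged.
#'
#' @param classification A [classify_fibers()] result.
#' @param n_per_category Number of fibers per category (typical range
#'   20-30; any >= 1 is accepted).
#' @param seed Integer seed.
#' @return List with `sampled` (data frame subset of `fibers`) and
#'   `exhausted` (character vector of categories that had fewer fibers
#'   than requested).
#' @export
sample_per_category <- function(classification, n_per_category = 25,
                                seed = 1) {
  stopifnot(inherits(classification, "fiber_classification"))
  if (n_per_category < 1) stop2("sample_per_category: n_per_category >= 1")
  fibers <- classification$fibers
  with_seed(seed, {
    picked <- lapply(levels(fibers$category), function(cat) {
      rows <- which(fibers$category == cat)
      if (length(rows) <= n_per_category) rows
      else rows[sample.int(length(rows), n_per_category)]
    })
    avail <- tabulate(fibers$category, nbins = 3)
    exhausted <- levels(fibers$category)[avail < n_per_category]
    sampled <- fibers[sort(unlist(picked)), , drop = FALSE]
    rownames(sampled) <- NULL
    list(sampled = sampled, exhausted = exhausted)
  })
}
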