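# Deduplication and log transforms applied before any statistics.

#' Deduplicate metabolite records by putative name
#'
#' Untargeted annotation pipelines routinely assign the same putative name
#' to several features.  One record per name is kept: the one with the
#' highest identification confidence; confidence ties are broken by the
#' larger intensity (mean across all samples by default, or the maximum
#' single value); any residual tie falls back to the first record in
#' table order, making the operation deterministic and idempotent.
#'
#' @param table A raw-scale [abundance_table()].
#' @param tie `"mean"` (default) or `"max"`: the intensity statistic used
#'   to break confidence ties.
#' @return An [abundance_table()] with one record per putative name.
#' @export
deduplicate <- function(table, tie = c("mean", "max")) {
  stopifnot(inherits(table, "abundance_table"))
  tie <- match.arg(tie)
  if (table$scale != "raw") stop2("deduplicate: table must be raw scale")
  stat <- if (tie == "mean") rowMeans(table$values) else
    apply(table$values, 1, max)
  conf <- table$metabolites$confidence
  keep <- vapply(split(seq_len(nrow(table$values)),
                       table$metabolites$putative_name),
                 function(idx) {
                   idx <- idx[conf[idx] == max(conf[idx])]
                   idx <- idx[stat[idx] == max(stat[idx])]
                   idx[1]
                 }, integer(1))
  keep <- sort(unname(keep))
  abundance_table(table$values[keep, , drop = FALSE],
                  table$metabolites[keep, , drop = FALSE],
                  table$samples, scale = "raw")
}

#' Log-transform a raw abundance table
#'
#' Base-2 for trend analyses, base-10 for comparative analyses.  Zero
#' intensities are undefined under the log; the default policy replaces a
#' zero with half the smallest positive value of that metabolite before
#' transforming (a standard half-minimum imputation), recording how many
#' cells were imputed in the `"zeros_imputed"` attribute.
#'
#' @param table A raw-scale [abundance_table()].
#' @param base 2 or 10.
#' @param zero_policy `"half_min"` (default) or `"error"`.
#' @return An [abundance_table()] on the chosen log scale.
#' @export
log_transform <- function(table, base = 2,
                          zero_policy = c("half_min", "error")) {
  stopifnot(inherits(table, "abundance_table"))
  zero_policy <- match.arg(zero_policy)
  if (!base %in% c(2, 10)) stop2("log_transform: base must be 2 or 10")
  if (table$scale != "raw") {
    stop2("log_transform: table already on ", table$scale, " scale")
  }
  vals <- table$values
  n_zero <- 0L
  zero_rows <- which(rowSums(vals == 0) > 0)
  if (length(zero_rows)) {
    if (zero_policy == "error") {
      stop2("log_transform: zero intensity for metabolite '",
            table$metabolites$metabolite_id[zero_rows[1]], "'")
    }
    for (i in zero_rows) {
      pos <- vals[i, ][vals[i, ] > 0]
      if (length(pos) == 0L) {
        stop2("log_transform: metabolite '",
              table$metabolites$metabolite_id[i],
              "' is all zero; cannot impute")
      }
      z <- vals[i, ] == 0
      n_zero <- n_zero + sum(z)
      vals[i, z] <- min(pos) / 2
    }
  }
  out <- abundance_table(log(vals, base = base), table$metabolites,
                         table$samples,
                         scale = if (base == 2) "log2" else "log10")
  attr(out, "zeros_imputed") <- n_zero
  out
}
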