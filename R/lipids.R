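# Lipid shorthand parsing, class aggregation, and acylcarnitine
# chain-length binning (short C2-C6, medium C7-C12, long C13-C22).

LIPID_CLASSES <- c("TG", "DG", "PC", "PE", "PI", "PS", "PG", "FA",
                   "CER", "ACAR", "OTHER")

chain_bin_from_carbons <- function(carbons) {
  ifelse(is.na(carbons), NA_character_,
         ifelse(carbons >= 2 & carbons <= 6, "short",
                ifelse(carbons >= 7 & carbons <= 12, "medium",
                       ifelse(carbons >= 13 & carbons <= 22, "long",
                              NA_character_))))
}

#' Parse lipid shorthand names into class annotations
#'
#' Minimal grammar: `CLASS(C:D)` (e.g. `"TG(52:2)"`) gives the class from
#' the prefix token, total acyl carbons C and double bonds D.  `CAR(n:d)`
#' and `"...carnitine Cn"` map to acylcarnitines (`ACAR`) with a
#' chain-length bin (short C2-C6, medium C7-C12, long C13-C22).
#' Anything unrecognized falls back to `OTHER`; the parser never raises.
#'
#' @param names Character vector of putative metabolite names.
#' @return Data frame with columns `putative_name`, `lipid_class`,
#'   `carbons`, `double_bonds`, `chain_bin`.
#' @export
parse_lipid_name <- function(names) {
  n <- length(names)
  out <- data.frame(putative_name = names,
                    lipid_class = rep("OTHER", n),
                    carbons = rep(NA_integer_, n),
                    double_bonds = rep(NA_integer_, n),
                    chain_bin = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  m <- regmatches(names,
                  regexec("^([A-Za-z]+)\\s*\\((\\d+):(\\d+)\\)", names))
  for (i in seq_len(n)) {
    if (length(m[[i]]) == 4L) {
      cls <- toupper(m[[i]][2])
      if (cls == "CAR") cls <- "ACAR"
      if (cls %in% LIPID_CLASSES) {
        out$lipid_class[i] <- cls
        out$carbons[i] <- as.integer(m[[i]][3])
        out$double_bonds[i] <- as.integer(m[[i]][4])
      }
    } else {
      cm <- regmatches(names[i],
                       regexec("carnitine\\s+C(\\d+)", names[i],
                               ignore.case = TRUE))[[1]]
      if (length(cm) == 2L) {
        out$lipid_class[i] <- "ACAR"
        out$carbons[i] <- as.integer(cm[2])
      }
    }
  }
  acar <- out$lipid_class == "ACAR"
  out$chain_bin[acar] <- chain_bin_from_carbons(out$carbons[acar])
  out
}

# resolve annotations: either a parse_lipid_name-style data frame keyed
# by metabolite_id, or NULL -> parse the table's putative names
resolve_annotations <- function(table, annotations) {
  if (is.null(annotations)) {
    ann <- parse_lipid_name(table$metabolites$putative_name)
    ann$metabolite_id <- table$metabolites$metabolite_id
    return(ann)
  }
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "lipid_class") %in% names(ann))) {
    stop2("annotations need columns metabolite_id, lipid_class")
  }
  missing <- setdiff(table$metabolites$metabolite_id, ann$metabolite_id)
  if (length(missing)) {
    message("lipids: ", length(missing),
            " metabolite(s) without annotation treated as OTHER")
    ann <- rbind(ann[, c("metabolite_id", "lipid_class")],
                 data.frame(metabolite_id = missing,
                            lipid_class = "OTHER",
                            stringsAsFactors = FALSE))
  }
  ann
}

#' Per-class total intensities over significantly altered metabolites
#'
#' For each lipid class, sums raw peak intensities over the metabolites
#' whose ANOVA p-value is below `alpha`, separately per group.  Classes
#' with no qualifying metabolite report zero totals.
#'
#' @param table A raw-scale [abundance_table()].
#' @param trend_calls A [run_trend_analysis()] result covering the
#'   table's metabolites (fitted on the log2 table; only `anova_p` is
#'   used here).
#' @param annotations Optional data frame (`metabolite_id`,
#'   `lipid_class`); default parses the table's putative names.
#' @param alpha Significance cut for "significantly altered"
#'   (default 0.05); `alpha = 1` includes every annotated species.
#' @param statistic `"sum"` (default) or `"mean"` per group.
#' @return Data frame, one row per lipid class: per-group totals and
#'   `n_metabolites_included`.
#' @export
class_totals <- function(table, trend_calls, annotations = NULL,
                         alpha = 0.05, statistic = c("sum", "mean")) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(trend_calls, "trend_analysis"))
  statistic <- match.arg(statistic)
  if (table$scale != "raw") {
    stop2("class_totals: peak-intensity totals need the raw-scale table")
  }
  ids <- table$metabolites$metabolite_id
  pv <- trend_calls$calls$anova_p[match(ids,
                                        trend_calls$calls$metabolite_id)]
  if (anyNA(pv)) {
    stop2("class_totals: trend call missing for metabolite '",
          ids[which(is.na(pv))[1]], "'")
  }
  ann <- resolve_annotations(table, annotations)
  cls <- ann$lipid_class[match(ids, ann$metabolite_id)]
  groups <- table$samples$group
  glev <- levels(groups)
  res <- lapply(LIPID_CLASSES, function(cl) {
    rows <- which(cls == cl & pv < alpha)
    tot <- if (length(rows) == 0L) {
      stats::setNames(rep(0, length(glev)), glev)
    } else {
      sub <- table$values[rows, , drop = FALSE]
      vapply(glev, function(g) {
        v <- sub[, groups == g, drop = FALSE]
        if (statistic == "sum") sum(v) else mean(colSums(v))
      }, numeric(1))
    }
    cbind(data.frame(lipid_class = cl, stringsAsFactors = FALSE),
          as.data.frame(as.list(tot), check.names = FALSE),
          data.frame(n_metabolites_included = length(rows)))
  })
  do.call(rbind, res)
}

#' Contingency of lipid class by trend group
#'
#' @param trend_calls A [run_trend_analysis()] result.
#' @param annotations Data frame (`metabolite_id`, `lipid_class`); any
#'   metabolite without annotation counts as OTHER.
#' @return Contingency table (classes x the five trend groups); row
#'   marginals equal class sizes.
#' @export
class_trend_distribution <- function(trend_calls, annotations) {
  stopifnot(inherits(trend_calls, "trend_analysis"))
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  ids <- trend_calls$calls$metabolite_id
  cls <- ann$lipid_class[match(ids, ann$metabolite_id)]
  cls[is.na(cls)] <- "OTHER"
  table(lipid_class = factor(cls, levels = LIPID_CLASSES),
        trend_group = trend_calls$calls$trend_group)
}
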