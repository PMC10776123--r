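# Reading and writing the tabular and graph artifacts of the pipeline.
# Abundance and metadata tables travel as CSV/TSV (delimiter sniffed from
# the extension, overridable); networks as GraphML or whitespace edge
# lists; summaries as JSON.

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Construct an abundance table
#'
#' The central container of the pipeline: a metabolites x samples matrix of
#' intensities plus metabolite records (id, putative name, identification
#' confidence) and sample metadata (id, ordered age/treatment group,
#' replicate index).  `scale` records the transform state: `"raw"` on
#' input, `"log2"`/`"log10"` after [log_transform()].
#'
#' @param values Numeric matrix, metabolites in rows, samples in columns.
#' @param metabolites Data frame with columns `metabolite_id`,
#'   `putative_name`, `confidence`.
#' @param samples Data frame with columns `sample_id`, `group` (coerced to
#'   an ordered factor; ordering taken from the factor levels or first
#'   appearance), and optionally `replicate_index`.
#' @param scale One of `"raw"`, `"log2"`, `"log10"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, metabolites, samples, scale = "raw") {
  scale <- match.arg(scale, c("raw", "log2", "log10"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop2("abundance_table: values contain NA")
  if (scale == "raw" && any(values < 0)) {
    stop2("abundance_table: raw-scale intensities must be >= 0")
  }
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "putative_name", "confidence")
  if (!all(need %in% names(metabolites))) {
    stop2("abundance_table: metabolites needs columns ",
          paste(need, collapse = ", "))
  }
  if (anyDuplicated(metabolites$metabolite_id)) {
    stop2("abundance_table: duplicated metabolite_id: ",
          metabolites$metabolite_id[duplicated(metabolites$metabolite_id)][1])
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop2("abundance_table: samples needs columns sample_id, group")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop2("abundance_table: duplicated sample_id: ",
          samples$sample_id[duplicated(samples$sample_id)][1])
  }
  if (!is.factor(samples$group)) {
    samples$group <- factor(samples$group, levels = unique(samples$group))
  }
  samples$group <- factor(samples$group, levels = levels(samples$group),
                          ordered = TRUE)
  if (is.null(samples$replicate_index)) {
    samples$replicate_index <- stats::ave(
      seq_along(samples$sample_id), samples$group, FUN = seq_along)
  }
  if (nrow(values) != nrow(metabolites)) {
    stop2("abundance_table: ", nrow(values), " value rows but ",
          nrow(metabolites), " metabolite records")
  }
  if (ncol(values) != nrow(samples)) {
    stop2("abundance_table: ", ncol(values), " value columns but ",
          nrow(samples), " sample records")
  }
  rownames(values) <- metabolites$metabolite_id
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, metabolites = metabolites, samples = samples,
         scale = scale),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table: ", nrow(x$values), " metabolites x ",
      ncol(x$values), " samples (", x$scale, " scale)\n", sep = "")
  cat("Groups:", paste(sprintf("%s (n=%d)", levels(x$samples$group),
                               tabulate(x$samples$group)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table and its sample metadata
#'
#' Expects a delimited file whose first three columns are
#' `metabolite_id`, `putative_name`, `confidence`, followed by one numeric
#' column per sample, and a metadata file mapping every sample column to a
#' group (columns `sample_id`, `group`, optional `replicate_index`).
#'
#' @param path Path to the abundance CSV/TSV.
#' @param meta_path Path to the sample metadata CSV/TSV.
#' @param sep,meta_sep Field delimiters; default sniffed from extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, meta_path, sep = NULL,
                                 meta_sep = NULL) {
  if (!file.exists(path)) stop2("read_abundance_table: no such file: ", path)
  if (!file.exists(meta_path)) {
    stop2("read_abundance_table: no such metadata file: ", meta_path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sniff_sep(path, sep),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop2("read_abundance_table: empty table: ", path)
  need <- c("metabolite_id", "putative_name", "confidence")
  if (!all(need %in% names(raw)[1:3])) {
    stop2("read_abundance_table: first columns must be ",
          paste(need, collapse = ", "))
  }
  meta <- utils::read.table(meta_path, header = TRUE,
                            sep = sniff_sep(meta_path, meta_sep),
                            stringsAsFactors = FALSE)
  sample_cols <- setdiff(names(raw), need)
  missing <- setdiff(sample_cols, meta$sample_id)
  if (length(missing)) {
    stop2("read_abundance_table: sample(s) missing from metadata: ",
          paste(missing, collapse = ", "))
  }
  vals <- raw[, sample_cols, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop2("read_abundance_table: non-numeric intensity at row ", bad,
            ", column '", sample_cols[j], "'")
    }
  }
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  abundance_table(as.matrix(vals), raw[, need], meta)
}

#' Write an abundance table (and its metadata) to delimited files
#'
#' Inverse of [read_abundance_table()]: values are written in full double
#' precision so a read round-trip reproduces the table.
#'
#' @param table An [abundance_table()].
#' @param path,meta_path Output paths (delimiter sniffed from extension).
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(table, path, meta_path) {
  stopifnot(inherits(table, "abundance_table"))
  out <- cbind(table$metabolites,
               as.data.frame(table$values, check.names = FALSE))
  utils::write.table(out, path, sep = sniff_sep(path, NULL),
                     row.names = FALSE, quote = FALSE)
  meta <- table$samples
  meta$group <- as.character(meta$group)
  utils::write.table(meta, meta_path, sep = sniff_sep(meta_path, NULL),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a survival cohort from per-individual death weeks
#'
#' @param death_weeks Numeric vector of death weeks, one per animal that
#'   died (week numbers are positive; week t means death observed at the
#'   census of week t).
#' @param censored Optional numeric vector of censoring weeks for animals
#'   last seen alive; censored animals never enter the death tally but
#'   count in the initial cohort size.
#' @param n Initial cohort size; default `length(death_weeks) +
#'   length(censored)`.
#' @return Object of class `survival_cohort` with elements `death_weeks`,
#'   `censored`, `n`.
#' @export
survival_cohort <- function(death_weeks, censored = numeric(0), n = NULL) {
  death_weeks <- as.numeric(death_weeks)
  censored <- as.numeric(censored)
  if (length(death_weeks) == 0L && length(censored) == 0L) {
    stop2("survival_cohort: empty cohort")
  }
  if (any(death_weeks < 0) || any(censored < 0)) {
    stop2("survival_cohort: negative weeks are invalid")
  }
  if (is.null(n)) n <- length(death_weeks) + length(censored)
  if (n < length(death_weeks) + length(censored)) {
    stop2("survival_cohort: n smaller than number of recorded animals")
  }
  structure(list(death_weeks = death_weeks, censored = censored, n = n),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat("Survival cohort: n =", x$n, "|", length(x$death_weeks), "deaths",
      if (length(x$censored)) paste0("| ", length(x$censored), " censored"),
      "\n")
  invisible(x)
}

#' Number alive at each census week
#'
#' Standard life-table bookkeeping: censored animals are removed from the
#' at-risk count after their censoring week but never counted as deaths.
#'
#' @param cohort A [survival_cohort()].
#' @param weeks Census weeks; default every week present in the data.
#' @return Data frame with columns `week` and `alive`.
#' @export
alive_counts <- function(cohort, weeks = NULL) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (is.null(weeks)) {
    weeks <- sort(unique(c(cohort$death_weeks, cohort$censored)))
  }
  alive <- vapply(weeks, function(w) {
    cohort$n - sum(cohort$death_weeks <= w) - sum(cohort$censored <= w)
  }, numeric(1))
  data.frame(week = weeks, alive = alive)
}

#' Read survival data from a delimited file
#'
#' Accepts either per-individual rows (column `death_week`, optional
#' logical/0-1 column `censored`) or a weekly census (columns `week`,
#' `alive`).  The census form is converted to per-individual death weeks
#' (deaths attributed to the census week at which the count dropped);
#' animals still alive at the last census are censored there.
#'
#' @param path Path to CSV/TSV.
#' @param sep Field delimiter, default sniffed from extension.
#' @return A [survival_cohort()].
#' @export
read_survival <- function(path, sep = NULL) {
  if (!file.exists(path)) stop2("read_survival: no such file: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sniff_sep(path, sep),
                      stringsAsFactors = FALSE),
    error = function(e) stop2("read_survival: cannot parse ", path, ": ",
                              conditionMessage(e)))
  if (nrow(tab) == 0L) stop2("read_survival: empty file: ", path)
  if (all(c("week", "alive") %in% names(tab))) {
    tab <- tab[order(tab$week), , drop = FALSE]
    if (any(tab$week < 0)) stop2("read_survival: negative week in ", path)
    if (any(diff(tab$alive) > 0)) {
      w <- tab$week[which(diff(tab$alive) > 0)[1] + 1L]
      stop2("read_survival: alive count increases at week ", w)
    }
    n <- tab$alive[1] + 0  # count before first recorded drop is the cohort
    deaths <- rep(tab$week[-1], pmax(0, -diff(tab$alive)))
    # animals at risk before the first census week: assume cohort size is
    # the first alive count; deaths at the first census are unobservable
    censored <- rep(tab$week[nrow(tab)], tab$alive[nrow(tab)])
    return(survival_cohort(deaths, censored, n = n))
  }
  if ("death_week" %in% names(tab)) {
    if (any(tab$death_week < 0)) {
      stop2("read_survival: negative death week in ", path)
    }
    cens <- if ("censored" %in% names(tab)) as.logical(tab$censored) else
      rep(FALSE, nrow(tab))
    return(survival_cohort(tab$death_week[!cens], tab$death_week[cens]))
  }
  stop2("read_survival: need columns (death_week[, censored]) or ",
        "(week, alive) in ", path)
}

#' Write a survival cohort to CSV
#'
#' @param cohort A [survival_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_survival <- function(cohort, path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  tab <- data.frame(
    death_week = c(cohort$death_weeks, cohort$censored),
    censored = c(rep(FALSE, length(cohort$death_weeks)),
                 rep(TRUE, length(cohort$censored))))
  utils::write.table(tab, path, sep = sniff_sep(path, NULL),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a co-abundance network to GraphML or an edge list
#'
#' Edge attributes `r` and `p_adj` are preserved to 6 significant digits.
#'
#' @param net A [coabundance_network()].
#' @param path Output path.
#' @param format `"graphml"` or `"edge_list"` (whitespace-delimited with
#'   header `from to r p_adj`).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_list")) {
  stopifnot(inherits(net, "coabundance_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    if (igraph::ecount(g) > 0) {
      igraph::E(g)$r <- signif(igraph::E(g)$r, 6)
      igraph::E(g)$p_adj <- signif(igraph::E(g)$p_adj, 6)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    edges <- net$edges
    out <- data.frame(from = edges$from, to = edges$to,
                      r = signif(edges$r, 6),
                      p_adj = signif(edges$p_adj, 6))
    utils::write.table(out, path, sep = " ", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edge_list"`.
#' @return A [coabundance_network()].
#' @export
read_network <- function(path, format = c("graphml", "edge_list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("read_network: no such file: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(
      metabolite_id = igraph::V(g)$name,
      trend_group = if ("trend_group" %in%
                        igraph::vertex_attr_names(g))
        igraph::V(g)$trend_group else NA_character_,
      stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(
      from = el[, 1], to = el[, 2],
      r = if (igraph::ecount(g)) igraph::E(g)$r else numeric(0),
      p_adj = if (igraph::ecount(g)) igraph::E(g)$p_adj else numeric(0),
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE,
                             stringsAsFactors = FALSE)
    edges <- tab
    nodes <- data.frame(
      metabolite_id = unique(c(tab$from, tab$to)),
      trend_group = NA_character_, stringsAsFactors = FALSE)
  }
  coabundance_network(nodes, edges)
}
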