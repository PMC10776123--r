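# End-to-end orchestration: simulate -> preprocess -> trends -> network
# -> influence -> lipids -> mortality -> fibers, with one config object,
# key=value logging and a deterministic result bundle.

#' Default pipeline configuration
#'
#' All stage parameters in one serializable list: significance level
#' (0.05), edge rule (r > 0.7, adjusted p < 0.01), MCL and IVI settings,
#' inflection settings, and the synthetic-data sizes used by the demo.
#'
#' @param alpha ANOVA/Tukey significance level.
#' @param r_min,p_max Co-abundance edge thresholds.
#' @param inflation MCL inflation.
#' @param ci_radius IVI collective-influence radius.
#' @param max_points Maximum inflection points.
#' @param n_metabolites,n_per_group,cohort_n Demo sizes.
#' @param seed Master seed for all synthetic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, r_min = 0.7, p_max = 0.01,
                            inflation = 2, ci_radius = 3, max_points = 2,
                            n_metabolites = 500, n_per_group = 7,
                            cohort_n = 10000, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, r_min >= -1, r_min <= 1,
            p_max > 0, p_max <= 1)
  structure(list(alpha = alpha, r_min = r_min, p_max = p_max,
                 inflation = inflation, ci_radius = ci_radius,
                 max_points = max_points, n_metabolites = n_metabolites,
                 n_per_group = n_per_group, cohort_n = cohort_n,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_line <- function(stage, ...) {
  kv <- c(...)
  message(format(Sys.time(), "%H:%M:%S"), " stage=", stage,
          if (length(kv)) paste0(" ", paste(names(kv), kv, sep = "=",
                                            collapse = " ")))
}

#' Run the whole pipeline on synthetic data
#'
#' One-command demo: generates an abundance table with the default trend
#' mixture, modules and hubs plus a Gompertz-plateau cohort and fiber
#' areas, then runs every analysis stage.  Deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes the abundance
#'   and truth CSVs, trend-call TSV, GraphML network, module and IVI
#'   TSVs, class-summary TSV, mortality TSV and a JSON summary.
#' @return Invisibly, a list with every stage result (`table`, `truth`,
#'   `trends`, `network`, `modules`, `centralities`, `ivi`, `ranking`,
#'   `lipid_totals`, `mortality`, `inflections`, `fibers`).
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  log_line("simulate", c(n_metabolites = config$n_metabolites,
                         n_per_group = config$n_per_group, seed = seed))
  specs <- trend_mixture(config$n_metabolites)
  n_mod <- max(1L, config$n_metabolites %/% 100L)
  modules <- replicate(n_mod, module_spec(20), simplify = FALSE)
  sim <- generate_abundance(specs, n_per_group = config$n_per_group,
                            modules = modules, seed = seed,
                            hub_count = 2, lipid_fraction = 0.3)

  log_line("preprocess", c(metabolites = nrow(sim$table$values)))
  dedup <- deduplicate(sim$table)
  log2_tab <- log_transform(dedup, base = 2)
  log10_tab <- log_transform(dedup, base = 10)

  log_line("trends", c(alpha = config$alpha))
  trends <- run_trend_analysis(log2_tab, alpha = config$alpha)

  log_line("network", c(r_min = config$r_min, p_max = config$p_max))
  net <- correlation_edges(log10_tab, r_min = config$r_min,
                           p_max = config$p_max, trend_calls = trends)
  modules_found <- mcl_cluster(net, mcl_config(inflation = config$inflation))

  log_line("influence", c(ci_radius = config$ci_radius))
  cent <- centralities(net, ivi_config(config$ci_radius))
  scores <- ivi(cent)
  ranking <- rank_influential(scores, cent, trends, k = 15)

  log_line("lipids")
  totals <- class_totals(dedup, trends, alpha = config$alpha)

  log_line("mortality", c(cohort_n = config$cohort_n))
  surv <- generate_survival(three_phase_survival_spec(n = config$cohort_n,
                                                      seed = seed))
  series <- cumulative_mortality(surv)
  inflections <- find_inflections(series, max_points = config$max_points)

  log_line("fibers")
  areas <- generate_fiber_areas(2000, seed = seed)
  fibers <- classify_fibers(areas)

  result <- list(table = sim$table, truth = sim$truth, trends = trends,
                 network = net, modules = modules_found,
                 centralities = cent, ivi = scores, ranking = ranking,
                 lipid_totals = totals, mortality = series,
                 inflections = inflections, fibers = fibers)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_abundance_table(sim$table, p("abundance.csv"), p("samples.csv"))
    utils::write.table(sim$truth, p("truth.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(trends$calls, p("trend_calls.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_network(net, p("network.graphml"), "graphml")
    utils::write.table(
      data.frame(metabolite_id = names(modules_found$membership),
                 module = modules_found$membership),
      p("modules.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    ivi_tab <- data.frame(metabolite_id = names(scores), IVI = scores)
    utils::write.table(ivi_tab, p("ivi.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(totals, p("lipid_class_totals.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(series), p("mortality.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           trend_proportions = as.list(trends$proportions),
           n_edges = nrow(net$edges),
           n_modules = modules_found$n_clusters,
           top15 = ranking$top$metabolite_id,
           inflection_weeks = inflections$inflection_weeks,
           fiber_counts = as.list(fibers$counts)),
      p("summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
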