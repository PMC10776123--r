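# Integrated Value of Influence (IVI): a composite node-influence score
# combining six centralities after range normalization to [1, 100]:
#
#   Hubness   = DC' + LH'            (degree, local H-index)
#   Spreading = (NC' + CR') * (BC' + CI')
#               (neighborhood connectivity, ClusterRank, betweenness,
#                collective influence at radius l)
#   IVI       = range-normalize(Hubness * Spreading) to [1, 100]
#
# Only relative ranks survive the normalization, so unnormalized
# betweenness is used and the choice is inert.

#' IVI configuration
#'
#' @param ci_radius Frontier radius l for collective influence
#'   (default 3); an empty frontier contributes 0.
#' @return List of class `ivi_config`.
#' @export
ivi_config <- function(ci_radius = 3L) {
  if (ci_radius < 1) stop2("ivi_config: ci_radius >= 1")
  structure(list(ci_radius = as.integer(ci_radius)), class = "ivi_config")
}

# H-index of a vector of neighbor degrees: largest h with >= h entries >= h
h_index <- function(degs) {
  if (length(degs) == 0L) return(0)
  s <- sort(degs, decreasing = TRUE)
  sum(s >= seq_along(s))
}

#' Six node centralities for the IVI composite
#'
#' For each node i of an undirected simple graph:
#' degree `DC`; neighborhood connectivity `NC` (mean neighbor degree, 0
#' if isolated); unnormalized shortest-path betweenness `BC`; local
#' H-index `LH(i) = h(i) + sum of h(j) over neighbors j`, where `h(i)` is
#' the largest h such that at least h neighbors of i have degree >= h;
#' ClusterRank `CR(i) = 10^(-c_i) * sum over neighbors (deg(j) + 1)` with
#' `c_i` the local clustering coefficient (0 for degree < 2); and
#' collective influence `CI(i) = (deg(i) - 1) * sum of (deg(j) - 1) over
#' nodes j at exactly distance l`.
#'
#' @param net A [coabundance_network()].
#' @param config An [ivi_config()].
#' @return Object of class `centrality_table`: data frame with the raw
#'   centralities (`DC`, `NC`, `BC`, `LH`, `CR`, `CI`) and their
#'   `[1, 100]` range-normalized versions (suffix `_n`), one row per node.
#' @export
centralities <- function(net, config = ivi_config()) {
  stopifnot(inherits(net, "coabundance_network"),
            inherits(config, "ivi_config"))
  ids <- net$nodes$metabolite_id
  nv <- length(ids)
  if (nv == 0L) {
    out <- data.frame(metabolite_id = character(0))
    class(out) <- c("centrality_table", "data.frame")
    return(out)
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  nbrs <- igraph::adjacent_vertices(g, igraph::V(g))
  nc <- vapply(nbrs, function(v) {
    if (length(v) == 0L) 0 else mean(deg[v])
  }, numeric(1))
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  h <- vapply(nbrs, function(v) h_index(deg[v]), numeric(1))
  lh <- h + vapply(nbrs, function(v) sum(h[v]), numeric(1))
  ci_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci_local[deg < 2] <- 0  # degree-1 convention: undefined clustering -> 0
  cr <- 10^(-ci_local) * vapply(nbrs, function(v) {
    if (length(v) == 0L) 0 else sum(deg[v] + 1)
  }, numeric(1))
  dmat <- igraph::distances(g)
  ci <- vapply(seq_len(nv), function(i) {
    frontier <- which(dmat[i, ] == config$ci_radius)
    (deg[i] - 1) * sum(deg[frontier] - 1)
  }, numeric(1))
  out <- data.frame(
    metabolite_id = ids,
    DC = as.numeric(deg), NC = nc, BC = as.numeric(bc),
    LH = lh, CR = cr, CI = ci,
    stringsAsFactors = FALSE, row.names = NULL)
  for (col in c("DC", "NC", "BC", "LH", "CR", "CI")) {
    out[[paste0(col, "_n")]] <- range_normalize(out[[col]])
  }
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Integrated Value of Influence per node
#'
#' Combines the normalized centralities as
#' `IVI = range-normalize((DC' + LH') * ((NC' + CR') * (BC' + CI')))`.
#' A graph where all centralities are constant (e.g. any regular,
#' vertex-transitive graph) yields IVI = 1 for every node by the
#' constant-vector convention of [range_normalize()].
#'
#' @param cent A [centralities()] table.
#' @return Named numeric vector of IVI scores in `[1, 100]`.
#' @export
ivi <- function(cent) {
  stopifnot(inherits(cent, "centrality_table"))
  if (nrow(cent) == 0L) return(stats::setNames(numeric(0), character(0)))
  hubness <- cent$DC_n + cent$LH_n
  spreading <- (cent$NC_n + cent$CR_n) * (cent$BC_n + cent$CI_n)
  stats::setNames(range_normalize(hubness * spreading),
                  cent$metabolite_id)
}

#' Top-k most influential nodes with trend annotation
#'
#' @param ivi_scores Named vector from [ivi()].
#' @param cent The matching [centralities()] table (supplies the degree
#'   tie-break).
#' @param trend_calls Optional [run_trend_analysis()] result; adds each
#'   node's trend group and tabulates groups within the top k.
#' @param k Number of nodes to return (default 15).  `k` larger than the
#'   node count returns everything with a warning.
#' @return Object of class `influence_ranking`: list with `top` (data
#'   frame: rank, metabolite_id, IVI, DC, trend_group) and `group_counts`.
#' @export
rank_influential <- function(ivi_scores, cent, trend_calls = NULL, k = 15) {
  stopifnot(inherits(cent, "centrality_table"))
  ids <- names(ivi_scores)
  if (!identical(sort(ids), sort(cent$metabolite_id))) {
    stop2("rank_influential: node sets of ivi_scores and cent differ")
  }
  if (k > length(ids)) {
    warning("rank_influential: k = ", k, " exceeds node count ",
            length(ids), "; returning all nodes", call. = FALSE)
    k <- length(ids)
  }
  dc <- cent$DC[match(ids, cent$metabolite_id)]
  ord <- order(-ivi_scores, -dc, ids)
  sel <- utils::head(ord, k)
  top <- data.frame(rank = seq_along(sel),
                    metabolite_id = ids[sel],
                    IVI = unname(ivi_scores[sel]),
                    DC = dc[sel],
                    stringsAsFactors = FALSE)
  top$trend_group <- rep(NA_character_, nrow(top))
  if (!is.null(trend_calls)) {
    stopifnot(inherits(trend_calls, "trend_analysis"))
    top$trend_group <- as.character(
      trend_calls$calls$trend_group[match(top$metabolite_id,
                                          trend_calls$calls$metabolite_id)])
  }
  counts <- table(factor(top$trend_group, levels = TREND_GROUPS))
  structure(list(top = top, group_counts = counts, k = k),
            class = "influence_ranking")
}

#' @export
print.influence_ranking <- function(x, ...) {
  cat("Top-", x$k, " nodes by IVI:\n", sep = "")
  print(x$top, row.names = FALSE)
  if (!all(is.na(x$top$trend_group))) {
    cat("\nTrend groups within top-", x$k, ":\n", sep = "")
    print(x$group_counts)
  }
  invisible(x)
}
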