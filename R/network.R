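# Co-abundance network inference and Markov Clustering.
#
# Edges connect metabolite pairs whose abundances across all samples have
# Pearson r > r_min (0.7) and Benjamini-Hochberg adjusted p < p_max (0.01);
# the rule is one-sided as printed, so strong anti-correlations are not
# edges.  MCL is implemented from scratch on the column-stochastic
# transition matrix with unit self-loops.

#' Construct a co-abundance network
#'
#' @param nodes Data frame with columns `metabolite_id` and optionally
#'   `trend_group`; isolated nodes are legitimate members.
#' @param edges Data frame with columns `from`, `to`, `r`, `p_adj`.
#'   Stored in canonical order (`from` before `to` in node order); self
#'   loops and duplicate pairs are errors.
#' @return Object of class `coabundance_network`.
#' @export
coabundance_network <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"metabolite_id" %in% names(nodes)) {
    stop2("coabundance_network: nodes needs column metabolite_id")
  }
  if (anyDuplicated(nodes$metabolite_id)) {
    stop2("coabundance_network: duplicated node id")
  }
  if (is.null(nodes$trend_group)) {
    nodes$trend_group <- rep(NA_character_, nrow(nodes))
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        r = numeric(0), p_adj = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("from", "to", "r", "p_adj")
    if (!all(need %in% names(edges))) {
      stop2("coabundance_network: edges need columns ",
            paste(need, collapse = ", "))
    }
    edges <- edges[, need]
    idx_f <- match(edges$from, nodes$metabolite_id)
    idx_t <- match(edges$to, nodes$metabolite_id)
    if (anyNA(idx_f) || anyNA(idx_t)) {
      bad <- c(edges$from[is.na(idx_f)], edges$to[is.na(idx_t)])[1]
      stop2("coabundance_network: edge endpoint '", bad, "' not in nodes")
    }
    if (any(idx_f == idx_t)) stop2("coabundance_network: self loop")
    swap <- idx_f > idx_t
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to))) {
      stop2("coabundance_network: duplicate edge")
    }
    edges <- edges[order(match(edges$from, nodes$metabolite_id),
                         match(edges$to, nodes$metabolite_id)), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges),
            class = "coabundance_network")
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat("Co-abundance network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a co-abundance network to an igraph object
#'
#' @param net A [coabundance_network()].
#' @return An undirected simple `igraph` graph with vertex attribute
#'   `trend_group` and edge attributes `r`, `p_adj`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coabundance_network"))
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$metabolite_id,
                          trend_group = net$nodes$trend_group,
                          stringsAsFactors = FALSE))
  g
}

#' Build the co-abundance network from an abundance table
#'
#' Pearson correlation across all samples of all time points for every
#' unique metabolite pair; two-sided p from the t distribution with
#' `n_samples - 2` degrees of freedom; p-values adjusted over all unique
#' pairs (Benjamini-Hochberg by default).  A pair becomes an edge iff
#' `r > r_min` (strict) and `p_adj < p_max` (strict).  Metabolites with
#' zero variance cannot be correlated and are excluded from pairing with
#' a warning, but remain in the node set.
#'
#' @param table A log-scale [abundance_table()] (log10 conventionally for
#'   comparative analyses).
#' @param r_min Correlation threshold, default 0.7.
#' @param p_max Adjusted-p threshold, default 0.01.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param use_absolute If `TRUE`, threshold `|r|` instead of `r`
#'   (off by default; the printed rule keeps positive co-abundance only).
#' @param trend_calls Optional [run_trend_analysis()] result used to
#'   annotate nodes with their trend group.
#' @return A [coabundance_network()].
#' @export
correlation_edges <- function(table, r_min = 0.7, p_max = 0.01,
                              adjust = c("BH", "bonferroni"),
                              use_absolute = FALSE, trend_calls = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  adjust <- match.arg(adjust)
  n <- ncol(table$values)
  if (n < 4) stop2("correlation_edges: need >= 4 samples, got ", n)
  ids <- table$metabolites$metabolite_id
  sds <- apply(table$values, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("correlation_edges: ", sum(constant),
            " constant metabolite(s) excluded from pairing: ",
            paste(utils::head(ids[constant], 5), collapse = ", "),
            call. = FALSE)
  }
  use <- which(!constant)
  edges <- NULL
  if (length(use) >= 2) {
    cm <- stats::cor(t(table$values[use, , drop = FALSE]))
    ut <- upper.tri(cm)
    r <- cm[ut]
    # clamp rounding excursions beyond +/-1 before the t transform
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[abs(r) == 1] <- 0
    p_adj <- stats::p.adjust(p, method = adjust)
    ii <- row(cm)[ut]
    jj <- col(cm)[ut]
    keep <- (if (use_absolute) abs(r) else r) > r_min & p_adj < p_max
    edges <- data.frame(from = ids[use[ii[keep]]],
                        to = ids[use[jj[keep]]],
                        r = r[keep], p_adj = p_adj[keep],
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(metabolite_id = ids, stringsAsFactors = FALSE)
  if (!is.null(trend_calls)) {
    stopifnot(inherits(trend_calls, "trend_analysis"))
    nodes$trend_group <- as.character(
      trend_calls$calls$trend_group[match(ids,
                                          trend_calls$calls$metabolite_id)])
  }
  coabundance_network(nodes, edges)
}

#' MCL configuration
#'
#' @param expansion Matrix power per iteration (integer >= 2, default 2).
#' @param inflation Elementwise power (> 1, default 2); larger values give
#'   finer clusters.
#' @param prune_threshold Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance on the max absolute column change
#'   (default 1e-6).
#' @return List of class `mcl_config`.
#' @export
mcl_config <- function(expansion = 2L, inflation = 2, prune_threshold = 1e-5,
                       max_iter = 100L, tol = 1e-6) {
  if (expansion < 2) stop2("mcl_config: expansion >= 2")
  if (inflation <= 1) stop2("mcl_config: inflation > 1")
  structure(list(expansion = as.integer(expansion), inflation = inflation,
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_config")
}

#' Markov Clustering of a co-abundance network
#'
#' From-scratch MCL: the adjacency matrix (unit self-loops added as
#' regularization) is column-normalized to a transition matrix, then
#' expansion (matrix power), inflation (elementwise power followed by
#' column renormalization) and pruning alternate until the matrix is
#' stable.  Clusters are read off the attractor structure: rows with
#' nonzero diagonal are attractors, and every node joins the cluster of
#' the attractors that reach it; overlapping attractor systems are merged
#' so the result is a partition.  Isolated nodes form singletons.
#'
#' @param net A [coabundance_network()].
#' @param config An [mcl_config()].
#' @return Object of class `mcl_result`: list with `membership` (named
#'   integer vector, cluster id per node), `n_clusters`, `iterations`,
#'   `converged`.
#' @export
mcl_cluster <- function(net, config = mcl_config()) {
  stopifnot(inherits(net, "coabundance_network"),
            inherits(config, "mcl_config"))
  ids <- net$nodes$metabolite_id
  nv <- length(ids)
  if (nv == 0L) stop2("mcl_cluster: empty node set")
  A <- matrix(0, nv, nv, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, ids)
    ti <- match(net$edges$to, ids)
    A[cbind(fi, ti)] <- 1
    A[cbind(ti, fi)] <- 1
  }
  diag(A) <- 1  # self-loop regularization
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    M_old <- M
    # expansion: M^e
    E <- M
    for (e in seq_len(config$expansion - 1L)) E <- E %*% M
    # inflation + pruning + renormalization
    E <- E ^ config$inflation
    E[E < config$prune_threshold] <- 0
    cs <- colSums(E)
    dead <- cs == 0
    if (any(dead)) {  # fully pruned column: restore self transition
      E[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M <- sweep(E, 2, cs, "/")
    if (max(abs(M - M_old)) < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("mcl_cluster: not converged after ", config$max_iter,
            " iterations", call. = FALSE)
  }
  # attractor interpretation: connect i--j when M[i, j] > 0 and i is an
  # attractor (nonzero row maximum on its own diagonal region); taking
  # weakly-connected components of the support graph merges overlapping
  # attractor systems into a partition.
  support <- M > 0
  g <- igraph::graph_from_adjacency_matrix(support | t(support),
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  membership <- stats::setNames(as.integer(factor(comp)), ids)
  structure(list(membership = membership,
                 n_clusters = length(unique(membership)),
                 iterations = iter, converged = converged),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  cat("MCL clustering:", x$n_clusters, "modules over",
      length(x$membership), "nodes (", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' items; used to score recovered modules against planted truth.
#'
#' @param a,b Vectors of cluster labels (same length).
#' @return Numeric scalar; 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  ntot <- comb2(length(a))
  expected <- sum_a * sum_b / ntot
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
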