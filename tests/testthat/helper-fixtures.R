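# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately written without the package's own code paths:
# ANOVA/Tukey via stats::aov/TukeyHSD, correlations via cor.test, graph
# centralities via adjacency-matrix hand computations.

make_table <- function(values, groups, ids = NULL, names = NULL,
                       confidence = NULL, scale = "raw") {
  values <- as.matrix(values)
  n_met <- nrow(values)
  n_samp <- ncol(values)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(n_met))
  if (is.null(names)) names <- ids
  if (is.null(confidence)) confidence <- rep(5, n_met)
  abundance_table(
    values,
    data.frame(metabolite_id = ids, putative_name = names,
               confidence = confidence, stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("S%02d", seq_len(n_samp)),
               group = groups, stringsAsFactors = FALSE),
    scale = scale)
}

# table with one row per planted direction at a given effect
planted_table <- function(directions, n_per_group = 7, effect = 2,
                          sd = 0.3, seed = 1) {
  specs <- lapply(directions, trend_spec, effect_size = effect,
                  noise_sd = sd)
  generate_abundance(specs, n_per_group = n_per_group, seed = seed)
}

oracle_anova_tukey <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  # TukeyHSD labels rows "B-A", "C-A", "C-B"; map to AB, AC, BC
  lev <- levels(groups)
  lab <- stats::setNames(LETTERS[seq_along(lev)], lev)
  rn <- vapply(strsplit(rownames(tk), "-"), function(p) {
    paste0(sort(c(lab[[p[2]]], lab[[p[1]]])), collapse = "")
  }, character(1))
  list(F = s$`F value`[1], p = s$`Pr(>F)`[1],
       tukey_p = stats::setNames(tk[, "p adj"], rn))
}

# ---- graph oracles (igraph-free) -------------------------------------

# adjacency matrix of a random simple graph
random_adj <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

adj_to_network <- function(A, ids = NULL) {
  n <- nrow(A)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
               r = 0.9, p_adj = 1e-5, stringsAsFactors = FALSE)
  } else NULL
  coabundance_network(data.frame(metabolite_id = ids), edges)
}

# all-pairs shortest-path distances by BFS
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# unnormalized shortest-path betweenness by exhaustive path enumeration
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  # count shortest paths s->t through recursion on predecessors
  nsp <- function(s, t) {
    if (s == t) return(1)
    preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
    sum(vapply(preds, function(p) nsp(s, p), numeric(1)))
  }
  nsp_via <- function(s, t, v) {
    if (!is.finite(D[s, v]) || !is.finite(D[v, t])) return(0)
    if (D[s, v] + D[v, t] != D[s, t]) return(0)
    nsp(s, v) * nsp(v, t)
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      tot <- tot + nsp_via(s, t, v) / nsp(s, t)
    }
    bc[v] <- tot
  }
  bc
}

bf_h_index <- function(degs) {
  if (!length(degs)) return(0)
  h <- 0
  for (cand in seq_len(max(degs))) {
    if (sum(degs >= cand) >= cand) h <- cand
  }
  h
}

bf_centralities <- function(A, radius = 3) {
  n <- nrow(A)
  deg <- rowSums(A)
  D <- bf_distances(A)
  nc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) 0 else mean(deg[nb])
  }, numeric(1))
  h <- vapply(seq_len(n), function(i) {
    bf_h_index(deg[which(A[i, ] > 0)])
  }, numeric(1))
  lh <- vapply(seq_len(n), function(i) {
    h[i] + sum(h[which(A[i, ] > 0)])
  }, numeric(1))
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  cr <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (!length(nb)) return(0)
    10^(-cc[i]) * sum(deg[nb] + 1)
  }, numeric(1))
  ci <- vapply(seq_len(n), function(i) {
    frontier <- which(D[i, ] == radius)
    (deg[i] - 1) * sum(deg[frontier] - 1)
  }, numeric(1))
  data.frame(DC = deg, NC = nc, BC = bf_betweenness(A), LH = lh,
             CR = cr, CI = ci)
}

# planted two-hub graph: three dense modules plus two hubs wired to a
# fixed fraction of every module (the influence-module test bed)
planted_hub_graph <- function(module_size = 20, p_within = 0.3,
                              hub_frac = 0.5, n_bridge = 3, seed = 1) {
  set.seed(seed)
  n <- 3 * module_size
  A <- matrix(0, n + 2, n + 2)
  for (m in 0:2) {
    idx <- m * module_size + seq_len(module_size)
    block <- matrix(0, module_size, module_size)
    block[upper.tri(block)] <-
      stats::rbinom(module_size * (module_size - 1) / 2, 1, p_within)
    A[idx, idx] <- block + t(block)
  }
  for (b in seq_len(n_bridge)) {
    pair <- sample(n, 2)
    A[pair[1], pair[2]] <- A[pair[2], pair[1]] <- 1
  }
  for (hub in n + 1:2) {
    for (m in 0:2) {
      idx <- m * module_size + seq_len(module_size)
      tgt <- sample(idx, round(hub_frac * module_size))
      A[hub, tgt] <- A[tgt, hub] <- 1
    }
  }
  diag(A) <- 0
  ids <- c(sprintf("n%02d", seq_len(n)), "hubA", "hubB")
  adj_to_network(A, ids)
}
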