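test_that("edge set equals a brute-force pairwise computation", {
  set.seed(21)
  # 30 metabolites, one planted module of 10, 21 samples
  specs <- replicate(30, trend_spec("no_change"), simplify = FALSE)
  sim <- generate_abundance(specs, n_per_group = 7,
                            modules = list(module_spec(10, loading = 0.9)),
                            seed = 15)
  tab <- log_transform(sim$table, base = 10)
  net <- correlation_edges(tab)

  # oracle: double loop over unique pairs with cor.test + BH
  vals <- tab$values
  n <- nrow(vals)
  pairs <- t(combn(n, 2))
  r <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ct <- cor.test(vals[pairs[k, 1], ], vals[pairs[k, 2], ])
    r[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  p_adj <- p.adjust(p, "BH")
  keep <- r > 0.7 & p_adj < 0.01
  ids <- tab$metabolites$metabolite_id
  oracle <- sort(paste(ids[pairs[keep, 1]], ids[pairs[keep, 2]]))
  got <- sort(paste(net$edges$from, net$edges$to))
  expect_identical(got, oracle)
  expect_gt(nrow(net$edges), 5)  # the planted module produced edges
  # attributes match too
  m <- match(paste(net$edges$from, net$edges$to),
             paste(ids[pairs[, 1]], ids[pairs[, 2]]))
  expect_equal(net$edges$r, r[m], tolerance = 1e-10)
  expect_equal(net$edges$p_adj, p_adj[m], tolerance = 1e-10)
})

test_that("the edge rule is strict and one-sided", {
  # construct rows with known correlations: identical (r = 1),
  # anti-correlated (r = -1), and an exact r = 0.7 pair
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  # build an exact r = 0.7 partner by Gram-Schmidt
  set.seed(2)
  z <- rnorm(8)
  z <- resid(lm(z ~ base))
  z <- z / sqrt(sum(z^2))
  bs <- scale(base)[, 1] / sqrt(sum(scale(base)[, 1]^2))
  exact <- 0.7 * bs + sqrt(1 - 0.49) * z
  expect_equal(cor(base, exact), 0.7, tolerance = 1e-12)

  tab <- make_table(rbind(base, base + 10, -base, exact + 10),
                    groups = rep(c("a", "b"), each = 4),
                    ids = c("x", "x_dup", "x_neg", "x_070"),
                    scale = "log10")
  net <- correlation_edges(tab, r_min = 0.7, p_max = 0.01)
  pairs <- paste(net$edges$from, net$edges$to)
  expect_true("x x_dup" %in% pairs)        # r = 1 kept
  expect_false(any(grepl("x_neg", pairs))) # r = -1 dropped (one-sided)
  expect_false(any(grepl("x_070", pairs))) # r = 0.70 exactly: strict >
  # absolute mode keeps the anti-correlated pair
  net_abs <- correlation_edges(tab, use_absolute = TRUE)
  expect_true(any(grepl("x_neg", paste(net_abs$edges$from,
                                       net_abs$edges$to))))
})

test_that("constant metabolites are excluded from pairing but kept as nodes", {
  tab <- make_table(rbind(1:8, (1:8) * 2, rep(5, 8)),
                    groups = rep(c("a", "b"), each = 4), scale = "log10")
  expect_warning(net <- correlation_edges(tab), "constant")
  expect_equal(nrow(net$nodes), 3)
  expect_false("m03" %in% c(net$edges$from, net$edges$to))
  small <- make_table(matrix(1:6, 2), groups = c("a", "a", "b"),
                      scale = "log10")
  expect_error(correlation_edges(small), ">= 4 samples")
})

test_that("MCL separates disconnected and bridged structures", {
  # two disjoint triangles -> 2 modules
  tri2 <- adj_to_network(rbind(
    c(0, 1, 1, 0, 0, 0), c(1, 0, 1, 0, 0, 0), c(1, 1, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1, 1), c(0, 0, 0, 1, 0, 1), c(0, 0, 0, 1, 1, 0)))
  res <- mcl_cluster(tri2)
  expect_equal(res$n_clusters, 2)
  expect_length(unique(res$membership[1:3]), 1)
  expect_length(unique(res$membership[4:6]), 1)

  # complete graph K5 -> 1 module
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(mcl_cluster(adj_to_network(K5))$n_clusters, 1)

  # two K5s joined by a single bridge edge -> 2 modules at inflation 2
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- K5; A[6:10, 6:10] <- K5
  A[5, 6] <- A[6, 5] <- 1
  res2 <- mcl_cluster(adj_to_network(A), mcl_config(inflation = 2))
  expect_equal(res2$n_clusters, 2)
  expect_length(unique(res2$membership[1:5]), 1)
  expect_length(unique(res2$membership[6:10]), 1)
})

test_that("MCL yields a partition and is relabeling-invariant", {
  set.seed(31)
  for (i in 1:5) {
    A <- random_adj(12, 0.25)
    net <- adj_to_network(A)
    res <- mcl_cluster(net)
    expect_setequal(names(res$membership), net$nodes$metabolite_id)
    expect_true(all(!is.na(res$membership)))
    # permuted node order gives the same partition
    perm <- sample(12)
    net_p <- adj_to_network(A[perm, perm],
                            ids = sprintf("n%02d", seq_len(12))[perm])
    res_p <- mcl_cluster(net_p)
    common <- names(res$membership)
    expect_equal(
      adjusted_rand_index(res$membership[common], res_p$membership[common]),
      1)
  }
})

test_that("isolated nodes become singleton modules", {
  net <- coabundance_network(
    data.frame(metabolite_id = c("a", "b", "c", "lonely")),
    data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
               r = 0.9, p_adj = 1e-5))
  res <- mcl_cluster(net)
  expect_equal(res$n_clusters, 2)
  expect_length(unique(res$membership[c("a", "b", "c")]), 1)
  expect_false(res$membership["lonely"] %in%
                 res$membership[c("a", "b", "c")])
  expect_error(mcl_cluster(coabundance_network(
    data.frame(metabolite_id = character(0)))), "empty")
})

test_that("module recovery on latent-factor data is near-perfect", {
  # scaled-down version of the network acceptance surface
  specs <- replicate(100, trend_spec("no_change"), simplify = FALSE)
  mods <- replicate(5, module_spec(20, loading = 0.9), simplify = FALSE)
  sim <- generate_abundance(specs, n_per_group = 7, modules = mods,
                            seed = 77)
  net <- correlation_edges(log_transform(sim$table, 10))
  res <- mcl_cluster(net)
  ari <- adjusted_rand_index(res$membership[sim$truth$metabolite_id],
                             sim$truth$module)
  expect_gte(ari, 0.8)
})
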