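star_graph <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, 2:(leaves + 1)] <- A[2:(leaves + 1), 1] <- 1
  A
}

test_that("centralities match hand values on canonical graphs", {
  # star K1,4: center DC 4 with leaf neighbors of degree 1
  net <- adj_to_network(star_graph(4),
                        ids = c("ctr", paste0("l", 1:4)))
  cent <- centralities(net)
  ctr <- cent[cent$metabolite_id == "ctr", ]
  leaf <- cent[cent$metabolite_id == "l1", ]
  expect_equal(ctr$DC, 4)
  expect_equal(ctr$NC, 1)
  expect_equal(leaf$DC, 1)
  expect_equal(leaf$NC, 4)

  # path A-B-C: only B carries shortest paths
  path3 <- adj_to_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                          ids = c("A", "B", "C"))
  bc <- centralities(path3)
  expect_equal(bc$BC[bc$metabolite_id == "B"], 1)
  expect_equal(bc$BC[bc$metabolite_id == "A"], 0)
})

test_that("the neighbor-degree H-index follows its definition", {
  expect_equal(metaboaging:::h_index(c(3, 3, 3)), 3)
  expect_equal(metaboaging:::h_index(c(1, 1, 5)), 1)
  expect_equal(metaboaging:::h_index(c(2, 2, 5)), 2)
  expect_equal(metaboaging:::h_index(numeric(0)), 0)
  # brute-force H over random degree vectors
  set.seed(17)
  for (i in 1:20) {
    degs <- sample(0:9, sample(1:8, 1), replace = TRUE)
    expect_equal(metaboaging:::h_index(degs), bf_h_index(degs))
  }
})

test_that("every centrality equals its brute-force oracle on small graphs", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    A <- random_adj(n, runif(1, 0.25, 0.7))
    radius <- sample(1:3, 1)
    net <- adj_to_network(A)
    cent <- centralities(net, ivi_config(ci_radius = radius))
    orc <- bf_centralities(A, radius = radius)
    for (col in c("DC", "NC", "BC", "LH", "CR", "CI")) {
      expect_equal(cent[[col]], orc[[col]], tolerance = 1e-10,
                   info = paste("centrality", col, "rep", i))
    }
  }
})

test_that("IVI spans [1, 100] with the star extremes and regular-graph floor", {
  # star K1,6: the center attains 100, leaves share the minimum
  net <- adj_to_network(star_graph(6), ids = c("ctr", paste0("l", 1:6)))
  cent <- centralities(net)
  scores <- ivi(cent)
  expect_equal(unname(scores["ctr"]), 100)
  expect_length(unique(scores[paste0("l", 1:6)]), 1)
  expect_equal(unname(scores["l1"]), min(scores))

  # cycle C6 is vertex-transitive: all centralities constant, IVI = 1
  C6 <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; C6[i, j] <- C6[j, i] <- 1 }
  s6 <- ivi(centralities(adj_to_network(C6)))
  expect_equal(unname(s6), rep(1, 6))

  # bounds hold on arbitrary graphs
  set.seed(71)
  for (i in 1:10) {
    s <- ivi(centralities(adj_to_network(random_adj(10, 0.3))))
    expect_true(all(s >= 1 & s <= 100))
  }
})

test_that("IVI is invariant under graph isomorphism", {
  set.seed(13)
  A <- random_adj(9, 0.4)
  ids <- sprintf("n%02d", 1:9)
  s1 <- ivi(centralities(adj_to_network(A, ids)))
  perm <- sample(9)
  s2 <- ivi(centralities(adj_to_network(A[perm, perm], ids[perm])))
  expect_equal(s1[ids], s2[ids], tolerance = 1e-10)
})

test_that("degenerate graphs take their conventions", {
  empty <- coabundance_network(data.frame(metabolite_id = character(0)))
  expect_equal(nrow(centralities(empty)), 0)
  expect_length(ivi(centralities(empty)), 0)
  single <- coabundance_network(data.frame(metabolite_id = "only"))
  expect_equal(unname(ivi(centralities(single))), 1)
})

test_that("ranking orders by IVI with degree then id tie-breaks", {
  cent <- structure(
    data.frame(metabolite_id = c("a", "b", "c", "d"),
               DC = c(5, 3, 3, 2), NC = 1, BC = 1, LH = 1, CR = 1, CI = 1,
               stringsAsFactors = FALSE),
    class = c("centrality_table", "data.frame"))
  scores <- stats::setNames(c(50, 50, 20, 90), c("a", "b", "c", "d"))
  rk <- rank_influential(scores, cent, k = 3)
  expect_equal(rk$top$metabolite_id, c("d", "a", "b"))  # DC 5 beats DC 3
  expect_equal(nrow(rank_influential(scores, cent, k = 0)$top), 0)
  expect_warning(all4 <- rank_influential(scores, cent, k = 10),
                 "exceeds")
  expect_equal(nrow(all4$top), 4)
})

test_that("planted hubs rank at the top of a two-hub network", {
  net <- planted_hub_graph(seed = 1)
  cent <- centralities(net)
  scores <- ivi(cent)
  top5 <- rank_influential(scores, cent, k = 5)$top$metabolite_id
  expect_true(all(c("hubA", "hubB") %in% top5))
})
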