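test_that("network construction keeps only supra-threshold positive edges", {
  m <- diag(4)
  dimnames(m) <- list(letters[1:4], letters[1:4])
  m["a", "b"] <- m["b", "a"] <- 0.5
  m["c", "d"] <- m["d", "c"] <- -0.9      # negative never becomes an edge
  net <- build_network(m, 0.3)
  expect_equal(net$nodes, c("a", "b"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 0.5)
  expect_warning(empty <- build_network(m, 0.95), "empty")
  expect_length(empty$nodes, 0)
  expect_error(build_network(m, 0), "positive")
})

test_that("map equation matches hand-evaluated codelengths", {
  tri <- make_network(data.frame(from = c("A", "A", "B"),
                                 to = c("B", "C", "C"), weight = 1))
  expect_equal(map_equation(tri, setNames(rep(1, 3), c("A", "B", "C"))),
               log2(3), tolerance = 1e-12)
  # two triangles joined by a bridge: bipartition beats the lump
  e <- data.frame(from = c("A", "A", "B", "D", "D", "E", "C"),
                  to = c("B", "C", "C", "E", "F", "F", "D"), weight = 1)
  net <- make_network(e)
  L1 <- map_equation(net, setNames(rep(1, 6), LETTERS[1:6]))
  L2 <- map_equation(net, setNames(c(1, 1, 1, 2, 2, 2), LETTERS[1:6]))
  expect_lt(L2, L1)
  # singletons on a clique are worse than one module
  clique <- make_network(expand.grid(from = LETTERS[1:4], to = LETTERS[1:4]) |>
                           subset(as.character(from) < as.character(to)) |>
                           transform(weight = 1))
  Lone <- map_equation(clique, setNames(rep(1, 4), LETTERS[1:4]))
  Lsing <- map_equation(clique, setNames(1:4, LETTERS[1:4]))
  expect_gt(Lsing, Lone)
  expect_error(map_equation(net, setNames(1, "A")), "cover")
})

test_that("community detection finds planted structure deterministically", {
  # two disconnected cliques: each its own module
  e <- data.frame(from = c("A", "A", "B", "D", "D", "E"),
                  to = c("B", "C", "C", "E", "F", "F"), weight = 1)
  net <- make_network(e)
  part <- detect_communities(net, seed = 1)
  expect_equal(part$n_modules, 2)
  expect_equal(unname(part$membership[c("A", "B", "C")]), rep(1L, 3))
  expect_equal(unname(part$membership[c("D", "E", "F")]), rep(2L, 3))
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  expect_identical(detect_communities(net, seed = 7)$membership,
                   detect_communities(net, seed = 7)$membership)
  # never worse than the one-module partition
  set.seed(180)
  for (rep in 1:10) {
    rnet <- random_network(sample(5:9, 1), p = 0.35, weights = TRUE)
    p <- detect_communities(rnet, trials = 5, seed = rep)
    L1 <- map_equation(rnet, setNames(rep(1, length(rnet$nodes)), rnet$nodes))
    expect_lte(p$codelength, L1 + 1e-9)
    expect_equal(p$codelength, map_equation(rnet, p$membership),
                 tolerance = 1e-12)
  }
})

test_that("modularity matches hand evaluation and stays in range", {
  e <- data.frame(from = c("A", "A", "B", "D", "D", "E"),
                  to = c("B", "C", "C", "E", "F", "F"), weight = 1)
  net <- make_network(e)
  one <- setNames(rep(1, 6), LETTERS[1:6])
  expect_equal(newman_modularity(net, one), 0)
  split <- setNames(c(1, 1, 1, 2, 2, 2), LETTERS[1:6])
  expect_equal(newman_modularity(net, split), 0.5)
  set.seed(190)
  for (rep in 1:10) {
    rnet <- random_network(8, p = 0.4, weights = TRUE)
    memb <- setNames(sample(1:3, length(rnet$nodes), TRUE), rnet$nodes)
    q <- newman_modularity(rnet, memb)
    expect_gte(q, -0.5); expect_lte(q, 1)
  }
})

test_that("normalized connectance is edges over possible edges", {
  expect_equal(normalized_connectance(graph_with_n_e(10, 45)), 1)  # complete
  expect_equal(normalized_connectance(graph_with_n_e(12, 20)),
               20 / choose(12, 2))
  expect_error(normalized_connectance(make_network(
    data.frame(from = "A", to = "B", weight = 1)[0, ])), "2 nodes")
})

test_that("betweenness matches canonical small cases and the oracle", {
  path3 <- make_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                   weight = 1))
  expect_equal(betweenness_centrality(path3),
               c(A = 0, B = 1, C = 0))
  star <- make_network(data.frame(from = "hub", to = sprintf("l%d", 1:4),
                                  weight = 1))
  bc <- betweenness_centrality(star)
  expect_equal(unname(bc["hub"]), 1)
  expect_true(all(bc[sprintf("l%d", 1:4)] == 0))
  two <- make_network(data.frame(from = "A", to = "B", weight = 1))
  expect_warning(z <- betweenness_centrality(two), "< 3 nodes")
  expect_equal(unname(z), c(0, 0))
  set.seed(200)
  for (rep in 1:10) {
    net <- random_network(sample(6:15, 1), p = 0.3)
    expect_equal(betweenness_centrality(net), betweenness_oracle(net),
                 tolerance = 1e-12)
  }
})

test_that("keystone listing honours the cutoff and ordering", {
  bc <- c(Aerococcus = 0.33, Bacteroides = 0.14, Lactobacillus = 0.02,
          Gardnerella = 0.14)
  ks <- keystone_taxa(bc, 0.10)
  expect_equal(ks$taxon, c("Aerococcus", "Bacteroides", "Gardnerella"))
  expect_equal(nrow(keystone_taxa(bc, 0.5)), 0)
  expect_error(keystone_taxa(bc, 0), "cutoff")
})

test_that("neighbour listings inherit the threshold invariant", {
  m <- diag(5); dimnames(m) <- list(letters[1:5], letters[1:5])
  m["a", "b"] <- m["b", "a"] <- 0.8
  m["a", "c"] <- m["c", "a"] <- 0.5
  m["a", "d"] <- m["d", "a"] <- 0.1   # below threshold
  net <- build_network(m, 0.3)
  nb <- neighbor_correlations(net, "a")
  expect_equal(nb$taxon, c("b", "c"))
  expect_true(all(nb$weight > net$threshold))
  expect_equal(nrow(neighbor_correlations(net, "a", top_n = 1)), 1)
  expect_error(neighbor_correlations(net, "d"), "not in the network")
})

test_that("networks serialize to edge lists and GraphML", {
  net <- graph_with_n_e(6, 8)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_network_edgelist(net, p1)
  back <- read_network_edgelist(p1, threshold = net$threshold)
  expect_equal(back$edges$weight, net$edges$weight)
  expect_setequal(back$nodes, net$nodes)
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, p2)
  expect_true(file.size(p2) > 0)
  g <- as_igraph(net)
  expect_equal(igraph::gorder(g), 6)
  expect_equal(igraph::gsize(g), 8)
})
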