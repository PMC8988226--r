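test_that("simulators are bitwise deterministic given a seed", {
  a <- simulate_counts(10, sprintf("t%d", 1:6), depth_mean = 1000, seed = 11)
  b <- simulate_counts(10, sprintf("t%d", 1:6), depth_mean = 1000, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(simulate_state_types(sprintf("t%d", 1:5), 3, 3, "t1", seed = 4),
                   simulate_state_types(sprintf("t%d", 1:5), 3, 3, "t1", seed = 4))
  expect_identical(ape::write.tree(simulate_tree(letters[1:6], seed = 2)),
                   ape::write.tree(simulate_tree(letters[1:6], seed = 2)))
  s1 <- simulate_study(seed = 3, n_case = 3, n_control = 4,
                       n_taxa_vaginal = 22, n_taxa_bladder = 30)
  s2 <- simulate_study(seed = 3, n_case = 3, n_control = 4,
                       n_taxa_vaginal = 22, n_taxa_bladder = 30)
  expect_identical(s1$vaginal, s2$vaginal)
  expect_identical(s1$metadata, s2$metadata)
})

test_that("simulate_counts validates its correlation matrix and composition", {
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.9
  expect_error(simulate_counts(5, letters[1:3], bad), "positive semidefinite")
  expect_error(simulate_counts(2, letters[1:4]), "n_samples")
  # single taxon with nearly all mass: counts concentrate there
  mu <- c(15, rep(-5, 4))
  sim <- simulate_counts(10, sprintf("t%d", 1:5), log_mean = mu, log_sd = 0.1,
                         depth_mean = 1000, seed = 5)
  expect_true(all(relative_abundance(sim$counts)[, 1] > 0.99))
  expect_true(all(sim$counts >= 0))
})

test_that("a planted pair dominates the estimated correlations", {
  sim <- simulate_counts(100, sprintf("t%02d", 1:20),
                         planted_pair_correlation(20, rho = 0.8),
                         depth_mean = 5000, seed = 17)
  fit <- sparcc(sim$counts, seed = 18)
  off <- fit$cor[upper.tri(fit$cor)]
  expect_equal(which.max(abs(off)), 1L)   # (1,2) is the first upper-tri cell
  expect_gt(fit$cor[1, 2], 0.5)
})

test_that("identity basis produces near-zero SparCC estimates", {
  sim <- simulate_counts(100, sprintf("t%02d", 1:50), depth_mean = 5000,
                         seed = 21)
  fit <- sparcc(sim$counts, seed = 22)
  off <- abs(fit$cor[upper.tri(fit$cor)])
  expect_lt(mean(off), 0.1)
  expect_gt(mean(off < 0.2), 0.95)
})

test_that("state-type compositions behave as declared", {
  taxa <- sprintf("g%02d", 1:12)
  st <- simulate_state_types(taxa, 6, 5, "g01", depth_mean = 5000, seed = 8)
  expect_equal(unname(st$truth$state_type_labels),
               rep(c("dominated", "diverse"), c(6, 5)))
  rel <- relative_abundance(st$counts)
  # dominant taxon drawn above 0.7 before multinomial noise
  expect_true(all(rel[1:6, "g01"] > 0.6))
  expect_equal(unname(rowSums(rel)), rep(1, 11))
  expect_error(simulate_state_types(taxa, 3, 3, "nope"), "not in taxon list")
  # single homogeneous group: low silhouette at k = 2
  one <- simulate_state_types(taxa, 12, 0, "g01", depth_mean = 5000, seed = 9)
  tr <- simulate_tree(taxa, seed = 10)
  wu <- weighted_unifrac(one$counts, tr)
  sil <- mean_silhouette(wu, cut_k(ward_d2_linkage(wu), 2))
  expect_lt(sil, 0.5)
})

test_that("random trees are rooted, bifurcating, and serializable", {
  taxa <- sprintf("sp%02d", 1:17)
  tr <- simulate_tree(taxa, seed = 30)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  expect_equal(tr$Nnode, length(taxa) - 1)      # n - 1 internal nodes
  expect_setequal(tr$tip.label, taxa)
  expect_true(all(tr$edge.length > 0))
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = FALSE))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-8)
  two <- simulate_tree(c("A", "B"), seed = 1)
  expect_equal(ape::Ntip(two), 2)
  expect_error(simulate_tree(c("A", "A")), "duplicate")
  expect_error(simulate_tree("A"), "at least 2")
})

test_that("contaminant spiking is inert at zero and detectable when planted", {
  base <- simulate_counts(20, sprintf("g%d", 1:8), depth_mean = 20000,
                          seed = 2)$counts
  conc <- setNames(exp(seq(log(0.1), log(10), length.out = 20)), rownames(base))
  none <- spike_contaminants(base, conc, 0)
  expect_identical(none$counts, base)
  expect_false(any(none$truth$contaminant_flags))
  # constant concentration: contaminant indistinguishable from resident
  flat <- setNames(rep(2, 20), rownames(base))
  sp <- spike_contaminants(base, flat, 1, noise_sdlog = 0, seed = 4)
  dc <- decontam_frequency(sp$counts, flat + runif(20, 0, 1e-6), 0.3)
  sc <- dc$scores$score[dc$scores$taxon == "contaminant_01"]
  expect_gt(sc, 0.3)
  expect_error(spike_contaminants(base, conc * -1, 1), "positive")
})

test_that("planted SparCC correlation is recovered across replicates", {
  # 20 replicates, one pair at rho = 0.8, D = 50, n = 100
  ests <- vapply(1:20, function(s) {
    sim <- simulate_counts(100, sprintf("t%02d", 1:50),
                           planted_pair_correlation(50, rho = 0.8),
                           depth_mean = 5000, seed = 100 + s)
    sparcc(sim$counts, seed = 200 + s)$cor[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.8), 0.15)
})
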