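test_that("alpha diversity indices match their closed forms", {
  even <- make_counts(matrix(10L, 1, 5))
  expect_equal(unname(observed_taxa(even)), 5)
  expect_equal(unname(inverse_simpson(even)), 5)
  expect_equal(unname(pielou_evenness(even)), 1)
  single <- make_counts(matrix(c(42L, 0L), 1, 2))
  expect_equal(unname(observed_taxa(single)), 1)
  expect_equal(unname(inverse_simpson(single)), 1)
  expect_true(is.na(pielou_evenness(single)))
  half <- make_counts(matrix(c(5L, 5L), 1, 2))
  expect_equal(unname(inverse_simpson(half)), 2)
  expect_error(observed_taxa(make_counts(matrix(0L, 1, 2))), "zero-total")
})

test_that("Bray-Curtis follows its formula", {
  x <- make_counts(rbind(c(10L, 0L), c(0L, 10L), c(5L, 5L), c(10L, 0L)))
  d <- bray_curtis(x)
  expect_equal(d[1, 2], 1)          # disjoint
  expect_equal(d[1, 4], 0)          # identical
  expect_equal(d[1, 3], 0.5)        # (|10-5|+|0-5|)/(15+5)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("UniFrac distances match hand evaluation on a two-leaf tree", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  x <- make_counts(matrix(c(10L, 0L, 0L, 10L, 5L, 5L), 3, 2, byrow = TRUE,
                          dimnames = list(c("s1", "s2", "s3"), c("A", "B"))))
  expect_equal(weighted_unifrac(x, tree, normalized = FALSE)[1, 2], 2)
  expect_equal(weighted_unifrac(x, tree, normalized = TRUE)[1, 2], 1)
  expect_equal(unweighted_unifrac(x, tree)[1, 2], 1)
  expect_equal(weighted_unifrac(x, tree)[1, 1], 0)
  y <- make_counts(matrix(c(3L, 3L), 2, 1,
                          dimnames = list(c("u", "v"), "A")))
  expect_error(weighted_unifrac(y, tree)[1, 2], NA)
  z <- make_counts(matrix(1L, 2, 3, dimnames = list(c("u", "v"),
                                                    c("A", "B", "C"))))
  expect_error(weighted_unifrac(z, tree), "C")
})

test_that("weighted UniFrac agrees with the per-branch oracle", {
  set.seed(31)
  for (rep in 1:5) {
    taxa <- sprintf("t%02d", 1:12)
    tr <- simulate_tree(taxa, seed = 40 + rep)
    x <- make_counts(matrix(rpois(8 * 12, 4) + 1L, 8, 12,
                            dimnames = list(sprintf("s%d", 1:8), taxa)))
    for (norm in c(TRUE, FALSE)) {
      mine <- weighted_unifrac(x, tr, normalized = norm)
      orac <- unifrac_oracle(x, tr, normalized = norm)
      expect_lt(max(abs(mine - orac)), 1e-10)
    }
  }
})

test_that("weighted UniFrac depends only on proportions", {
  taxa <- sprintf("t%d", 1:6)
  tr <- simulate_tree(taxa, seed = 50)
  x <- make_counts(matrix(rpois(18, 10) + 1L, 3, 6,
                          dimnames = list(c("a", "b", "c"), taxa)))
  y <- x; y[1, ] <- y[1, ] * 10L
  expect_equal(weighted_unifrac(x, tr), weighted_unifrac(y, tr),
               tolerance = 1e-12)
  # bounds for the normalized variant
  d <- weighted_unifrac(x, tr)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA reproduces Euclidean configurations", {
  pts <- c(0, 3, 5)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  ax1 <- ord$coordinates[, 1]
  expect_equal(sort(as.vector(dist(ax1))), sort(as.vector(dist(pts))),
               tolerance = 1e-10)
  # full-space pairwise distances equal input for Euclidean input
  set.seed(60)
  conf <- matrix(rnorm(30), 10, 3)
  d2 <- as.matrix(dist(conf))
  ord2 <- pcoa(d2)
  expect_equal(as.matrix(dist(ord2$coordinates)), d2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(ord2$eigenvalues) <= 1e-8))
  # degenerate: all-zero distances
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(ncol(pcoa(z)$coordinates), 0)
})

test_that("PERMANOVA reduces to classical ANOVA for 1-D Euclidean data", {
  set.seed(70)
  y <- c(rnorm(8, 0), rnorm(7, 1.5))
  g <- rep(c("a", "b"), c(8, 7))
  d <- as.matrix(dist(y))
  dimnames(d) <- list(sprintf("s%d", 1:15), sprintf("s%d", 1:15))
  md <- data.frame(group = g, row.names = rownames(d))
  res <- permanova(d, md, terms = "group", permutations = 99, seed = 1)
  f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F, f_aov, tolerance = 1e-10)
  # determinism given seed
  res2 <- permanova(d, md, terms = "group", permutations = 99, seed = 1)
  expect_identical(res$p_value, res2$p_value)
  # permutations = 1: add-one rule leaves p in {0.5, 1}
  res3 <- permanova(d, md, terms = "group", permutations = 1, seed = 2)
  expect_true(res3$p_value %in% c(0.5, 1))
  md$const <- "x"
  expect_error(permanova(d, md, terms = "const"), "constant")
})

test_that("distance matrices round-trip through disk", {
  set.seed(80)
  x <- make_counts(matrix(rpois(40, 8) + 1L, 4, 10))
  d <- bray_curtis(x)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  expect_equal(read_distance_matrix(path), d, tolerance = 1e-12)
})
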