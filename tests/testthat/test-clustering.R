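test_that("Ward.D2 linkage matches the reference implementation", {
  set.seed(90)
  for (rep in 1:8) {
    d <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    dimnames(d) <- list(letters[1:8], letters[1:8])
    mine <- ward_d2_linkage(d)
    expect_equal(sort(mine$height), ward_d2_oracle_heights(d),
                 tolerance = 1e-10)
    ref <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    for (k in 2:4) {
      tab <- table(cutree(mine, k), cutree(ref, k))
      expect_equal(sum(apply(tab, 1, max)), 8)  # identical partitions
    }
  }
})

test_that("merge order respects the Ward criterion", {
  # two identical samples merge first at height zero
  d <- as.matrix(dist(c(1, 1, 5, 9)))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  h <- ward_d2_linkage(d)
  expect_equal(h$height[1], 0)
  expect_setequal(h$merge[1, ], c(-1, -2))
  # two tight pairs merge before any cross-pair merge
  d2 <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  dimnames(d2) <- list(letters[1:4], letters[1:4])
  h2 <- ward_d2_linkage(d2)
  expect_setequal(as.vector(h2$merge[1:2, ]), c(-1, -2, -3, -4))
  # sample order invariance of heights
  perm <- c(3, 1, 4, 2)
  h3 <- ward_d2_linkage(d2[perm, perm])
  expect_equal(sort(h3$height), sort(h2$height), tolerance = 1e-12)
})

test_that("cut_k returns exactly k clusters with valid bounds", {
  d <- as.matrix(dist(c(0, 1, 10, 11, 20)))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  h <- ward_d2_linkage(d)
  expect_equal(unname(cut_k(h, 1)), rep(1L, 5))
  expect_equal(sort(unname(cut_k(h, 5))), 1:5)
  expect_length(unique(cut_k(h, 3)), 3)
  expect_error(cut_k(h, 0), "k must lie")
  expect_error(cut_k(h, 6), "k must lie")
})

test_that("mean silhouette matches hand evaluation", {
  d <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  s <- mean_silhouette(d, c(1, 1, 2, 2))
  # a = 0.1; b = mean(10, 10.1) or mean(9.9, 10): s = (b - a)/b
  b1 <- mean(c(10, 10.1)); b2 <- mean(c(9.9, 10))
  expect_equal(s, mean(c((b1 - 0.1) / b1, (b2 - 0.1) / b2,
                         (b2 - 0.1) / b2, (b1 - 0.1) / b1)),
               tolerance = 1e-12)
  expect_equal(round(s, 3), 0.99)
  # perfect separation with zero within-cluster distance
  dd <- matrix(1, 4, 4) - diag(4)
  dd[1, 2] <- dd[2, 1] <- 0; dd[3, 4] <- dd[4, 3] <- 0
  dimnames(dd) <- list(letters[1:4], letters[1:4])
  expect_equal(mean_silhouette(dd, c(1, 1, 2, 2)), 1)
  # random labels on structureless data: near zero
  set.seed(100)
  dr <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  dimnames(dr) <- list(sprintf("s%d", 1:30), sprintf("s%d", 1:30))
  sil <- mean(replicate(20, mean_silhouette(dr, sample(rep(1:2, 15)))))
  expect_lt(abs(sil), 0.12)
  expect_error(mean_silhouette(dr, rep(1, 30)), "at least 2")
  # scale invariance
  expect_equal(mean_silhouette(d, c(1, 1, 2, 2)),
               mean_silhouette(d * 13, c(1, 1, 2, 2)), tolerance = 1e-12)
})

test_that("silhouette-based k selection recovers planted group counts", {
  set.seed(110)
  centers <- c(0, 30, 80)
  for (g in 2:3) {
    y <- unlist(lapply(centers[1:g], function(c) rnorm(8, c)))
    d <- as.matrix(dist(y))
    n <- length(y)
    dimnames(d) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
    sel <- select_k(d, 2:6)
    expect_equal(sel$k, g)
    expect_equal(sel$silhouette, mean_silhouette(d, sel$cluster))
    expect_equal(unname(sel$silhouette_by_k[as.character(g)]),
                 sel$silhouette)
  }
})

test_that("dendrograms serialize as merge tables", {
  d <- as.matrix(dist(c(0, 1, 10, 11, 20)))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  h <- ward_d2_linkage(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dendrogram(h, path)
  lines <- readLines(path)
  expect_match(lines[1], "^#labels: a\tb\tc\td\te$")
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(tab), 4)                  # n - 1 merges
  expect_equal(tab$height, h$height)
  expect_equal(as.matrix(tab[, c("left", "right")]), h$merge,
               ignore_attr = TRUE)
})

test_that("Fisher's exact 2x2 matches enumeration and the reference", {
  # recurrent-UTI style margins: 5/20 cases vs 0/30 controls
  expect_equal(round(fisher_exact_2x2(5, 15, 0, 30), 3), 0.007)
  expect_equal(fisher_exact_2x2(0, 10, 0, 10), 1)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  set.seed(120)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 6), 2, 2)
    mine <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-7)
    # brute-force enumeration over all tables with the observed margins
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    supp <- max(0, k - n):min(k, m)
    probs <- dhyper(supp, m, n, k)
    brute <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
    expect_equal(mine, min(1, brute), tolerance = 1e-12)
  }
})

test_that("cluster association generalizes Fisher's test", {
  cl <- setNames(rep(1:2, each = 10), sprintf("s%d", 1:20))
  v <- setNames(rep(c("x", "y"), each = 10), names(cl))
  res <- cluster_association(cl, v)
  expect_equal(res$p_value,
               fisher_exact_2x2(10, 0, 0, 10))
  # 2x2 path identical to fisher_exact_2x2 on arbitrary data
  set.seed(130)
  v2 <- setNames(sample(c("x", "y"), 20, replace = TRUE), names(cl))
  tab <- table(cl, v2)
  expect_equal(cluster_association(cl, v2)$p_value,
               fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  # constant variable: warning and p = 1
  expect_warning(res3 <- cluster_association(cl, setNames(rep("x", 20), names(cl))))
  expect_equal(res3$p_value, 1)
  # r x c Monte Carlo path approximates the exact network algorithm
  cl3 <- setNames(rep(1:3, c(7, 7, 6)), sprintf("s%d", 1:20))
  v3 <- setNames(sample(c("x", "y", "z"), 20, replace = TRUE), names(cl3))
  mc <- cluster_association(cl3, v3, mc_draws = 2e4, seed = 5)$p_value
  ref <- stats::fisher.test(table(cl3, v3))$p.value
  expect_lt(abs(mc - ref), 0.02)
  # determinism of the Monte Carlo path
  expect_identical(cluster_association(cl3, v3, mc_draws = 1e4, seed = 9)$p_value,
                   cluster_association(cl3, v3, mc_draws = 1e4, seed = 9)$p_value)
})
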