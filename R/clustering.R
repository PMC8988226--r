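#' Ward.D2 agglomerative hierarchical clustering
#'
#' Lance-Williams recursion on squared dissimilarities with square-rooted
#' merge heights (the "ward.D2" criterion): when clusters `i` and `j`
#' (sizes `n_i`, `n_j`) merge, the squared dissimilarity to any cluster `k`
#' becomes
#' `[(n_i + n_k) d_ik^2 + (n_j + n_k) d_jk^2 - n_k d_ij^2] / (n_i + n_j + n_k)`.
#' Returns a standard `hclust` object so [stats::cutree()] and plotting
#' work unchanged.
#'
#' @param d symmetric distance matrix over >= 2 samples.
#' @return object of class `hclust`.
#' @export
ward_d2_linkage <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop_ug("need at least 2 samples to cluster")
  labels <- rownames(d) %||% as.character(seq_len(n))
  d2 <- d^2
  diag(d2) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negatives = singletons
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- d2[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(best)]; j <- idx[max(best)]
    height[step] <- sqrt(d2[i, j])
    merge[step, ] <- sort(c(id[i], id[j]))
    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    id[i] <- step
    active[j] <- FALSE
    d2[j, ] <- d2[, j] <- Inf
  }
  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge),
                 labels = labels, method = "ward.D2",
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

# Leaf order by traversal of the merge tree (left-to-right).
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Write a dendrogram as a merge table
#'
#' Tab-delimited text with one row per merge: `step`, `left`, `right`
#' (negative values are singleton samples, positive values earlier merge
#' steps — the `hclust` convention), `height`, plus a `#labels:` header
#' line mapping singleton indices to sample ids.
#'
#' @param dend `hclust` object.
#' @param path file path.
#' @export
write_dendrogram <- function(dend, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#labels: %s", paste(dend$labels, collapse = "\t")), con)
  df <- data.frame(step = seq_along(dend$height),
                   left = dend$merge[, 1], right = dend$merge[, 2],
                   height = dend$height)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges, yielding exactly `k` clusters
#' (standard `cutree` semantics).
#'
#' @param dend `hclust` object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster labels in `1..k`.
#' @export
cut_k <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop_ug("k must lie in 1..%d, got %s", n, format(k))
  cutree(dend, k = k)
}

#' Mean silhouette width of a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean within-cluster
#' distance and `b` the smallest mean distance to another cluster; members
#' of singleton clusters contribute 0. Requires `k >= 2`.
#'
#' @param d distance matrix.
#' @param cluster integer cluster labels aligned with `d` rows.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(d, cluster) {
  d <- check_distance_matrix(d)
  cluster <- as.integer(factor(cluster))
  k <- length(unique(cluster))
  if (k < 2) stop_ug("silhouette requires at least 2 clusters")
  n <- nrow(d)
  s <- numeric(n)
  sizes <- tabulate(cluster, k)
  for (i in seq_len(n)) {
    ci <- cluster[i]
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sum(d[i, cluster == ci]) / (sizes[ci] - 1)
    b <- min(vapply(setdiff(seq_len(k), ci),
                    function(cj) mean(d[i, cluster == cj]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by mean silhouette
#'
#' Cuts the Ward.D2 dendrogram at each `k` in `k_range` and returns the cut
#' with the largest mean silhouette width; ties break toward smaller `k`.
#'
#' @param d distance matrix with more samples than `max(k_range)`.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param dend optional precomputed dendrogram (defaults to
#'   `ward_d2_linkage(d)`).
#' @return list with `cluster` (named labels), `k`, `silhouette` (the
#'   selected mean width), `silhouette_by_k`, and the `dend` used.
#' @export
select_k <- function(d, k_range = 2:6, dend = NULL) {
  d <- check_distance_matrix(d)
  if (nrow(d) <= max(k_range))
    stop_ug("need more than %d samples to consider k up to %d",
            max(k_range), max(k_range))
  dend <- dend %||% ward_d2_linkage(d)
  widths <- vapply(k_range, function(k) mean_silhouette(d, cut_k(dend, k)),
                   numeric(1))
  best <- k_range[which.max(widths)]   # which.max takes the first maximum
  list(cluster = cut_k(dend, best), k = best,
       silhouette = max(widths),
       silhouette_by_k = setNames(widths, k_range),
       dend = dend)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by enumeration of all tables with the observed margins:
#' the sum of hypergeometric point probabilities no greater than that of the
#' observed table. An all-zero table returns p = 1 by convention.
#'
#' @param a,b,c,d cell counts: `a/b` = outcome yes/no in group 1, `c/d` in
#'   group 2. A 2x2 matrix may be passed as `a`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_ug("cell counts must be nonnegative integers")
  if (sum(cells) == 0) return(1)
  m <- a + b          # group 1 size
  n <- c + d          # group 2 size
  k <- a + c          # outcome margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Association between a clustering and a categorical variable
#'
#' For two clusters and a binary variable this is exactly
#' [fisher_exact_2x2()]; larger tables use the same point-probability rule
#' estimated by Monte Carlo over tables with the observed margins
#' (`stats::r2dtable`). A constant variable returns p = 1 with a warning.
#'
#' @param cluster cluster labels named by sample id.
#' @param variable categorical covariate (named by sample id, or aligned).
#' @param mc_draws Monte Carlo table draws for tables larger than 2x2
#'   (default 1e5).
#' @param seed optional integer seed for the Monte Carlo path.
#' @return list with `p_value` and the contingency `table`.
#' @export
cluster_association <- function(cluster, variable, mc_draws = 1e5, seed = NULL) {
  if (!is.null(names(variable)) && !is.null(names(cluster)))
    variable <- variable[names(cluster)]
  keep <- !is.na(variable)
  tab <- table(cluster = cluster[keep], variable = variable[keep])
  if (ncol(tab) < 2 || nrow(tab) < 2) {
    warning("variable or clustering is constant; p = 1")
    return(list(p_value = 1, table = tab))
  }
  if (all(dim(tab) == c(2, 2))) {
    p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else {
    p_obs <- table_log_prob(tab)
    p <- with_seed_if(seed, {
      draws <- r2dtable(mc_draws, rowSums(tab), colSums(tab))
      hits <- sum(vapply(draws, table_log_prob, numeric(1)) <= p_obs + 1e-7)
      (hits + 1) / (mc_draws + 1)
    })
  }
  list(p_value = p, table = tab)
}

# Log point probability of an r x c table under fixed margins
# (multivariate hypergeometric).
table_log_prob <- function(tab) {
  tab <- as.matrix(tab)
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}
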