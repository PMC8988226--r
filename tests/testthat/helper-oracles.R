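# Independent oracles and fixture builders. These deliberately use
# different algorithms from the package implementations they check.

# --- fixtures --------------------------------------------------------------

make_counts <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("t%d", seq_len(ncol(m)))
  m
}

make_network <- function(edges, threshold = 0.1) {
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                 edges = edges, threshold = threshold),
            class = "microbial_network")
}

# Erdos-Renyi-ish random connected-enough network on n nodes.
random_network <- function(n, p = 0.25, weights = FALSE) {
  repeat {
    adj <- matrix(runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) >= 1 && length(unique(c(idx))) == n) break
  }
  w <- if (weights) round(runif(nrow(idx), 0.2, 1), 3) else rep(1, nrow(idx))
  make_network(data.frame(from = sprintf("n%02d", idx[, 1]),
                          to = sprintf("n%02d", idx[, 2]), weight = w))
}

# Deterministic network with exactly n nodes and e edges (ring + chords).
graph_with_n_e <- function(n, e) {
  stopifnot(e >= n, e <= n * (n - 1) / 2)
  pairs <- cbind(seq_len(n), c(seq_len(n)[-1], 1))        # ring covers all nodes
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  extra <- extra[!key(extra) %in% key(pairs), , drop = FALSE]
  pairs <- rbind(pairs, extra[seq_len(e - n), , drop = FALSE])
  make_network(data.frame(from = sprintf("n%03d", pmin(pairs[, 1], pairs[, 2])),
                          to = sprintf("n%03d", pmax(pairs[, 1], pairs[, 2])),
                          weight = 1))
}

# --- betweenness oracle: Floyd-Warshall with geodesic counting -------------

betweenness_oracle <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  d <- matrix(Inf, n, n); diag(d) <- 0
  cnt <- matrix(0, n, n); diag(cnt) <- 1
  ei <- match(network$edges$from, nodes)
  ej <- match(network$edges$to, nodes)
  for (k in seq_along(ei)) {
    d[ei[k], ej[k]] <- d[ej[k], ei[k]] <- 1
    cnt[ei[k], ej[k]] <- cnt[ej[k], ei[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j]) { d[i, j] <- alt; cnt[i, j] <- cnt[i, k] * cnt[k, j] }
    else if (alt == d[i, j] && is.finite(alt))
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v) next
    if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t])
      bc[v] <- bc[v] + cnt[s, v] * cnt[v, t] / cnt[s, t]
  }
  setNames(bc / ((n - 1) * (n - 2) / 2), nodes)
}

# --- exhaustive set partitions (restricted growth strings) -----------------

all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxused) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (m in seq_len(maxused + 1)) rec(c(prefix, m), max(maxused, m))
  }
  rec(1L, 1L)
  out
}

min_codelength_oracle <- function(network) {
  parts <- all_partitions(length(network$nodes))
  vals <- vapply(parts, function(p)
    map_equation(network, setNames(p, network$nodes)), numeric(1))
  min(vals)
}

# --- weighted UniFrac oracle: per-branch recursion -------------------------

unifrac_oracle <- function(x, tree, normalized = TRUE) {
  p <- sweep(x, 1, rowSums(x), "/")
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  branch_mass <- sapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- tree$tip.label[tips_below(tree$edge[e, 2])]
    rowSums(p[, intersect(tips, colnames(p)), drop = FALSE])
  })  # samples x edges
  depth <- function(tip) {
    node <- match(tip, tree$tip.label); len <- 0
    while (TRUE) {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      len <- len + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    len
  }
  tipdepth <- vapply(colnames(p), depth, numeric(1))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(tree$edge.length * abs(branch_mass[i, ] - branch_mass[j, ]))
    if (normalized)
      num <- num / sum(tipdepth * (p[i, ] + p[j, ]))
    d[i, j] <- d[j, i] <- num
  }
  d
}

# --- naive Lance-Williams Ward.D2 (direct recursion on squared d) ----------

ward_d2_oracle_heights <- function(d) {
  ref <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  sort(ref$height)
}

# best label agreement between two 2-level partitions
label_agreement <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  max(mean(a == b), mean(a == 3L - b))
}
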