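#' Build a co-occurrence network from a correlation matrix
#'
#' An undirected edge joins taxa `i` and `j` whenever their correlation
#' strictly exceeds `threshold` (> 0); negative correlations never form
#' edges. Taxa with no retained edge are excluded from the node set, so the
#' node count can be smaller than the number of taxa.
#'
#' @param corr `sparcc_fit` object or a symmetric correlation matrix with
#'   taxon dimnames.
#' @param threshold positive edge threshold (e.g. from
#'   [permutation_threshold()]).
#' @return object of class `microbial_network`: list with `nodes`
#'   (character), `edges` (data.frame `from, to, weight`), `threshold`.
#' @export
build_network <- function(corr, threshold) {
  m <- if (inherits(corr, "sparcc_fit")) corr$cor else corr
  if (!is.matrix(m) || is.null(colnames(m)))
    stop_ug("corr must be a named correlation matrix or sparcc_fit")
  if (threshold <= 0) stop_ug("edge threshold must be positive")
  ut <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  edges <- data.frame(from = colnames(m)[ut[, 1]],
                      to = colnames(m)[ut[, 2]],
                      weight = m[ut],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (length(nodes) == 0)
    warning("no correlations exceed the threshold; network is empty")
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "microbial_network")
}

#' @export
print.microbial_network <- function(x, ...) {
  cat(sprintf("microbial_network: %d nodes, %d edges (threshold %.4g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

as_network <- function(network) {
  if (!inherits(network, "microbial_network"))
    stop_ug("expected a microbial_network object")
  network
}

# Edge list with integer node indices + per-node strengths.
network_index <- function(network) {
  nodes <- network$nodes
  e <- network$edges
  ei <- match(e$from, nodes); ej <- match(e$to, nodes)
  strength <- numeric(length(nodes))
  for (k in seq_along(ei)) {
    strength[ei[k]] <- strength[ei[k]] + e$weight[k]
    strength[ej[k]] <- strength[ej[k]] + e$weight[k]
  }
  list(nodes = nodes, i = ei, j = ej, w = e$weight, strength = strength,
       total_weight = sum(e$weight))
}

plogp <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Two-level map equation codelength
#'
#' Expected per-step description length (bits) of a random walk on the
#' undirected weighted network under a two-level coding scheme: node visit
#' rates are `p_i = strength_i / 2W`, module exit rates are
#' `q_m = (boundary-crossing weight) / 2W`, and
#' `L = q H(Q) + sum_m p_m^o H(P_m)` with `q = sum q_m` and
#' `p_m^o = q_m + sum_{i in m} p_i`.
#'
#' @param network `microbial_network`.
#' @param membership module id per node, named by node or aligned with
#'   `network$nodes`; must cover every node.
#' @return codelength in bits.
#' @export
map_equation <- function(network, membership) {
  network <- as_network(network)
  membership <- align_membership(network, membership)
  idx <- network_index(network)
  map_equation_core(idx, as.integer(factor(membership)))
}

align_membership <- function(network, membership) {
  if (!is.null(names(membership))) {
    missing <- setdiff(network$nodes, names(membership))
    if (length(missing) > 0)
      stop_ug("membership does not cover node(s): %s",
              paste(missing, collapse = ", "))
    membership <- membership[network$nodes]
  } else if (length(membership) != length(network$nodes)) {
    stop_ug("membership must cover all %d nodes", length(network$nodes))
  }
  membership
}

# Vectorized codelength for integer membership over a network_index.
map_equation_core <- function(idx, mem) {
  nmod <- max(mem)
  p <- idx$strength / (2 * idx$total_weight)
  cross <- mem[idx$i] != mem[idx$j]
  qm <- numeric(nmod)
  if (any(cross)) {
    w2 <- idx$w[cross] / (2 * idx$total_weight)
    qm <- qm + unname(rowsum_vec(w2, mem[idx$i][cross], nmod))
    qm <- qm + unname(rowsum_vec(w2, mem[idx$j][cross], nmod))
  }
  pm <- rowsum_vec(p, mem, nmod)
  q <- sum(qm)
  pmo <- qm + pm
  plogp(q) - 2 * sum(plogp(qm)) + sum(plogp(pmo)) - sum(plogp(p))
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Map-equation community detection
#'
#' Greedy minimization of the two-level map equation, InfoMap style: from a
#' singleton partition, repeatedly move single nodes to the neighbouring
#' module giving the largest codelength decrease until no move helps, then
#' attempt module-level aggregations (merging adjacent modules) and repeat.
#' The best of `trials` seeded restarts (random node orders) is returned
#' together with its codelength and modularity.
#'
#' @param network nonempty `microbial_network`.
#' @param trials number of restarts (default 10).
#' @param seed optional integer seed; results are deterministic given it.
#' @return list of class `network_partition`: `membership` (named module
#'   ids, 1-based, relabelled by first appearance), `codelength`,
#'   `modularity`, `n_modules`, `n_trials`, `seed`.
#' @export
detect_communities <- function(network, trials = 10, seed = NULL) {
  network <- as_network(network)
  if (length(network$nodes) == 0) stop_ug("cannot partition an empty network")
  idx <- network_index(network)
  n <- length(idx$nodes)
  # adjacency list: for each node, (neighbour, weight)
  nbr <- vector("list", n)
  for (k in seq_along(idx$i)) {
    nbr[[idx$i[k]]] <- rbind(nbr[[idx$i[k]]], c(idx$j[k], idx$w[k]))
    nbr[[idx$j[k]]] <- rbind(nbr[[idx$j[k]]], c(idx$i[k], idx$w[k]))
  }
  best <- with_seed_if(seed, {
    acc <- NULL
    for (tr in seq_len(trials)) {
      mem <- infomap_greedy(idx, nbr, sample.int(n))
      L <- map_equation_core(idx, renumber(mem))
      if (is.null(acc) || L < acc$L - 1e-12) acc <- list(mem = mem, L = L)
    }
    acc
  })
  mem <- as.integer(factor(best$mem, levels = unique(best$mem)))
  names(mem) <- idx$nodes
  structure(list(membership = mem, codelength = best$L,
                 modularity = newman_modularity(network, mem),
                 n_modules = max(mem), n_trials = trials, seed = seed),
            class = "network_partition")
}

# One greedy run: local node moves to convergence, then module merges.
infomap_greedy <- function(idx, nbr, order) {
  n <- length(idx$nodes)
  mem <- seq_len(n)
  L <- map_equation_core(idx, renumber(mem))
  repeat {
    improved <- FALSE
    for (v in order) {
      cand <- unique(mem[nbr[[v]][, 1]])
      cand <- setdiff(cand, mem[v])
      if (length(cand) == 0) next
      for (m in cand) {
        trial <- mem; trial[v] <- m
        Lt <- map_equation_core(idx, renumber(trial))
        if (Lt < L - 1e-12) { mem <- trial; L <- Lt; improved <- TRUE }
      }
    }
    # aggregation phase: try merging pairs of adjacent modules
    merged <- TRUE
    while (merged) {
      merged <- FALSE
      mods <- unique(mem)
      adj <- unique(t(apply(cbind(mem[idx$i], mem[idx$j]), 1, sort)))
      adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
      if (nrow(adj) > 0) {
        for (r in seq_len(nrow(adj))) {
          a <- adj[r, 1]; b <- adj[r, 2]
          if (!all(c(a, b) %in% mem)) next
          trial <- mem; trial[trial == b] <- a
          Lt <- map_equation_core(idx, renumber(trial))
          if (Lt < L - 1e-12) { mem <- trial; L <- Lt; improved <- TRUE; merged <- TRUE }
        }
      }
    }
    if (!improved) break
  }
  mem
}

renumber <- function(mem) as.integer(factor(mem))

#' Weighted Newman-Girvan modularity
#'
#' `Q = sum_m [W_m / W - (S_m / 2W)^2]` with `W_m` the within-module edge
#' weight, `S_m` the module's total strength, and `W` the total edge
#' weight.
#'
#' @inheritParams map_equation
#' @return modularity `Q`.
#' @export
newman_modularity <- function(network, membership) {
  network <- as_network(network)
  membership <- align_membership(network, membership)
  mem <- as.integer(factor(membership))
  idx <- network_index(network)
  W <- idx$total_weight
  within <- idx$w[mem[idx$i] == mem[idx$j]]
  wm <- rowsum_vec(within, mem[idx$i][mem[idx$i] == mem[idx$j]], max(mem))
  sm <- rowsum_vec(idx$strength, mem, max(mem))
  sum(wm / W - (sm / (2 * W))^2)
}

#' Normalized connectance
#'
#' Realized edges over possible edges, `E / (N (N - 1) / 2)`.
#'
#' @param network `microbial_network` with >= 2 nodes.
#' @return connectance in `[0, 1]`.
#' @export
normalized_connectance <- function(network) {
  network <- as_network(network)
  n <- length(network$nodes)
  if (n < 2) stop_ug("connectance needs at least 2 nodes")
  nrow(network$edges) / (n * (n - 1) / 2)
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Shortest-path betweenness on the unweighted topology (edges count as
#' unit steps: correlation magnitude is a similarity, not a cost), computed
#' by breadth-first shortest-path counting with dependency
#' back-propagation, normalized by `(N - 1)(N - 2) / 2` so values lie in
#' `[0, 1]`. Node pairs in different components contribute nothing. With
#' fewer than 3 nodes all values are 0 (with a warning).
#'
#' @param network `microbial_network`.
#' @return named numeric vector of normalized betweenness values.
#' @export
betweenness_centrality <- function(network) {
  network <- as_network(network)
  n <- length(network$nodes)
  if (n < 3) {
    warning("betweenness undefined for networks with < 3 nodes; returning zeros")
    return(setNames(numeric(n), network$nodes))
  }
  idx <- network_index(network)
  adj <- vector("list", n)
  for (k in seq_along(idx$i)) {
    adj[[idx$i[k]]] <- c(adj[[idx$i[k]]], idx$j[k])
    adj[[idx$j[k]]] <- c(adj[[idx$j[k]]], idx$i[k])
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    stack <- integer(0)
    queue <- c(s); qhead <- 1L
    preds <- vector("list", n)
    while (qhead <= length(queue)) {
      v <- queue[qhead]; qhead <- qhead + 1L
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(stack)) {
      for (u in preds[[v]])
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc <- bc / 2                      # undirected: each pair counted twice
  setNames(bc / ((n - 1) * (n - 2) / 2), idx$nodes)
}

#' Keystone taxa by betweenness cutoff
#'
#' Taxa whose normalized betweenness strictly exceeds `cutoff`, in
#' descending order of centrality (alphabetical tie-break).
#'
#' @param centrality named betweenness vector from
#'   [betweenness_centrality()].
#' @param cutoff threshold in (0, 1); 0.10 in the motivating study, chosen
#'   because ~90% of centrality values fell below it.
#' @return data.frame `taxon, betweenness`, possibly empty.
#' @export
keystone_taxa <- function(centrality, cutoff = 0.10) {
  if (cutoff <= 0 || cutoff >= 1) stop_ug("cutoff must lie in (0, 1)")
  sel <- centrality[centrality > cutoff]
  ord <- order(-sel, names(sel))
  data.frame(taxon = names(sel)[ord], betweenness = unname(sel[ord]),
             row.names = NULL)
}

#' Neighbours of a focal taxon, strongest first
#'
#' @param network `microbial_network`.
#' @param focal taxon name present in the network.
#' @param top_n number of neighbours to return (default all).
#' @return data.frame `taxon, weight` sorted by descending edge weight.
#' @export
neighbor_correlations <- function(network, focal, top_n = Inf) {
  network <- as_network(network)
  if (!focal %in% network$nodes)
    stop_ug("taxon '%s' is not in the network", focal)
  e <- network$edges
  hit <- e$from == focal | e$to == focal
  other <- ifelse(e$from[hit] == focal, e$to[hit], e$from[hit])
  ord <- order(-e$weight[hit], other)
  out <- data.frame(taxon = other[ord], weight = e$weight[hit][ord],
                    row.names = NULL)
  head(out, n = top_n)
}

#' Network serialization
#'
#' Edge lists are written as tab-delimited text (`from`, `to`, `weight`);
#' GraphML export goes through igraph.
#'
#' @param network `microbial_network` / @param path file path.
#' @export
write_network_edgelist <- function(network, path) {
  network <- as_network(network)
  write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edgelist
#' @param threshold threshold recorded on the read-back object.
#' @export
read_network_edgelist <- function(path, threshold) {
  e <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(e$from, e$to)))
  structure(list(nodes = nodes, edges = e, threshold = threshold),
            class = "microbial_network")
}

#' @rdname write_network_edgelist
#' @export
as_igraph <- function(network) {
  network <- as_network(network)
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' @rdname write_network_edgelist
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
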