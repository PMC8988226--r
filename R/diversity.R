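#' Alpha diversity indices
#'
#' `observed_taxa()` counts taxa with nonzero abundance; `inverse_simpson()`
#' is `1 / sum(p_i^2)`; `pielou_evenness()` is Shannon entropy divided by
#' `log(observed)`, reported as `NA` for single-taxon samples (division by
#' `log 1`). All operate per sample on a count table and fail on zero-total
#' samples.
#'
#' @param x count table (samples x taxa).
#' @return named numeric vector, one value per sample.
#' @export
observed_taxa <- function(x) {
  check_positive_totals(x)
  rowSums(x > 0)
}

#' @rdname observed_taxa
#' @export
inverse_simpson <- function(x) {
  p <- relative_abundance(x)
  1 / rowSums(p^2)
}

#' @rdname observed_taxa
#' @export
pielou_evenness <- function(x) {
  p <- relative_abundance(x)
  shannon <- -rowSums(ifelse(p > 0, p * log(p), 0))
  s <- rowSums(x > 0)
  ifelse(s > 1, shannon / log(s), NA_real_)
}

#' @rdname observed_taxa
#' @return for `alpha_diversity()`, a data.frame with one row per sample.
#' @export
alpha_diversity <- function(x) {
  data.frame(sample_id = rownames(x),
             observed = observed_taxa(x),
             inverse_simpson = inverse_simpson(x),
             pielou = pielou_evenness(x),
             row.names = NULL)
}

check_positive_totals <- function(x) {
  x <- validate_count_table(x)
  tot <- rowSums(x)
  if (any(tot == 0))
    stop_ug("zero-total sample(s): %s", paste(rownames(x)[tot == 0], collapse = ", "))
  invisible(x)
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa, computed on
#' counts as given.
#'
#' @param x count table.
#' @return symmetric distance matrix (base `matrix` with zero diagonal).
#' @export
bray_curtis <- function(x) {
  check_positive_totals(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - x[j, ])) / sum(xi + x[j, ])
    }
  }
  d
}

# Branch table for UniFrac: for each edge, proportion of each sample's reads
# descending from it, by postorder accumulation over the tree.
branch_profile <- function(x, tree) {
  absent <- setdiff(colnames(x), tree$tip.label)
  if (length(absent) > 0)
    stop_ug("taxa absent from tree: %s", paste(absent, collapse = ", "))
  p <- relative_abundance(x)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- ape::reorder.phylo(tree, "postorder")
  # node_mass[node, sample]: fraction of sample's reads at tips below node
  node_mass <- matrix(0, nnode, nrow(x))
  tipidx <- match(tree$tip.label, colnames(x))
  present <- !is.na(tipidx)
  node_mass[seq_len(ntip)[present], ] <- t(p[, tipidx[present], drop = FALSE])
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    node_mass[par, ] <- node_mass[par, ] + node_mass[child, ]
  }
  list(lengths = tree$edge.length,
       mass = node_mass[tree$edge[, 2], , drop = FALSE],  # edges x samples
       tree = tree, ntip = ntip)
}

# Root-to-tip distances in tip-label order.
root_tip_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge)))
    depth[pre$edge[e, 2]] <- depth[pre$edge[e, 1]] + pre$edge.length[e]
  depth[seq_len(ntip)]
}

#' UniFrac phylogenetic distances
#'
#' `weighted_unifrac()` accumulates `l_b * |p_A(b) - p_B(b)|` over branches,
#' where `p(b)` is the fraction of a sample's reads descending from branch
#' `b`; the normalized variant divides by `sum_tips d_tip * (p_A + p_B)`
#' with `d_tip` the root-to-tip distance, giving values in `[0, 1]`.
#' `unweighted_unifrac()` is the branch length unique to either sample's
#' taxon set divided by the branch length spanned by their union. All table
#' taxa must be tips of `tree`.
#'
#' @param x count table.
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param normalized logical; normalize weighted UniFrac (default TRUE,
#'   matching common implementations).
#' @return symmetric distance matrix.
#' @export
weighted_unifrac <- function(x, tree, normalized = TRUE) {
  bp <- branch_profile(x, tree)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (normalized) {
    depths <- root_tip_depths(bp$tree)
    tipmass <- {
      p <- relative_abundance(x)
      p[, match(bp$tree$tip.label, colnames(x)), drop = FALSE]
    }
    persample <- as.vector(tipmass %*% depths)  # sum_tips d_tip * p_tip
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(bp$lengths * abs(bp$mass[, i] - bp$mass[, j]))
      d[i, j] <- d[j, i] <- if (normalized)
        num / (persample[i] + persample[j]) else num
    }
  }
  d
}

#' @rdname weighted_unifrac
#' @export
unweighted_unifrac <- function(x, tree) {
  bp <- branch_profile(x, tree)
  pres <- bp$mass > 0
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      either <- pres[, i] | pres[, j]
      uniq <- xor(pres[, i], pres[, j])
      denom <- sum(bp$lengths[either])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(bp$lengths[uniq]) / denom
    }
  }
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the Gower double-centered matrix of squared
#' distances. Axes with eigenvalue <= 0 are excluded from the coordinates;
#' all eigenvalues (including negative ones) are reported, with proportion
#' explained relative to the sum of positive eigenvalues.
#'
#' @param d symmetric distance matrix.
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `proportion_explained`.
#' @export
pcoa <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(1e-12, 1e-9 * abs(e$values[1]))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))
  possum <- sum(e$values[e$values > 0])
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion_explained = e$values / possum)
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
}

check_distance_matrix <- function(d, tol = 1e-12) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_ug("distance matrix must be square")
  if (max(abs(d - t(d))) > max(tol, 1e-8 * max(abs(d))))
    stop_ug("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) stop_ug("distance matrix diagonal must be zero")
  if (any(d < -tol)) stop_ug("distances must be nonnegative")
  (d + t(d)) / 2
}

#' PERMANOVA on a distance matrix
#'
#' Sequential (order-of-entry) partitioning of the distance matrix's sum of
#' squares, with a permutation p-value
#' `(#\{F_perm >= F_obs\} + 1) / (permutations + 1)` for `test_term`.
#' Backed by [vegan::adonis2()] with `by = "terms"`; put the adjusted term
#' last to test it after the covariates.
#'
#' @param d distance matrix (samples match `metadata` rows).
#' @param metadata data.frame with sample_id row names.
#' @param terms ordered character vector of covariate names; the sums of
#'   squares are sequential in this order.
#' @param test_term covariate whose pseudo-F and p-value are returned
#'   (default: the last term).
#' @param permutations number of label permutations (default 999).
#' @param seed optional integer seed; the p-value is deterministic given it.
#' @return list with `pseudo_F`, `p_value`, and the full `table`.
#' @export
permanova <- function(d, metadata, terms, test_term = terms[length(terms)],
                      permutations = 999, seed = NULL) {
  d <- check_distance_matrix(d)
  if (!all(rownames(d) %in% rownames(metadata)))
    stop_ug("metadata missing sample(s): %s",
            paste(setdiff(rownames(d), rownames(metadata)), collapse = ", "))
  md <- metadata[rownames(d), , drop = FALSE]
  missing <- setdiff(terms, names(md))
  if (length(missing) > 0)
    stop_ug("unknown covariate(s): %s", paste(missing, collapse = ", "))
  if (!test_term %in% terms) stop_ug("test_term must be one of terms")
  tt <- md[[test_term]]
  if (length(unique(tt[!is.na(tt)])) < 2)
    stop_ug("test_term '%s' is constant", test_term)
  if (permutations < 1) stop_ug("permutations must be >= 1")
  fml <- stats::as.formula(paste("as.dist(d) ~", paste(terms, collapse = " + ")))
  fit <- with_seed_if(seed,
    vegan::adonis2(fml, data = md, permutations = permutations, by = "terms"))
  row <- match(test_term, rownames(fit))
  list(pseudo_F = fit$F[row], p_value = fit$`Pr(>F)`[row],
       table = as.data.frame(fit))
}

#' Read and write square distance matrices
#'
#' Tab-delimited square matrix with a header row and a first column of
#' sample ids.
#' @param d distance matrix / @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  d <- check_distance_matrix(d)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = 1)
  check_distance_matrix(as.matrix(df))
}
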