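#' Project a symmetric matrix to the nearest correlation matrix
#'
#' Eigenvalue clipping (negative eigenvalues set to zero) followed by
#' rescaling to unit diagonal. Used to make "stated" planted-correlation
#' designs feasible when they are not positive semidefinite; the realized
#' planted values then differ from the nominal ones and are recorded in the
#' ground truth.
#'
#' @param m symmetric matrix with unit diagonal intent.
#' @return positive-semidefinite correlation matrix.
#' @export
nearest_correlation <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

check_basis_correlation <- function(m, n_taxa) {
  if (!is.matrix(m) || nrow(m) != n_taxa || ncol(m) != n_taxa)
    stop_ug("basis_correlation must be a %d x %d matrix", n_taxa, n_taxa)
  if (max(abs(m - t(m))) > 1e-10) stop_ug("basis_correlation must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10) stop_ug("basis_correlation must have unit diagonal")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_ug("basis_correlation is not positive semidefinite (min eigenvalue %.3g); consider nearest_correlation()", min(ev))
  invisible(m)
}

# PSD square root via eigendecomposition (chol fails on semidefinite input).
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate compositional counts with a planted log-basis correlation
#'
#' Latent basis abundances are multivariate log-normal: log-scale Gaussian
#' with the given correlation matrix (unit variances scaled by `log_sd`),
#' exponentiated and normalized to a composition per sample; counts are then
#' multinomial at a per-sample depth drawn log-normally around `depth_mean`.
#' This matches the generative assumptions under which SparCC's basis
#' correlations are identified, so recovery tests are interpretable.
#'
#' @param n_samples number of samples (>= 3).
#' @param taxa character vector of taxon ids.
#' @param basis_correlation symmetric PSD matrix with unit diagonal
#'   (default identity = no planted association).
#' @param depth_mean expected sequencing depth (default 15000).
#' @param depth_sdlog log-scale sd of depth (default 0.3; heterogeneous
#'   depths exercise rarefaction).
#' @param log_mean per-taxon log-scale mean(s), recycled (default 0); may
#'   also be an `n_samples x length(taxa)` matrix for per-sample structure
#'   (e.g. community state types).
#' @param log_sd log-scale standard deviation (default 1).
#' @param seed optional integer seed.
#' @return list with `counts` (count table) and `truth` (ground-truth list
#'   recording the planted structure and the seed).
#' @export
simulate_counts <- function(n_samples, taxa, basis_correlation = NULL,
                            depth_mean = 15000, depth_sdlog = 0.3,
                            log_mean = 0, log_sd = 1, seed = NULL) {
  d <- length(taxa)
  if (anyDuplicated(taxa)) stop_ug("duplicate taxon names")
  if (n_samples < 3) stop_ug("n_samples must be >= 3")
  if (is.null(basis_correlation)) basis_correlation <- diag(d)
  check_basis_correlation(basis_correlation, d)
  if (is.matrix(log_mean)) {
    if (!all(dim(log_mean) == c(n_samples, d)))
      stop_ug("log_mean matrix must be n_samples x n_taxa")
    mu <- log_mean
  } else {
    mu <- matrix(rep_len(log_mean, d), n_samples, d, byrow = TRUE)
  }
  counts <- with_seed_if(seed, {
    z <- matrix(rnorm(n_samples * d), n_samples, d) %*% psd_sqrt(basis_correlation)
    basis <- exp(z * log_sd + mu)
    frac <- basis / rowSums(basis)
    depth <- pmax(1L, as.integer(round(rlnorm(n_samples,
                                              log(depth_mean) - depth_sdlog^2 / 2,
                                              depth_sdlog))))
    cnt <- t(vapply(seq_len(n_samples),
                    function(i) rmultinom(1, depth[i], frac[i, ])[, 1],
                    integer(d)))
    cnt
  })
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n_samples)), taxa)
  storage.mode(counts) <- "integer"
  truth <- list(basis_correlation = basis_correlation,
                log_mean = mu, log_sd = log_sd,
                depth_mean = depth_mean, seed = seed)
  list(counts = counts, truth = truth)
}

#' Simulate two community state types
#'
#' "Dominated" samples give `dominant_taxon` a relative abundance drawn
#' uniformly in (0.7, 0.98), with the remaining mass spread over the other
#' taxa by a symmetric Dirichlet; "diverse" samples draw their whole
#' composition from a flat symmetric Dirichlet. Either group may be empty
#' (at least two samples in total). State labels are recorded.
#'
#' @param taxa character vector of taxon ids.
#' @param n_dominated,n_diverse group sizes.
#' @param dominant_taxon member of `taxa` dominating the first group.
#' @param depth_mean expected sequencing depth.
#' @param seed optional integer seed.
#' @return list with `counts` and `truth` (`state_type_labels` a named
#'   character vector with values `"dominated"`/`"diverse"`).
#' @export
simulate_state_types <- function(taxa, n_dominated, n_diverse, dominant_taxon,
                                 depth_mean = 15000, seed = NULL) {
  if (!dominant_taxon %in% taxa)
    stop_ug("dominant_taxon '%s' not in taxon list", dominant_taxon)
  n <- n_dominated + n_diverse
  if (n < 2) stop_ug("need at least two samples in total")
  d <- length(taxa)
  j <- match(dominant_taxon, taxa)
  counts <- with_seed_if(seed, {
    frac <- matrix(0, n, d)
    if (n_dominated > 0) {
      p_dom <- runif(n_dominated, 0.7, 0.98)
      rest <- rdirichlet(n_dominated, rep(1, d - 1))
      frac[seq_len(n_dominated), -j] <- rest * (1 - p_dom)
      frac[seq_len(n_dominated), j] <- p_dom
    }
    if (n_diverse > 0)
      frac[n_dominated + seq_len(n_diverse), ] <- rdirichlet(n_diverse, rep(1, d))
    depth <- pmax(1L, as.integer(round(rlnorm(n, log(depth_mean) - 0.045, 0.3))))
    t(vapply(seq_len(n), function(i) rmultinom(1, depth[i], frac[i, ])[, 1],
             integer(d)))
  })
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n)), taxa)
  storage.mode(counts) <- "integer"
  labels <- setNames(rep(c("dominated", "diverse"), c(n_dominated, n_diverse)),
                     rownames(counts))
  list(counts = counts,
       truth = list(state_type_labels = labels, dominant_taxon = dominant_taxon,
                    seed = seed))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a random rooted bifurcating tree
#'
#' Random bifurcating topology with exponential branch lengths, one tip per
#' taxon; a stand-in for a neighbour-joining tree built from an alignment.
#'
#' @param taxa character vector of unique taxon ids (>= 2).
#' @param seed optional integer seed.
#' @return an [ape::phylo] object, rooted, with positive branch lengths.
#' @export
simulate_tree <- function(taxa, seed = NULL) {
  if (length(taxa) < 2) stop_ug("need at least 2 taxa for a tree")
  if (anyDuplicated(taxa)) stop_ug("duplicate taxon names in tree tips")
  with_seed_if(seed, {
    tr <- ape::rtree(length(taxa), tip.label = taxa,
                     br = function(n) rexp(n, rate = 5) + 1e-4)
    tr
  })
}

#' Spike contaminant taxa whose frequency tracks 1/concentration
#'
#' Adds `n_contaminants` taxa whose expected relative abundance in each
#' sample is proportional to the reciprocal of that sample's DNA
#' concentration, with multiplicative log-normal noise — the signature that
#' frequency-based contaminant screening detects. With `noise_sdlog = 0`
#' the spike is noiseless and [decontam_frequency()] scores it near zero.
#'
#' @param x count table of resident taxa.
#' @param dna_concentration strictly positive, named by sample or in row
#'   order.
#' @param n_contaminants number of taxa to add (0 returns `x` unchanged).
#' @param strength target mean relative abundance of each contaminant at the
#'   geometric-mean concentration (default 0.05).
#' @param noise_sdlog log-scale sd of the multiplicative noise (default 0.3).
#' @param seed optional integer seed.
#' @return list with `counts` (augmented table) and `truth`
#'   (`contaminant_flags`: named logical over all taxa).
#' @export
spike_contaminants <- function(x, dna_concentration, n_contaminants,
                               strength = 0.05, noise_sdlog = 0.3, seed = NULL) {
  x <- validate_count_table(x)
  conc <- dna_concentration
  if (!is.null(names(conc))) conc <- conc[rownames(x)]
  if (length(conc) != nrow(x) || anyNA(conc) || any(conc <= 0))
    stop_ug("dna_concentration must be strictly positive for every sample")
  flags <- setNames(rep(FALSE, ncol(x)), colnames(x))
  if (n_contaminants == 0)
    return(list(counts = x, truth = list(contaminant_flags = flags,
                                         dna_concentration = conc, seed = seed)))
  gm <- exp(mean(log(conc)))
  tot <- rowSums(x)
  newcols <- with_seed_if(seed, {
    vapply(seq_len(n_contaminants), function(k) {
      f <- strength * gm / conc
      if (noise_sdlog > 0) f <- f * rlnorm(length(f), -noise_sdlog^2 / 2, noise_sdlog)
      f <- pmin(f, 0.9)
      as.integer(round(f / (1 - f) * tot))
    }, integer(nrow(x)))
  })
  colnames(newcols) <- sprintf("contaminant_%02d", seq_len(n_contaminants))
  rownames(newcols) <- rownames(x)
  out <- cbind(x, newcols)
  storage.mode(out) <- "integer"
  flags <- setNames(c(rep(FALSE, ncol(x)), rep(TRUE, n_contaminants)),
                    colnames(out))
  list(counts = out,
       truth = list(contaminant_flags = flags, dna_concentration = conc,
                    seed = seed))
}

#' Planted-correlation design helpers
#'
#' `planted_pair_correlation()` builds an identity correlation matrix with a
#' single correlated pair. `hub_correlation()` builds a hub design in which
#' one taxon is nominally correlated at `rho` with `n_leaves` otherwise
#' uncorrelated taxa; because that nominal matrix is not positive
#' semidefinite for `rho > 1/sqrt(n_leaves)`, it is projected with
#' [nearest_correlation()] and the realized (feasible) values are returned —
#' for the default `rho = 0.6`, hub-leaf ~= 0.40 and leaf-leaf ~= 0.04.
#'
#' @param n_taxa matrix dimension.
#' @param pair indices of the correlated pair.
#' @param rho nominal planted correlation.
#' @return correlation matrix.
#' @export
planted_pair_correlation <- function(n_taxa, pair = c(1, 2), rho = 0.8) {
  m <- diag(n_taxa)
  m[pair[1], pair[2]] <- m[pair[2], pair[1]] <- rho
  m
}

#' @rdname planted_pair_correlation
#' @param hub index of the hub taxon.
#' @param n_leaves number of taxa attached to the hub.
#' @export
hub_correlation <- function(n_taxa, hub = 1, n_leaves = 8, rho = 0.6) {
  if (n_taxa < n_leaves + 1) stop_ug("n_taxa must exceed n_leaves")
  m <- diag(n_taxa)
  leaves <- hub + seq_len(n_leaves)
  m[hub, leaves] <- m[leaves, hub] <- rho
  nearest_correlation(m)
}
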