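#' SparCC compositional correlation estimation
#'
#' Estimates correlations between the latent (basis) log abundances
#' underlying compositional count data. For each of `inner_resamples`
#' resamples, per-sample fractions are drawn from a Dirichlet posterior with
#' a unit pseudocount over the observed counts; the variation matrix
#' `t_ij = Var[log(f_i / f_j)]` is formed; the basis log-variances
#' `omega_i^2` solve the linear system implied by the sparsity approximation
#' `t_ij ~ omega_i^2 + omega_j^2` (system matrix `(D - 2) I + 1`); and
#' correlations follow as
#' `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`, clamped
#' to `[-1, 1]`. The sparsity assumption is protected by iterative
#' exclusion: up to `exclusion_iterations` times, the strongest remaining
#' pair with `|rho| > exclusion_threshold` is removed from the system
#' (one pair per iteration, strongest first) and the basis variances are
#' re-solved. The returned matrix is the element-wise median over
#' resamples.
#'
#' @param x count table with >= 4 taxa and >= 3 samples; no taxon may be
#'   zero in every sample.
#' @param inner_resamples Dirichlet posterior resamples (default 20).
#' @param exclusion_threshold `|rho|` above which a pair is excluded from
#'   the basis-variance system (default 0.1).
#' @param exclusion_iterations maximum exclusion rounds (default 10).
#' @param seed optional integer seed.
#' @return list of class `sparcc_fit`: `cor` (taxa x taxa), `n_resamples`,
#'   `exclusions` (per-resample list of excluded pairs).
#' @export
sparcc <- function(x, inner_resamples = 20, exclusion_threshold = 0.1,
                   exclusion_iterations = 10, seed = NULL) {
  x <- validate_count_table(x)
  d <- ncol(x)
  if (d < 4) stop_ug("SparCC needs >= 4 taxa (basis system underdetermined)")
  if (nrow(x) < 3) stop_ug("SparCC needs >= 3 samples")
  allzero <- colSums(x) == 0
  if (any(allzero))
    stop_ug("taxa with all-zero counts: %s",
            paste(colnames(x)[allzero], collapse = ", "))
  res <- with_seed_if(seed, {
    fits <- vector("list", inner_resamples)
    for (r in seq_len(inner_resamples)) {
      frac <- dirichlet_fractions(x)
      fits[[r]] <- sparcc_once(log(frac), exclusion_threshold,
                               exclusion_iterations)
    }
    fits
  })
  arr <- vapply(res, `[[`, matrix(0, d, d), "rho")
  med <- matrix(elementwise_median(matrix(arr, d * d, inner_resamples)), d, d)
  med <- (med + t(med)) / 2
  diag(med) <- 1
  dimnames(med) <- list(colnames(x), colnames(x))
  structure(list(cor = med, n_resamples = inner_resamples,
                 exclusions = lapply(res, `[[`, "excluded")),
            class = "sparcc_fit")
}

# Row-wise median of a matrix, vectorized over rows (one global sort).
elementwise_median <- function(m) {
  r <- ncol(m)
  if (r == 1) return(m[, 1])
  sorted <- matrix(m[order(row(m), m)], nrow(m), r, byrow = TRUE)
  if (r %% 2 == 1) sorted[, (r + 1) / 2]
  else (sorted[, r / 2] + sorted[, r / 2 + 1]) / 2
}

# Posterior fractions: Dirichlet(counts + 1) per sample.
dirichlet_fractions <- function(x) {
  g <- matrix(rgamma(length(x), shape = t(x) + 1), ncol(x), nrow(x))
  t(g) / colSums(g)
}

# One SparCC fit on a log-fraction matrix (samples x taxa).
sparcc_once <- function(logf, exclusion_threshold, exclusion_iterations) {
  d <- ncol(logf)
  cv <- cov(logf)
  v <- diag(cv)
  tmat <- outer(v, v, "+") - 2 * cv          # variation matrix t_ij
  m <- matrix(1, d, d); diag(m) <- d - 1     # (D - 2) I + ones
  tt <- tmat
  excluded <- matrix(integer(0), 0, 2)
  rho <- solve_basis(m, tt, tmat)
  for (it in seq_len(exclusion_iterations)) {
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded) > 0) cand[excluded] <- 0
    top <- arrayInd(which.max(cand), dim(cand))
    i <- top[1]; j <- top[2]
    if (cand[i, j] <= exclusion_threshold) break
    # Refuse exclusions that would disconnect a taxon from the system.
    if (m[i, i] <= 2 || m[j, j] <= 2) break
    m[i, j] <- m[j, i] <- 0
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    tt[i, j] <- tt[j, i] <- 0
    excluded <- rbind(excluded, c(i, j), c(j, i))
    rho <- solve_basis(m, tt, tmat)
  }
  list(rho = rho, excluded = excluded[seq_len(nrow(excluded)) %% 2 == 1, ,
                                      drop = FALSE])
}

# Solve for basis variances and convert to correlations.
solve_basis <- function(m, tt, tmat) {
  omega2 <- tryCatch(solve(m, rowSums(tt)),
                     error = function(e) rep(NA_real_, nrow(m)))
  if (anyNA(omega2)) omega2 <- rowSums(tt) / diag(m)  # degenerate fallback
  omega2 <- pmax(omega2, 1e-12)
  om <- sqrt(omega2)
  rho <- (outer(omega2, omega2, "+") - tmat) / (2 * outer(om, om))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

#' Permutation-null edge threshold
#'
#' Destroys all inter-taxon association by independently permuting every
#' taxon's counts across samples (marginals preserved), runs SparCC, and
#' pools all off-diagonal correlations over `trials` independent
#' permutations. The threshold is the empirical `1 - tail` quantile of the
#' pooled null distribution: correlations above it are unlikely to arise
#' without real co-occurrence structure.
#'
#' @inheritParams sparcc
#' @param trials number of permutation trials (default 1000, as in the
#'   motivating study; 100 is a documented fast mode).
#' @param tail upper-tail fraction defining the threshold (default 0.05;
#'   `tail = 0` gives the null maximum).
#' @param sparcc_params named list of overrides passed to [sparcc()].
#' @return list of class `sparcc_null`: `values` (pooled null
#'   correlations), `n_trials`, `tail`, `threshold`.
#' @export
permutation_threshold <- function(x, trials = 1000, tail = 0.05, seed = NULL,
                                  sparcc_params = list()) {
  x <- validate_count_table(x)
  if (trials < 1) stop_ug("trials must be >= 1")
  if (tail < 0 || tail >= 1) stop_ug("tail must lie in [0, 1)")
  n <- nrow(x)
  ut <- upper.tri(diag(ncol(x)))
  values <- with_seed_if(seed, {
    vals <- vector("list", trials)
    for (b in seq_len(trials)) {
      perm <- apply(x, 2, function(col) col[sample.int(n)])
      rownames(perm) <- rownames(x)
      fit <- do.call(sparcc, c(list(x = perm), sparcc_params))
      vals[[b]] <- fit$cor[ut]
    }
    unlist(vals)
  })
  thr <- as.numeric(quantile(values, 1 - tail, names = FALSE, type = 7))
  structure(list(values = values, n_trials = trials, tail = tail,
                 threshold = thr),
            class = "sparcc_null")
}
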