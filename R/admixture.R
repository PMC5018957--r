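#' Fit the Bayesian admixture model for one K
#'
#' STRUCTURE-style Gibbs sampler on haploid binary genotypes: each
#' accession a draws the allele at site s from cluster z[a,s] with
#' probability p[z,s]; z[a,s] ~ Categorical(q[a, ] * likelihood); cluster
#' frequencies get a Beta(lambda, lambda) prior (lambda = 1, the
#' "uncorrelated frequencies" default); ancestry rows q[a, ] get a
#' symmetric Dirichlet(alpha) prior with alpha itself sampled by a
#' Metropolis step under a uniform prior on (0, 10]. The run's
#' log-likelihood L is the post-burn-in mean of the data log-likelihood;
#' Q and P are posterior means.
#'
#' `reps` counts post-burn-in sweeps, so total sweeps are
#' `burnin + reps`.
#'
#' @param M a `biallelic_matrix` (or plain 0/1 matrix with accession row
#'   names).
#' @param K number of ancestral populations (1 <= K <= accessions).
#' @param burnin burn-in sweeps (default 30000).
#' @param reps post-burn-in sweeps (default 60000).
#' @param seed integer seed.
#' @param alpha_init,alpha_prop_sd,alpha_max Dirichlet-alpha sampler
#'   settings (defaults 1, 0.05, 10).
#' @param lambda Beta prior parameter for cluster frequencies (default 1).
#' @return Object of class `admixture_fit`: list with `K`, `Q`
#'   (accessions x K posterior-mean ancestry, rows sum to 1), `P`
#'   (K x sites posterior-mean alt frequencies), `L` (mean post-burn-in
#'   log-likelihood), `L_trace`, `alpha`, `burnin`, `reps`, `seed`.
#' @export
fit_admixture <- function(M, K, burnin = 30000L, reps = 60000L, seed = 1L,
                          alpha_init = 1, alpha_prop_sd = 0.05,
                          alpha_max = 10, lambda = 1) {
  G <- if (inherits(M, "biallelic_matrix")) M$G else M
  stopifnot(is.matrix(G), all(G %in% c(0L, 1L)))
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(G))
    stop("K (", K, ") exceeds the number of accessions (", nrow(G), ")")
  if (reps <= 0L) stop("reps (post-burn-in sweeps) must be positive")
  set.seed(seed)
  res <- admixture_gibbs(G, as.integer(K), as.integer(burnin),
                         as.integer(reps), alpha_init, alpha_prop_sd,
                         alpha_max, lambda)
  rownames(res$Q) <- rownames(G)
  structure(list(K = as.integer(K), Q = res$Q, P = res$P, L = res$L,
                 L_trace = res$L_trace, alpha = res$alpha,
                 burnin = as.integer(burnin), reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K=%d, %d accession(s), L=%.2f (burnin %d, reps %d, seed %d)\n",
              x$K, nrow(x$Q), x$L, x$burnin, x$reps, x$seed))
  invisible(x)
}

#' Run the admixture model over a range of K with replicate runs
#'
#' @param M as in [fit_admixture()].
#' @param k_range integer vector of K values (e.g. `1:15`).
#' @param n_runs replicate runs per K (default 3).
#' @param seed base seed; run r of K k uses `seed + 1000 * k + r`.
#' @param ... passed to [fit_admixture()].
#' @return List with `fits` (list of lists of `admixture_fit`, indexed
#'   `fits[[as.character(K)]][[r]]`) and `L` (named list of per-K replicate
#'   log-likelihood vectors).
#' @export
admixture_scan <- function(M, k_range, n_runs = 3L, seed = 1L, ...) {
  fits <- lapply(k_range, function(k)
    lapply(seq_len(n_runs), function(r)
      fit_admixture(M, k, seed = seed + 1000L * k + r, ...)))
  names(fits) <- as.character(k_range)
  L <- lapply(fits, function(fk) vapply(fk, `[[`, 0, "L"))
  list(fits = fits, L = L)
}

#' Evanno delta-K model selection
#'
#' For interior K with replicate runs, delta K is the mean over replicates
#' of |L_r(K-1) - 2 L_r(K) + L_r(K+1)| divided by the standard deviation
#' of L(K) across replicates (the Structure Harvester implementation of
#' Evanno's statistic). When sd(L(K)) = 0: delta K is reported as `Inf` if
#' the mean second difference is non-zero, and as 0 (with a warning)
#' when it is also zero.
#'
#' @param L_runs named list: `L_runs[["k"]]` is the vector of replicate
#'   log-likelihoods at K = k; K values must be consecutive integers.
#' @return `data.frame(K, mean_L, sd_L, delta_K)`; `delta_K` is `NA` at
#'   the boundary K values.
#' @export
evanno_delta_k <- function(L_runs) {
  ks <- as.integer(names(L_runs))
  if (length(ks) < 3L) stop("Evanno delta K needs >= 3 consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  nrep <- lengths(L_runs)
  if (any(nrep < 2L))
    stop("each K needs >= 2 replicate runs for a standard deviation; K = ",
         paste(ks[nrep < 2L], collapse = ", "), " has fewer")
  if (length(unique(nrep)) != 1L)
    stop("all K values must have the same number of replicate runs")
  Lmat <- do.call(cbind, L_runs)   # replicates x K
  mean_L <- colMeans(Lmat)
  sd_L <- apply(Lmat, 2, sd)
  delta <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    sec <- abs(Lmat[, i - 1] - 2 * Lmat[, i] + Lmat[, i + 1])
    num <- mean(sec)
    delta[i] <- if (sd_L[i] > 0) num / sd_L[i]
    else if (num > 0) Inf
    else {
      warning("sd(L) and second difference both zero at K = ", ks[i],
              "; delta K reported as 0")
      0
    }
  }
  data.frame(K = ks, mean_L = mean_L, sd_L = sd_L, delta_K = delta,
             row.names = NULL)
}

#' Align an estimated ancestry matrix to a reference up to cluster
#' permutation
#'
#' Label switching makes cluster indices arbitrary; this finds the column
#' permutation of `Q` minimising the mean absolute difference to `Q_ref`
#' (exhaustive over permutations, K <= 8).
#'
#' @param Q,Q_ref accessions x K matrices.
#' @return List with `Q` (permuted), `perm`, and `mad` (mean |Q - Q_ref|).
#' @export
match_clusters <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q), K <= 8)
  perms <- permutations_of(K)
  best <- NULL; best_mad <- Inf
  for (i in seq_len(nrow(perms))) {
    mad <- mean(abs(Q[, perms[i, ], drop = FALSE] - Q_ref))
    if (mad < best_mad) { best_mad <- mad; best <- perms[i, ] }
  }
  list(Q = Q[, best, drop = FALSE], perm = best, mad = best_mad)
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(first) {
    rest <- setdiff(seq_len(K), first)
    cbind(first, matrix(rest[sub], nrow(sub)), deparse.level = 0)
  }))
}
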