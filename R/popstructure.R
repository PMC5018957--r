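#' p-distance matrix from a bi-allelic matrix
#'
#' Entry (a, b) is the proportion of sites at which accessions a and b
#' differ; equals `1 - pairwise_identity(M)` entrywise.
#'
#' @param M a `biallelic_matrix` with at least two accessions.
#' @return Symmetric accessions x accessions matrix with zero diagonal.
#' @export
p_distance <- function(M) {
  stopifnot(inherits(M, "biallelic_matrix"), nrow(M$G) >= 2)
  1 - pairwise_identity(M)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: the pair (i, j) minimising
#' Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k) is joined at
#' each step; ties are broken by the lexicographically smallest pair of
#' current node labels so results are platform-independent. Branch lengths
#' follow the standard NJ formulas; a negative branch length is clamped to
#' zero with the deficit moved to its sister branch, so the path length
#' between the joined nodes is preserved. On additive distances the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param D symmetric non-negative distance matrix with labelled rows.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  n <- nrow(D)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # subtrees carried as newick fragments; joining appends branch lengths
  node <- labels
  repeat {
    m <- nrow(D)
    if (m == 3L) break
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(node[cand[, 1]], node[cand[, 2]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_lab <- sprintf("(%s:%.10f,%s:%.10f)", node[i], bi, node[j], bj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    node <- c(node[keep], new_lab)
    dimnames(D2) <- list(node, node)
    D <- D2
  }
  # final three nodes: three-point formulas
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- c(b1, b2, b3)
  for (k in which(b < 0)) {
    # move the deficit onto the other two branches equally
    b[-k] <- b[-k] + b[k] / 2
    b[k] <- 0
  }
  nwk <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 node[1], b[1], node[2], b[2], node[3], b[3])
  ape::read.tree(text = nwk)
}

#' Neighbour-joining tree from a bi-allelic matrix
#'
#' Convenience wrapper: [p_distance()] then [neighbor_joining()].
#' @param M a `biallelic_matrix`.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(M) neighbor_joining(p_distance(M))

#' Write a tree as newick with fixed precision
#'
#' @param tree an [ape::phylo].
#' @param path output path.
#' @param digits branch-length decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  tree$edge.length <- round(tree$edge.length, digits)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Principal component analysis of a genotype matrix
#'
#' Sites (columns) are centred by their mean; with
#' `patterson_normalize = TRUE` each column is also divided by
#' sqrt(p(1 - p)) where p = (1 + sum g) / (2 + n) is the shrunken
#' allele-frequency estimate (haploid analogue of the smartpca
#' normalisation). Monomorphic sites are dropped. The accession covariance
#' matrix (1/S) X X' is eigendecomposed; scores are eigenvectors scaled by
#' the square root of their eigenvalues, so score columns are orthogonal
#' with squared norm equal to the eigenvalue.
#'
#' @param M a `biallelic_matrix` with >= 2 accessions and >= 2 polymorphic
#'   sites.
#' @param n_components number of components to return (default 10, capped).
#' @param patterson_normalize logical, default `TRUE`.
#' @return List with `scores` (accessions x components), `eigenvalues`
#'   (all, decreasing) and `n_sites_used`.
#' @export
run_pca <- function(M, n_components = 10L, patterson_normalize = TRUE) {
  stopifnot(inherits(M, "biallelic_matrix"), nrow(M$G) >= 2)
  G <- M$G
  n <- nrow(G)
  poly <- apply(G, 2, function(col) length(unique(col)) > 1L)
  if (!any(poly)) stop("all sites are monomorphic across these accessions")
  X <- G[, poly, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (patterson_normalize) {
    p_hat <- (1 + colSums(X)) / (2 + n)
    Xc <- sweep(Xc, 2, sqrt(p_hat * (1 - p_hat)), "/")
  }
  S <- ncol(Xc)
  C <- tcrossprod(Xc) / S
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  k <- min(n_components, n)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  list(scores = scores, eigenvalues = ev, n_sites_used = S)
}
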