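mk_mat <- function(G) {
  structure(list(G = G,
                 sites = data.frame(chrom = "chr1H",
                                    pos = seq_len(ncol(G)) * 100L,
                                    ref = "A", alt = "G")),
            class = "biallelic_matrix")
}

test_that("p-distance hits its closed-form extremes", {
  G <- rbind(a = rep(1L, 50), b = rep(1L, 50), c = rep(0L, 50))
  D <- p_distance(mk_mat(G))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("neighbour joining is exact on additive distances", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- neighbor_joining(D)
  expect_equal(ape::cophenetic.phylo(tr)[taxa, taxa], D, tolerance = 1e-8)
  # AB|CD split with branch lengths 1,2,(1),3,4
  expect_equal(as.numeric(ape::dist.topo(tr, ape::read.tree(
    text = "((A:1,B:2):1,C:3,D:4);"))), 0)
  ext <- setNames(tr$edge.length[tr$edge[, 2] <= 4], tr$tip.label)
  expect_equal(ext[taxa], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa solve the three-point equations exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  ext <- setNames(tr$edge.length[order(tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(ext[letters[1:3]]), c(0.5, 1.5, 2.5))
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
  Dbad <- D; Dbad[1, 2] <- 9
  expect_error(neighbor_joining(Dbad), "symmetric")
  Dneg <- D; Dneg[1, 2] <- Dneg[2, 1] <- -1
  expect_error(neighbor_joining(Dneg), "non-negative")
})

test_that("random additive trees (4-7 taxa) are recovered against the ls-enumeration oracle", {
  set.seed(11)
  for (i in 1:25) {
    nt <- sample(4:7, 1)
    rt <- ape::rtree(nt)
    rt$edge.length <- runif(nrow(rt$edge), 0.05, 2)
    D <- ape::cophenetic.phylo(rt)
    tr <- neighbor_joining(D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-6)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt), tr)), 0)
    # independent implementation agrees on topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), tr)), 0)
  }
})

test_that("two diverged groups come out monophyletic in the NJ tree", {
  hits <- vapply(1:10, function(s) {
    tr <- simulate_populations(two_group_model(
      n_per_group = 8, F = 0.3, n_sites = 400, seed = 400 + s))
    phy <- nj_tree(truth_matrix(tr))
    ape::is.monophyletic(phy, pure_names("A", 8)) &&
      ape::is.monophyletic(phy, pure_names("B", 8))
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("PCA separates two opposite-fixed clusters on PC1", {
  G <- rbind(matrix(1L, 5, 60), matrix(0L, 5, 60))
  rownames(G) <- sprintf("t%02d", 1:10)
  p <- run_pca(mk_mat(G))
  pc1 <- p$scores[, 1]
  expect_equal(length(unique(round(pc1, 9))), 2L)
  expect_lt(max(pc1[1:5]) * max(pc1[6:10]), 0)  # opposite signs
  expect_gt(p$eigenvalues[1] / sum(p$eigenvalues), 0.99)
})

test_that("PCA is invariant to duplicating an accession's genotypes", {
  set.seed(3)
  G <- matrix(rbinom(8 * 50, 1, 0.4), 8, 50)
  rownames(G) <- sprintf("t%d", 1:8)
  G[8, ] <- G[1, ]  # duplicate row
  p <- run_pca(mk_mat(G))
  # informative components only; trailing ~zero-eigenvalue axes are noise
  keep <- p$eigenvalues[seq_len(ncol(p$scores))] > 1e-8
  expect_equal(p$scores[1, keep], p$scores[8, keep], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PCA spectra behave: PSD, variance-preserving, orthogonal scores", {
  set.seed(4)
  G <- matrix(rbinom(12 * 80, 1, runif(80)), 12, 80, byrow = FALSE)
  G[, 1] <- 1L  # a monomorphic column must be dropped silently
  rownames(G) <- sprintf("t%02d", 1:12)
  p <- run_pca(mk_mat(G), n_components = 12)
  expect_true(all(p$eigenvalues >= 0))
  poly <- apply(G, 2, function(x) length(unique(x)) > 1)
  Xc <- sweep(G[, poly], 2, colMeans(G[, poly]))
  ph <- (1 + colSums(G[, poly])) / (2 + nrow(G))
  Xn <- sweep(Xc, 2, sqrt(ph * (1 - ph)), "/")
  expect_equal(sum(p$eigenvalues), sum(diag(tcrossprod(Xn) / ncol(Xn))),
               tolerance = 1e-8)
  gram <- crossprod(p$scores)
  expect_equal(gram, diag(diag(gram)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(run_pca(mk_mat(matrix(1L, 3, 5,
    dimnames = list(c("a", "b", "c"), NULL)))), "monomorphic")
})

test_that("admixed accessions land between the pure groups on PC1", {
  hits <- vapply(1:10, function(s) {
    adm <- data.frame(name = sprintf("m%d", 1:4),
                      A = c(0.35, 0.45, 0.55, 0.65))
    adm$B <- 1 - adm$A
    tr <- simulate_populations(two_group_model(
      n_per_group = 10, F = 0.3, n_sites = 500, admixed = adm,
      seed = 600 + s))
    p <- run_pca(truth_matrix(tr))
    pc1 <- p$scores[, 1]
    a_rng <- range(pc1[pure_names("A", 10)])
    b_rng <- range(pc1[pure_names("B", 10)])
    lo <- min(max(a_rng), max(b_rng)); hi <- max(min(a_rng), min(b_rng))
    all(pc1[adm$name] > lo & pc1[adm$name] < hi)
  }, NA)
  expect_gte(mean(hits), 0.95)
})
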