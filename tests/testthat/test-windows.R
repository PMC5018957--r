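test_that("genome windows tile chromosomes with a truncated last window", {
  w <- make_windows(c(chr1H = 12e6), w = 5e6)
  expect_equal(w$start, c(0, 5e6, 10e6))
  expect_equal(w$end, c(5e6, 10e6, 12e6))
  w1 <- make_windows(c(chr1H = 5e6), w = 5e6)
  expect_equal(nrow(w1), 1L)
  w2 <- make_windows(c(chr1H = 1), w = 5e6)
  expect_equal(c(w2$start, w2$end), c(0, 1))
  expect_error(make_windows(c(chr1H = 10), w = 0), "positive")
})

test_that("SNP counts respect half-open window boundaries and are conserved", {
  w <- make_windows(c(chr1H = 10e6), w = 5e6)
  cs <- mk_calls(pos = c(1L, 5000001L, 9999999L), alt = "G",
                 alt_reads = 9L, depth = 10L)
  d <- snp_density(cs, w)
  expect_equal(d$snp_count, c(1L, 2L))
  expect_equal(sum(d$snp_count), nrow(cs))
  empty <- mk_calls(integer(0), character(0), integer(0), integer(0))
  expect_equal(snp_density(empty, w)$snp_count, c(0L, 0L))
  beyond <- mk_calls(pos = 10000001L, alt = "G", alt_reads = 9L,
                     depth = 10L)
  expect_error(snp_density(beyond, w, chrom_lengths = c(chr1H = 10e6)),
               "chr1H:10000001")
})

test_that("haplotype diversity matches Nei's closed form", {
  sites <- data.frame(chrom = "chr1H", pos = c(10L, 20L, 30L),
                      ref = "A", alt = "G")
  w <- make_windows(c(chr1H = 100), w = 100)
  # four accessions, all haplotypes distinct -> (4/3)(1 - 4/16) = 1
  G <- rbind(a = c(0L, 0L, 0L), b = c(1L, 0L, 0L),
             c = c(0L, 1L, 0L), d = c(1L, 1L, 1L))
  M <- structure(list(G = G, sites = sites), class = "biallelic_matrix")
  expect_equal(haplotype_diversity(M, letters[1:4], w)$hd, 1)
  # two haplotypes at 2/2 -> (4/3)(1 - 1/2) = 2/3
  G2 <- rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L),
              c = c(1L, 1L, 0L), d = c(1L, 1L, 0L))
  M2 <- structure(list(G = G2, sites = sites), class = "biallelic_matrix")
  expect_equal(haplotype_diversity(M2, letters[1:4], w)$hd, 2 / 3,
               tolerance = 1e-12)
  # monomorphic window -> 0; windowless region -> NA
  G3 <- rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L))
  M3 <- structure(list(G = G3, sites = sites), class = "biallelic_matrix")
  w2 <- make_windows(c(chr1H = 100), w = 50)
  hd <- haplotype_diversity(M3, c("a", "b"), w2)$hd
  expect_equal(hd, c(0, NA))
  expect_error(haplotype_diversity(M3, "a", w2), ">= 2")
})

test_that("Hudson F_ST spans its defining extremes", {
  sites <- data.frame(chrom = "chr1H", pos = 1:20 * 10L, ref = "A",
                      alt = "G")
  w <- make_windows(c(chr1H = 300), w = 300)
  # fixed opposite alleles: Hw = 0 -> F_ST = 1
  G <- rbind(matrix(1L, 4, 20), matrix(0L, 4, 20))
  rownames(G) <- sprintf("t%d", 1:8)
  M <- structure(list(G = G, sites = sites), class = "biallelic_matrix")
  r <- pairwise_fst(M, sprintf("t%d", 1:4), sprintf("t%d", 5:8), w)
  expect_equal(r$genome_wide, 1)
  expect_error(pairwise_fst(M, sprintf("t%d", 1:4), sprintf("t%d", 4:8), w),
               "overlap")
  # identical allele frequencies with within-group variation -> ~0
  set.seed(6)
  Gn <- matrix(rbinom(100 * 1000, 1, rep(runif(1000, 0.2, 0.8),
                                         each = 100)), 100, 1000)
  rownames(Gn) <- sprintf("n%03d", 1:100)
  sitesn <- data.frame(chrom = "chr1H", pos = sort(sample.int(5e6, 1000)),
                       ref = "A", alt = "G")
  Mn <- structure(list(G = Gn, sites = sitesn), class = "biallelic_matrix")
  wn <- make_windows(c(chr1H = 5e6), w = 5e6)
  r0 <- pairwise_fst(Mn, sprintf("n%03d", 1:50), sprintf("n%03d", 51:100),
                     wn)
  expect_lt(abs(r0$genome_wide), 0.05)
})

test_that("window statistics ignore accession and site ordering", {
  tr <- simulate_populations(two_group_model(n_per_group = 6, n_sites = 200,
                                             chrom_len = 4e5, seed = 51))
  M <- truth_matrix(tr)
  w <- make_windows(c(chr1H = 4e5), w = 1e5)
  grpA <- pure_names("A", 6); grpB <- pure_names("B", 6)
  base_hd <- haplotype_diversity(M, grpA, w)$hd
  base_fst <- pairwise_fst(M, grpA, grpB, w)$windows$fst
  set.seed(9)
  perm_acc <- sample(nrow(M$G)); perm_site <- sample(ncol(M$G))
  M2 <- structure(list(G = M$G[perm_acc, perm_site],
                       sites = M$sites[perm_site, ]),
                  class = "biallelic_matrix")
  expect_equal(haplotype_diversity(M2, sample(grpA), w)$hd, base_hd)
  expect_equal(pairwise_fst(M2, sample(grpA), sample(grpB), w)$windows$fst,
               base_fst)
})

test_that("an admixed blend is more diverse and less differentiated than its sources", {
  tr <- simulate_populations(demo_three_group_model(seed = 61))
  M <- truth_matrix(tr)
  w <- make_windows(setNames(tr$model$chromosome_lengths,
                             sprintf("chr%dH", 1:7)), w = 5e6)
  grps <- panel_groups(tr)
  ds <- diversity_summary(M, grps, w)
  expect_gt(ds$hd_mean["admixed"],
            max(ds$hd_mean[c("oriental", "occidental")]))
  fst <- setNames(ds$fst$fst, paste(ds$fst$group1, ds$fst$group2))
  pp <- fst[["occidental oriental"]]
  expect_gt(pp, fst[["admixed occidental"]])
  expect_gt(pp, fst[["admixed oriental"]])
})
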