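test_that("F = 0 collapses every group frequency onto the ancestral frequency", {
  m <- two_group_model(n_per_group = 3, F = 0, n_sites = 100, seed = 3)
  tr <- simulate_populations(m)
  expect_equal(tr$freq["A", ], tr$freq["B", ])
})

test_that("degenerate models are rejected", {
  expect_error(population_model(groups = data.frame(
    name = "A", n = 2L, F = 1)), "\\[0, 1\\)")
  expect_error(population_model(n_sites = 2000L, chromosome_lengths = 1000),
               "distinct")
  expect_error(population_model(
    groups = data.frame(name = c("A", "B"), n = c(2L, 2L), F = c(0, 0)),
    admixed = data.frame(name = "x", A = 0.6, B = 0.6)), "sum to 1")
})

test_that("the generator is deterministic given its seed", {
  m <- two_group_model(n_per_group = 4, n_sites = 80, seed = 99)
  tr1 <- simulate_populations(m)
  tr2 <- simulate_populations(m)
  expect_identical(tr1, tr2)
  o1 <- simulate_caller_outputs(tr1, default_caller_profiles(30), seed = 5)
  o2 <- simulate_caller_outputs(tr2, default_caller_profiles(30), seed = 5)
  expect_identical(o1, o2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_panel(tr1, o1, d1)
  write_simulated_panel(tr2, o2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("per-group empirical allele frequencies track the drawn frequencies", {
  m <- two_group_model(n_per_group = 120, F = 0.2, n_sites = 800, seed = 7)
  tr <- simulate_populations(m)
  for (g in c("A", "B")) {
    emp <- colMeans(tr$G[pure_names(g, 120), ])
    p <- tr$freq[g, ]
    z_ok <- abs(emp - p) < 3 * sqrt(pmax(p * (1 - p), 1e-12) / 120) + 1e-9
    expect_gte(mean(z_ok), 0.99)  # ~3-sigma band
  }
})

test_that("Hudson F_ST on emitted genotypes recovers the Balding-Nichols F", {
  m <- population_model(2, 10e6, 1000,
                        data.frame(name = c("A", "B"), n = c(50, 50),
                                   F = c(0.2, 0.2)), seed = 21)
  tr <- simulate_populations(m)
  M <- truth_matrix(tr)
  w <- make_windows(c(chr1H = 10e6, chr2H = 10e6), w = 5e6)
  est <- pairwise_fst(M, pure_names("A", 50), pure_names("B", 50), w)$genome_wide
  expect_lt(abs(est - 0.2), 0.05)
  # independent oracle from the drawn frequencies themselves
  pa <- tr$freq["A", ]; pb <- tr$freq["B", ]
  hb <- pa * (1 - pb) + pb * (1 - pa)
  hw <- pa * (1 - pa) + pb * (1 - pb)
  oracle <- 1 - sum(hw) / sum(hb)
  expect_lt(abs(est - oracle), 0.03)
})

test_that("instant donor resetting leaves no linkage above the permutation baseline", {
  adm <- data.frame(name = sprintf("x%03d", 1:200), A = 0.5, B = 0.5)
  m <- population_model(1, 5e5, 400,
                        data.frame(name = c("A", "B"), n = c(0, 0),
                                   F = c(0.5, 0.5)),
                        admixed = adm, recomb_rate = 1e3, seed = 13)
  tr <- simulate_populations(m)
  poly <- apply(tr$G, 2, var) > 0
  r2 <- cor(tr$G[, poly])^2
  obs <- mean(r2[upper.tri(r2)])
  set.seed(31)
  perm <- tr$G[, sample(which(poly))]
  r2p <- cor(perm)^2
  expect_lt(abs(obs - mean(r2p[upper.tri(r2p)])), 0.02)
})

test_that("linked mosaics show distance-decaying r-squared", {
  adm <- data.frame(name = sprintf("x%03d", 1:200), A = 0.5, B = 0.5)
  m <- population_model(1, 1e6, 2000,
                        data.frame(name = c("A", "B"), n = c(0, 0),
                                   F = c(0.5, 0.5)),
                        admixed = adm, recomb_rate = 1 / 5000, seed = 17)
  tr <- simulate_populations(m)
  pr <- pairwise_ld(truth_matrix(tr), max_dist = 2e4)
  dec <- ld_decay(pr, bin_width = 2000)
  ct <- suppressWarnings(
    cor.test(dec$bins$bin_mid, dec$bins$mean_r2, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("caller outputs follow the planted truth and the stated error models", {
  m <- two_group_model(n_per_group = 2, n_sites = 400, chrom_len = 4e5,
                       seed = 11)
  tr <- simulate_populations(m)
  # no-noise case: consensus equals the planted set per accession
  prof <- lapply(c("fb", "glf", "st"), caller_profile,
                 fn_rate = 0, fp_rate = 0, depth_lambda = 50)
  out <- simulate_caller_outputs(tr, prof, seed = 2, error_rate = 0)
  for (a in rownames(tr$G)[1:2]) {
    cons <- consensus_calls(out[[a]]$calls, depth = out[[a]]$depth)$consensus
    planted <- which(tr$G[a, ] == 1L)
    expect_identical(paste(cons$chrom, cons$pos, cons$alt),
                     paste(tr$sites$chrom[planted], tr$sites$pos[planted],
                           tr$sites$alt[planted]))
  }
  # shallow depth: Poisson tail P(depth < 5 | lambda = 3) kills most sites
  prof3 <- lapply(c("fb", "glf", "st"), caller_profile,
                  fn_rate = 0, fp_rate = 0, depth_lambda = 3)
  out3 <- simulate_caller_outputs(tr, prof3, seed = 3, error_rate = 0)
  a <- rownames(tr$G)[1]
  filt <- filter_homozygous(out3[[a]]$calls[[1]], min_depth = 5)
  frac_failed <- 1 - nrow(filt) / sum(tr$G[a, ])
  expect_gt(frac_failed, 0.5)
  expect_lt(abs(frac_failed - ppois(4, 3)), 0.10)
})

test_that("independent per-caller false negatives thin the intersection geometrically", {
  m <- population_model(1, 2e6, 5000,
                        data.frame(name = "A", n = 4L, F = 0.3), seed = 23)
  tr <- simulate_populations(m)
  prof <- lapply(c("fb", "glf", "st"), caller_profile,
                 fn_rate = 0.1, fp_rate = 0, depth_lambda = 50)
  out <- simulate_caller_outputs(tr, prof, seed = 4, error_rate = 0)
  surv <- vapply(rownames(tr$G), function(a) {
    cons <- consensus_calls(out[[a]]$calls, depth = out[[a]]$depth)$consensus
    nrow(cons) / sum(tr$G[a, ])
  }, 0)
  expect_lt(max(abs(surv - 0.9^3)), 0.03)
})

test_that("absurd false-positive rates are refused", {
  m <- two_group_model(n_per_group = 2, n_sites = 50, seed = 1)
  tr <- simulate_populations(m)
  bad <- list(caller_profile("a", 0, 1e4, 30), caller_profile("b", 0, 0, 30),
              caller_profile("c", 0, 0, 30))
  expect_error(simulate_caller_outputs(tr, bad, seed = 1), "false")
})
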