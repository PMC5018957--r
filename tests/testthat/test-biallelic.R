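# panel fixture: n accessions with explicit per-accession calls and flat
# depth tracks
panel <- function(call_pos, call_alt, n_acc, depth = 10L, len = 1e4) {
  acc <- sprintf("a%02d", seq_len(n_acc))
  cons <- lapply(seq_len(n_acc), function(i) {
    k <- which(vapply(call_pos, function(p) i %in% p$acc, NA))
    mk_calls(pos = vapply(call_pos[k], `[[`, 0L, "pos"),
             alt = call_alt[k], alt_reads = 9L, depth = 10L,
             accession = acc[i], caller = "consensus")
  })
  names(cons) <- acc
  deps <- lapply(acc, function(a) flat_track(depth, len = len, accession = a))
  names(deps) <- acc
  list(cons = cons, deps = deps)
}

test_that("site retention follows the three matrix criteria", {
  # 21 accessions; site 100 called G in 20; site 200 called in none of the
  # tracked accessions is impossible by construction (union of calls)
  p <- panel(call_pos = list(list(pos = 100L, acc = 1:20)),
             call_alt = "G", n_acc = 21)
  M <- build_biallelic_matrix(p$cons, p$deps, reference_name = "Morex")
  expect_equal(ncol(M$G), 1L)
  expect_equal(sum(M$G[, 1]), 20L)
  expect_equal(rownames(M$G)[22], "Morex")
  expect_equal(unname(M$G["Morex", 1]), 0L)
})

test_that("a minority third allele is tolerated and recoded to reference", {
  # 10 accessions call G, 1 calls T: 1/21 = 4.8% < 10%
  p <- panel(call_pos = list(list(pos = 100L, acc = 1:10),
                             list(pos = 100L, acc = 11L)),
             call_alt = c("G", "T"), n_acc = 21)
  M <- build_biallelic_matrix(p$cons, p$deps)
  expect_equal(ncol(M$G), 1L)
  expect_equal(M$sites$alt, "G")
  expect_equal(unname(M$G["a11", 1]), 0L)     # T carrier recoded
  expect_equal(sum(M$G[, 1]), 10L)
  # with drop_site policy the site disappears instead (empty-matrix warning)
  expect_warning(
    M2 <- build_biallelic_matrix(p$cons, p$deps, third_allele = "drop_site"),
    "no site passed")
  expect_equal(ncol(M2$G), 0L)
})

test_that("a single under-covered accession removes the site", {
  p <- panel(call_pos = list(list(pos = 100L, acc = 1:3)),
             call_alt = "G", n_acc = 4)
  p$deps[["a04"]] <- depth_track(
    data.frame(chrom = "chr1H", start = 0L, end = 10000L, depth = 4L),
    accession = "a04")
  M <- suppressWarnings(build_biallelic_matrix(p$cons, p$deps))
  expect_equal(ncol(M$G), 0L)
  expect_error(build_biallelic_matrix(p$cons, p$deps[1:3]), "depth track")
})

test_that("noise-free full-coverage data reproduce the planted genotypes exactly", {
  m <- two_group_model(n_per_group = 5, n_sites = 250, chrom_len = 3e5,
                       seed = 19)
  tr <- simulate_populations(m)
  prof <- lapply(c("fb", "glf", "st"), caller_profile,
                 fn_rate = 0, fp_rate = 0, depth_lambda = 50)
  out <- simulate_caller_outputs(tr, prof, seed = 6, error_rate = 0)
  cons <- lapply(out, function(o)
    consensus_calls(o$calls, depth = o$depth)$consensus)
  deps <- lapply(out, `[[`, "depth")
  M <- build_biallelic_matrix(cons, deps, reference_name = NULL)
  seg <- colSums(tr$G) >= 1L
  expect_identical(unname(M$G), unname(tr$G[, seg]))
  expect_equal(M$sites$pos, tr$sites$pos[seg])
  expect_equal(M$sites$alt, tr$sites$alt[seg])
})

test_that("pairwise identity is the exact match fraction and complements p-distance", {
  G <- rbind(a = c(rep(1L, 75), rep(0L, 25)),
             b = c(rep(1L, 75), rep(0L, 25)),
             c = c(rep(0L, 75), rep(1L, 25)),
             d = c(rep(1L, 50), rep(0L, 50)))
  sites <- data.frame(chrom = "chr1H", pos = seq_len(100L) * 10L,
                      ref = "A", alt = "G")
  M <- structure(list(G = G, sites = sites), class = "biallelic_matrix")
  idm <- pairwise_identity(M)
  expect_equal(unname(diag(idm)), rep(1, 4))
  expect_equal(idm["a", "b"], 1)
  expect_equal(idm["a", "c"], 0)      # complementary rows
  expect_equal(idm["a", "d"], 0.75)   # differ at 25 of 100 sites
  expect_equal(idm, 1 - p_distance(M), tolerance = 1e-12)
})

test_that("matrix VCF and TSV round-trip", {
  m <- two_group_model(n_per_group = 3, n_sites = 40, chrom_len = 5e4,
                       n_chrom = 2, seed = 29)
  tr <- simulate_populations(m)
  M <- truth_matrix(tr)
  rownames(M$G) <- rownames(tr$G)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_vcf(M, f1)
  write_matrix_tsv(M, f2)
  b1 <- read_matrix_vcf(f1)
  b2 <- read_matrix_tsv(f2)
  for (b in list(b1, b2)) {
    expect_equal(unname(b$G), unname(M$G))
    expect_equal(rownames(b$G), rownames(M$G))
    expect_equal(b$sites$pos, M$sites$pos)
    expect_equal(b$sites$alt, M$sites$alt)
  }
})

test_that("tightening thresholds never increases the site count", {
  m <- two_group_model(n_per_group = 6, n_sites = 150, chrom_len = 2e5,
                       seed = 31)
  tr <- simulate_populations(m)
  out <- simulate_caller_outputs(tr, default_caller_profiles(12), seed = 8)
  cons <- lapply(out, function(o)
    consensus_calls(o$calls, depth = o$depth)$consensus)
  deps <- lapply(out, `[[`, "depth")
  n_sites <- vapply(c(2L, 5L, 8L, 12L), function(md)
    ncol(suppressWarnings(
      build_biallelic_matrix(cons, deps, min_depth = md))$G), 0L)
  expect_true(all(diff(n_sites) <= 0))
  n_sites3 <- vapply(c(0.3, 0.1, 0.05), function(tf)
    ncol(suppressWarnings(build_biallelic_matrix(
      cons, deps, max_third_allele_frac = tf))$G), 0L)
  expect_true(all(diff(n_sites3) <= 0))
})
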