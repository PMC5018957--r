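#' Pairwise linkage disequilibrium (r² and D′) within a group
#'
#' For haploid pairs of sites on the same chromosome within `max_dist` bp:
#' with alt-allele frequencies p_A, p_B and alt-alt haplotype frequency
#' p_AB, D = p_AB - p_A p_B, r² = D² / (p_A(1-p_A) p_B(1-p_B)), and
#' D′ = |D| / D_max with D_max = min(p_A(1-p_B), (1-p_A)p_B) for D > 0
#' and min(p_A p_B, (1-p_A)(1-p_B)) for D < 0. Sites with minor-allele
#' frequency below `maf_min` in the group are excluded; both measures are
#' invariant to allele relabelling.
#'
#' @param M a `biallelic_matrix`.
#' @param group accession names (>= 4); default all accessions.
#' @param max_dist maximum pair distance in bp (default 500 kb).
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @return `data.frame(chrom, i, j, pos_i, pos_j, dist, r2, dprime)` where
#'   `i < j` index the (MAF-filtered) site list; attribute `sites` holds
#'   that list with its genotype submatrix columns.
#' @export
pairwise_ld <- function(M, group = rownames(M$G), max_dist = 5e5,
                        maf_min = 0.05) {
  stopifnot(inherits(M, "biallelic_matrix"))
  if (length(group) < 4L) stop("LD estimation needs >= 4 accessions")
  G <- M$G[group, , drop = FALSE]
  n <- nrow(G)
  p <- colMeans(G)
  keep <- pmin(p, 1 - p) >= maf_min
  G <- G[, keep, drop = FALSE]
  sites <- M$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  out <- list()
  for (ch in unique(sites$chrom)) {
    ci <- which(sites$chrom == ch)
    if (length(ci) < 2L) next
    Gc <- G[, ci, drop = FALSE]
    pos <- sites$pos[ci]
    pA <- colMeans(Gc)
    pAB <- crossprod(Gc) / n
    Dm <- pAB - outer(pA, pA)
    denom <- outer(pA * (1 - pA), pA * (1 - pA))
    r2 <- Dm^2 / denom
    dmax_pos <- outer(pA, 1 - pA, function(a, qb) a * qb)
    dmax_pos <- pmin(dmax_pos, t(dmax_pos))
    dmax_neg <- pmin(outer(pA, pA), outer(1 - pA, 1 - pA))
    dprime <- abs(Dm) / ifelse(Dm >= 0, dmax_pos, dmax_neg)
    dprime[Dm == 0] <- 0
    ut <- which(upper.tri(Dm), arr.ind = TRUE)
    dist <- pos[ut[, 2]] - pos[ut[, 1]]
    sel <- dist > 0 & dist <= max_dist
    ut <- ut[sel, , drop = FALSE]; dist <- dist[sel]
    out[[ch]] <- data.frame(
      chrom = rep(ch, nrow(ut)), i = ci[ut[, 1]], j = ci[ut[, 2]],
      pos_i = pos[ut[, 1]], pos_j = pos[ut[, 2]], dist = dist,
      r2 = r2[ut], dprime = pmin(dprime[ut], 1),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), i = integer(), j = integer(),
               pos_i = integer(), pos_j = integer(), dist = integer(),
               r2 = numeric(), dprime = numeric())
  rownames(res) <- NULL
  attr(res, "sites") <- sites
  attr(res, "G") <- G
  attr(res, "n") <- n
  res
}

#' Distance-binned LD decay
#'
#' Pairs are binned by physical distance (`floor(dist / bin_width)`); the
#' half-decay distance is the midpoint of the first bin whose mean r² has
#' fallen to half of the first occupied bin's mean (NA when never reached
#' within the pair list's distance range).
#'
#' @param pairs a [pairwise_ld()] result.
#' @param bin_width bin width in bp (default 1000).
#' @return List with `bins` (`data.frame(bin_mid, mean_r2, n_pairs)`) and
#'   `half_decay_distance` (bp or `NA`).
#' @export
ld_decay <- function(pairs, bin_width = 1000) {
  if (!nrow(pairs)) stop("empty LD pair list")
  b <- floor(pairs$dist / bin_width)
  agg <- aggregate(pairs$r2, by = list(bin = b), FUN = mean)
  cnt <- as.data.frame(table(bin = b), stringsAsFactors = FALSE)
  bins <- data.frame(bin_mid = (as.integer(agg$bin) + 0.5) * bin_width,
                     mean_r2 = agg$x,
                     n_pairs = as.integer(cnt$Freq))
  bins <- bins[order(bins$bin_mid), , drop = FALSE]
  rownames(bins) <- NULL
  thr <- bins$mean_r2[1] / 2
  hit <- which(bins$mean_r2 <= thr)
  half <- if (length(hit)) bins$bin_mid[hit[1]] else NA_real_
  list(bins = bins, half_decay_distance = half)
}

# two-sided CI on |D'| by normalising the multinomial likelihood of the
# observed two-locus haplotype counts over a |D'| grid (Wall & Pritchard
# style, as in Haploview's Gabriel block routine)
dprime_ci <- function(gi, gj, grid_step = 0.001, conf = 0.90) {
  n <- length(gi)
  pA <- mean(gi); pB <- mean(gj)
  pAB <- mean(gi * gj)
  D <- pAB - pA * pB
  s <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(c(NA_real_, NA_real_))
  counts <- c(n11 = sum(gi == 1 & gj == 1), n10 = sum(gi == 1 & gj == 0),
              n01 = sum(gi == 0 & gj == 1), n00 = sum(gi == 0 & gj == 0))
  dgrid <- seq(0, 1, by = grid_step)
  Dg <- s * dgrid * dmax
  f11 <- pmax(pA * pB + Dg, 1e-12)
  f10 <- pmax(pA * (1 - pB) - Dg, 1e-12)
  f01 <- pmax((1 - pA) * pB - Dg, 1e-12)
  f00 <- pmax((1 - pA) * (1 - pB) + Dg, 1e-12)
  ll <- counts[1] * log(f11) + counts[2] * log(f10) +
    counts[3] * log(f01) + counts[4] * log(f00)
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  a <- (1 - conf) / 2
  lo <- dgrid[which(cum >= a)[1]]
  hi <- dgrid[which(cum >= 1 - a)[1]]
  c(lo, hi)
}

#' Gabriel-style LD block detection
#'
#' Per informative site pair a 90% confidence interval on |D′| is computed
#' by likelihood-grid normalisation; a pair is in "strong LD" when the CI
#' lower bound is at least `ci_strong[1]` and the upper bound at least
#' `ci_strong[2]`, and shows "strong recombination" when the upper bound
#' is below `ci_recomb_high`. A run of consecutive sites is a candidate
#' block when at least `min_strong_frac` of its informative pairs are in
#' strong LD; maximal non-overlapping
#' blocks are chosen greedily by bp span, longest first.
#'
#' @param M a `biallelic_matrix`.
#' @param group accession names (>= 4); default all.
#' @param ci_strong lower/upper CI thresholds for strong LD
#'   (default `c(0.70, 0.98)`).
#' @param ci_recomb_high CI-upper threshold for strong recombination
#'   (default 0.90).
#' @param min_strong_frac required strong-LD fraction among informative
#'   pairs (default 0.95).
#' @param maf_min,max_dist passed to [pairwise_ld()].
#' @param min_span_bp optional output filter: drop blocks spanning fewer bp.
#' @return `data.frame(chrom, start_pos, end_pos, span_bp, n_sites)`,
#'   non-overlapping and sorted within chromosomes.
#' @export
ld_blocks <- function(M, group = rownames(M$G), ci_strong = c(0.70, 0.98),
                      ci_recomb_high = 0.90, min_strong_frac = 0.95,
                      maf_min = 0.05, max_dist = 5e5, min_span_bp = 0) {
  pr <- pairwise_ld(M, group, max_dist = max_dist, maf_min = maf_min)
  sites <- attr(pr, "sites")
  G <- attr(pr, "G")
  blocks <- list()
  for (ch in unique(sites$chrom)) {
    ci <- which(sites$chrom == ch)
    S <- length(ci)
    if (S < 2L) next
    pos <- sites$pos[ci]
    # classify pairs: 1 strong LD, -1 strong recombination, 0 uninformative
    cls <- matrix(0L, S, S)
    prc <- pr[pr$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(prc))) {
      a <- match(prc$i[r], ci); b <- match(prc$j[r], ci)
      bounds <- dprime_ci(G[, ci[a]], G[, ci[b]])
      if (anyNA(bounds)) next
      if (bounds[1] >= ci_strong[1] && bounds[2] >= ci_strong[2])
        cls[a, b] <- 1L
      else if (bounds[2] < ci_recomb_high)
        cls[a, b] <- -1L
    }
    cand <- list()
    for (a in seq_len(S - 1L)) {
      n_strong <- 0L; n_inf <- 0L
      for (b in (a + 1L):S) {
        new_pairs <- cls[a:(b - 1L), b]
        n_strong <- n_strong + sum(new_pairs == 1L)
        n_inf <- n_inf + sum(new_pairs != 0L)
        if (pos[b] - pos[a] > max_dist) break
        if (n_inf > 0L && n_strong / n_inf >= min_strong_frac)
          cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    span <- pos[cm[, 2]] - pos[cm[, 1]]
    ord <- order(-span, cm[, 1])
    taken <- rep(FALSE, S)
    for (k in ord) {
      rng <- cm[k, 1]:cm[k, 2]
      if (any(taken[rng])) next
      taken[rng] <- TRUE
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = ch, start_pos = pos[cm[k, 1]], end_pos = pos[cm[k, 2]],
        span_bp = span[k], n_sites = length(rng),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(), start_pos = integer(),
               end_pos = integer(), span_bp = integer(),
               n_sites = integer(), stringsAsFactors = FALSE)
  res <- res[res$span_bp >= min_span_bp, , drop = FALSE]
  res <- res[order(res$chrom, res$start_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}
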