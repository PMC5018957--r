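#' Tile chromosomes into genome windows
#'
#' Non-overlapping half-open tiles `[start, end)` of width `w` bp (0-based;
#' the last tile of a chromosome may be shorter). A step equal to the
#' window width is the package's reading of "sliding windows" for
#' genome-track summaries; `step` can be lowered for overlapping windows.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param w window width in bp (default 5e6).
#' @param step step between window starts (default `w`, i.e. tiling).
#' @return `data.frame(chrom, start, end)` of class `genome_windows`.
#' @export
make_windows <- function(chrom_lengths, w = 5e6, step = w) {
  if (w <= 0) stop("window width must be positive")
  if (step <= 0) stop("window step must be positive")
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(L - 1, 0), by = step)
    data.frame(chrom = ch, start = starts, end = pmin(starts + w, L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("genome_windows", "data.frame")
  out
}

# window index for 1-based positions; NA when outside every window
window_index <- function(windows, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    wi <- which(windows$chrom == ch)
    if (!length(wi)) next
    sel <- which(chrom == ch)
    p0 <- pos[sel] - 1  # 1-based position occupies [pos-1, pos)
    j <- findInterval(p0, windows$start[wi])
    ok <- j >= 1L
    ok[ok] <- p0[ok] < windows$end[wi][j[ok]]
    idx[sel[ok]] <- wi[j[ok]]
  }
  idx
}

#' Windowed SNP counts
#'
#' @param calls a [callset()] (or any data.frame with `chrom`, `pos`).
#' @param windows a [make_windows()] result.
#' @param chrom_lengths optional named lengths; positions beyond a
#'   chromosome's length raise an error naming the record.
#' @return `windows` with an added `snp_count` column.
#' @export
snp_density <- function(calls, windows, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    bad <- which(calls$pos > chrom_lengths[calls$chrom])
    if (length(bad))
      stop("SNP at ", calls$chrom[bad[1]], ":", calls$pos[bad[1]],
           " lies beyond the chromosome end")
  }
  idx <- window_index(windows, calls$chrom, calls$pos)
  if (anyNA(idx))
    stop("SNP position outside every window (is chrom_lengths consistent?)")
  windows$snp_count <- tabulate(idx, nbins = nrow(windows))
  windows
}

#' Windowed haplotype diversity
#'
#' Within each window the accessions' window-restricted genotype strings
#' are the haplotypes; with k distinct haplotypes at sample frequencies
#' p_i among n accessions, Nei's haplotype diversity is
#' Hd = n/(n-1) (1 - sum p_i^2). Windows containing no matrix site get
#' `NA` (undefined), windows whose sites are all monomorphic in the group
#' get 0.
#'
#' @param M a `biallelic_matrix`.
#' @param group character vector of accession names (>= 2).
#' @param windows a [make_windows()] result.
#' @return `windows` with added columns `n_sites` and `hd`.
#' @export
haplotype_diversity <- function(M, group, windows) {
  stopifnot(inherits(M, "biallelic_matrix"))
  if (length(group) < 2L) stop("haplotype diversity needs >= 2 accessions")
  if (!all(group %in% rownames(M$G)))
    stop("unknown accession(s): ",
         paste(setdiff(group, rownames(M$G)), collapse = ", "))
  G <- M$G[group, , drop = FALSE]
  n <- length(group)
  idx <- window_index(windows, M$sites$chrom, M$sites$pos)
  hd <- rep(NA_real_, nrow(windows))
  ns <- integer(nrow(windows))
  for (wi in unique(idx[!is.na(idx)])) {
    cols <- which(idx == wi)
    ns[wi] <- length(cols)
    hap <- apply(G[, cols, drop = FALSE], 1, paste, collapse = "")
    p <- table(hap) / n
    hd[wi] <- n / (n - 1) * (1 - sum(p^2))
  }
  windows$n_sites <- ns
  windows$hd <- hd
  windows
}

#' Windowed and genome-wide Hudson F_ST between two groups
#'
#' Per window, over the window's sites: Hw is the mean pairwise difference
#' count within groups (average of the two groups), Hb the mean pairwise
#' difference count between groups, each summed over sites;
#' F_ST = 1 - Hw/Hb, clamped to `[0, 1]`; windows with Hb = 0 (or no
#' sites) are undefined (`NA`). The genome-wide value is the mean over
#' defined windows.
#'
#' @param M a `biallelic_matrix`.
#' @param groupA,groupB disjoint accession-name vectors, each >= 2.
#' @param windows a [make_windows()] result.
#' @return List with `windows` (input plus `fst` column) and `genome_wide`.
#' @export
pairwise_fst <- function(M, groupA, groupB, windows) {
  stopifnot(inherits(M, "biallelic_matrix"))
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need >= 2 accessions")
  GA <- M$G[groupA, , drop = FALSE]
  GB <- M$G[groupB, , drop = FALSE]
  nA <- nrow(GA); nB <- nrow(GB)
  cA <- colSums(GA); cB <- colSums(GB)
  hwA <- cA * (nA - cA) / choose(nA, 2)   # per-site mean pairwise diff in A
  hwB <- cB * (nB - cB) / choose(nB, 2)
  hb <- (cA * (nB - cB) + cB * (nA - cA)) / (nA * nB)
  idx <- window_index(windows, M$sites$chrom, M$sites$pos)
  fst <- rep(NA_real_, nrow(windows))
  for (wi in unique(idx[!is.na(idx)])) {
    cols <- which(idx == wi)
    Hw <- (sum(hwA[cols]) + sum(hwB[cols])) / 2
    Hb <- sum(hb[cols])
    if (Hb > 0) fst[wi] <- min(max(1 - Hw / Hb, 0), 1)
  }
  windows$fst <- fst
  list(windows = windows,
       genome_wide = if (all(is.na(fst))) NA_real_ else
         mean(fst, na.rm = TRUE))
}

#' Three-group windowed diversity summary
#'
#' Convenience wrapper producing, for a named list of groups, per-group
#' windowed and average haplotype diversity and all pairwise genome-wide
#' F_ST values — the layout of a sub-population diversity table.
#'
#' @param M a `biallelic_matrix`.
#' @param groups named list of accession-name vectors.
#' @param windows a [make_windows()] result.
#' @return List with `hd` (windows with one hd column per group),
#'   `hd_mean` (named vector), `fst` (`data.frame(group1, group2, fst)`).
#' @export
diversity_summary <- function(M, groups, windows) {
  hd_tab <- windows
  hd_mean <- setNames(numeric(length(groups)), names(groups))
  for (g in names(groups)) {
    wg <- haplotype_diversity(M, groups[[g]], windows)
    hd_tab[[paste0("hd_", g)]] <- wg$hd
    hd_mean[g] <- mean(wg$hd, na.rm = TRUE)
  }
  prs <- utils::combn(names(groups), 2)
  fst <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    fst = apply(prs, 2, function(p)
                      pairwise_fst(M, groups[[p[1]]], groups[[p[2]]],
                                   windows)$genome_wide),
                    stringsAsFactors = FALSE)
  list(hd = hd_tab, hd_mean = hd_mean, fst = fst)
}
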