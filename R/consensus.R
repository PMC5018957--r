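#' Filter a call set to putative homozygous SNPs
#'
#' Keeps records with read depth at least `min_depth` and alternative
#' allele fraction strictly above `min_alt_frac` (the "above 90%" rule is
#' read as a strict inequality; a 9/10 call at the 0.90 boundary is
#' dropped). Records with depth 0 are dropped and counted separately.
#' When a [depth_track()] is supplied its depth at each position replaces
#' the caller-reported `depth` for the depth threshold (disagreements are
#' reported via a message), matching a genome-coverage-derived depth.
#'
#' @param calls a [callset()].
#' @param min_depth minimum read depth (default 5).
#' @param min_alt_frac alt-fraction threshold, strict (default 0.90).
#' @param depth optional [depth_track()] for the same accession.
#' @return The filtered [callset()]; attributes `n_input`, `n_dropped_depth0`
#'   record bookkeeping.
#' @export
filter_homozygous <- function(calls, min_depth = 5L, min_alt_frac = 0.90,
                              depth = NULL) {
  stopifnot(inherits(calls, "callset"))
  d <- calls$depth
  if (!is.null(depth)) {
    if (nzchar(depth$accession) && nzchar(attr(calls, "accession")) &&
        depth$accession != attr(calls, "accession"))
      stop("depth track accession (", depth$accession,
           ") does not match call set (", attr(calls, "accession"), ")")
    d_track <- depth_at(depth, calls$chrom, calls$pos)
    n_dis <- sum(d_track != d)
    if (n_dis > 0)
      message("filter_homozygous: caller DP and depth track disagree at ",
              n_dis, " position(s); using the depth track")
    d <- d_track
  }
  zero <- d == 0L
  frac <- ifelse(calls$depth > 0L, calls$alt_reads / calls$depth, 0)
  keep <- !zero & d >= min_depth & frac > min_alt_frac
  out <- calls[keep, , drop = FALSE]
  out <- callset(out$chrom, out$pos, out$ref, out$alt, out$alt_reads,
                 out$depth, accession = attr(calls, "accession"),
                 caller = attr(calls, "caller"))
  attr(out, "n_input") <- nrow(calls)
  attr(out, "n_dropped_depth0") <- sum(zero)
  out
}

#' Intersect three callers' filtered call sets
#'
#' Returns the records whose (chromosome, position, ref, alt) occur in all
#' three inputs — the "reliable SNP" set. Allele identity is required: the
#' same position with different alternative alleles across callers does not
#' count. Read counts are taken from the first input.
#'
#' @param a,b,c filtered [callset()]s for the same accession.
#' @return A [callset()] with `caller = "consensus"`.
#' @export
intersect_callers <- function(a, b, c) {
  accs <- c(attr(a, "accession"), attr(b, "accession"), attr(c, "accession"))
  if (length(unique(accs)) != 1L)
    stop("call sets come from different accessions: ",
         paste(unique(accs), collapse = ", "))
  full_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  keep <- full_key(a) %in% full_key(b) & full_key(a) %in% full_key(c)
  out <- a[keep, , drop = FALSE]
  callset(out$chrom, out$pos, out$ref, out$alt, out$alt_reads, out$depth,
          accession = accs[1], caller = "consensus")
}

#' Per-accession consensus calling
#'
#' Applies [filter_homozygous()] to each caller's call set and intersects
#' the three filtered sets with [intersect_callers()].
#'
#' @param calls named list of three [callset()]s (one per caller).
#' @param depth optional shared [depth_track()].
#' @inheritParams filter_homozygous
#' @return List with elements `consensus` (a [callset()]), `filtered`
#'   (list of the three filtered sets) and `summary` (a one-row
#'   `data.frame`: accession, per-caller raw and filtered counts, and the
#'   consensus count).
#' @export
consensus_calls <- function(calls, depth = NULL, min_depth = 5L,
                            min_alt_frac = 0.90) {
  stopifnot(length(calls) == 3L)
  filtered <- lapply(calls, filter_homozygous, min_depth = min_depth,
                     min_alt_frac = min_alt_frac, depth = depth)
  cons <- intersect_callers(filtered[[1]], filtered[[2]], filtered[[3]])
  callers <- vapply(calls, attr, "", "caller")
  summary <- data.frame(
    accession = attr(cons, "accession"),
    t(setNames(vapply(calls, nrow, 0L), paste0("raw_", callers))),
    t(setNames(vapply(filtered, nrow, 0L), paste0("filtered_", callers))),
    consensus = nrow(cons), stringsAsFactors = FALSE)
  list(consensus = cons, filtered = filtered, summary = summary)
}
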