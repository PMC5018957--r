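#' Construct a call set
#'
#' A call set holds the SNPs one variant caller (or a consensus of callers)
#' reports for one accession: chromosome, 1-based position, reference and
#' alternative allele (single bases), the number of reads supporting the
#' alternative allele, and the total read depth at the position.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference / alternative alleles.
#' @param alt_reads,depth alternative-allele read counts and total depths.
#' @param accession accession (sample) name.
#' @param caller caller name, e.g. `"freebayes"`; `"consensus"` for merged
#'   sets.
#' @return A `data.frame` of class `callset` with columns
#'   `chrom, pos, ref, alt, alt_reads, depth` and attributes `accession` and
#'   `caller`, sorted by (chrom, pos).
#' @export
callset <- function(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    alt_reads = integer(), depth = integer(),
                    accession = "", caller = "") {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    alt_reads = as.integer(alt_reads), depth = as.integer(depth),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(nchar(df$ref) != 1L) || any(nchar(df$alt) != 1L))
      stop("callset records must have single-base ref and alt alleles")
    if (any(df$ref == df$alt))
      stop("callset records must have ref != alt")
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    if (anyDuplicated(paste(df$chrom, df$pos, df$alt)))
      stop("duplicate (chrom, pos, alt) records in callset")
  }
  attr(df, "accession") <- accession
  attr(df, "caller") <- caller
  class(df) <- c("callset", "data.frame")
  df
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> accession=%s caller=%s: %d SNP record(s)\n",
              attr(x, "accession"), attr(x, "caller"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

callset_key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")

#' Read a VCF file into a call set
#'
#' Reads a VCF (v4.x) and returns the SNP records as a [callset()].
#' Multi-allelic records are decomposed into one record per alternative
#' allele; indels and multi-nucleotide variants are dropped (a message
#' reports how many). Alt-read counts and depths are taken from the INFO
#' fields `AO` (comma-separated per alt allele) and `DP`; when `AO` is
#' absent, per-sample `AD`/`DP` FORMAT fields are used instead.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param accession,caller names stored on the returned call set; default to
#'   values parsed from the file name stem (`<accession>.<caller>.vcf`).
#' @return A [callset()].
#' @export
read_vcf <- function(path, accession = NULL, caller = NULL) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  check_vcf_lines(path)
  stem <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  parts <- strsplit(stem, ".", fixed = TRUE)[[1]]
  if (is.null(accession)) accession <- parts[1]
  if (is.null(caller)) caller <- if (length(parts) > 1) parts[2] else ""
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L)
    return(callset(accession = accession, caller = caller))
  info <- fix[, "INFO"] %||% rep(NA_character_, n)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ao_raw <- vcfR::extract.info(v, "AO")
  chrom <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0); ao <- integer(0); dpv <- integer(0)
  dropped <- 0L
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    aos <- if (!is.null(ao_raw) && !is.na(ao_raw[i]))
      suppressWarnings(as.integer(strsplit(ao_raw[i], ",", fixed = TRUE)[[1]]))
    else rep(NA_integer_, length(alts))
    if (length(aos) < length(alts)) aos <- rep(aos, length.out = length(alts))
    for (j in seq_along(alts)) {
      if (nchar(fix[i, "REF"]) != 1L || nchar(alts[j]) != 1L ||
          alts[j] %in% c(".", "*")) {
        dropped <- dropped + 1L
        next
      }
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, fix[i, "REF"])
      alt <- c(alt, alts[j])
      ao <- c(ao, aos[j])
      dpv <- c(dpv, dp[i])
    }
  }
  if (anyNA(ao) || anyNA(dpv))
    stop("VCF ", path, " lacks AO/DP depth information for some records; ",
         "regenerate with depth fields or supply a companion depth track")
  if (dropped > 0L)
    message("read_vcf: dropped ", dropped, " non-SNP allele(s) from ",
            basename(path))
  callset(chrom, pos, ref, alt, ao, dpv,
          accession = accession, caller = caller)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cheap structural validation so malformed lines are reported by number
check_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("malformed VCF line ", i, " in ", path,
           ": expected >= 8 tab-separated fields")
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed VCF line ", i, " in ", path, ": POS is not an integer")
  }
  invisible(TRUE)
}

#' Write a call set as a minimal single-sample VCF
#'
#' Emits VCF v4.2 with INFO fields `DP` (total depth) and `AO` (alt reads).
#'
#' @param x a [callset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(x, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popsnp",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele read count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(x)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AO=%d",
            x$chrom, x$pos, x$ref, x$alt, x$depth, x$alt_reads)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Construct a depth track
#'
#' Per-accession read depth over the reference, stored as half-open 0-based
#' intervals per chromosome (BedGraph convention). Positions not covered by
#' any interval have depth 0.
#'
#' @param intervals `data.frame` with columns `chrom, start, end, depth`
#'   (`start`/`end` 0-based half-open).
#' @param accession accession name.
#' @return Object of class `depth_track`.
#' @export
depth_track <- function(intervals, accession = "") {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(intervals)))
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, accession = accession),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> accession=%s: %d interval(s) on %d chromosome(s)\n",
              x$accession, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Query read depth at positions
#'
#' @param track a [depth_track()].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @return Integer vector of depths (0 where uncovered).
#' @export
depth_at <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  out <- integer(n)
  for (ch in unique(chrom)) {
    iv <- track$intervals[track$intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!nrow(iv)) next
    p0 <- pos[sel] - 1L  # to 0-based
    idx <- findInterval(p0, iv$start)
    d <- integer(sum(sel))
    hit <- idx >= 1L
    hit[hit] <- p0[hit] < iv$end[idx[hit]]
    d[hit] <- iv$depth[idx[hit]]
    out[sel] <- d
  }
  out
}

#' Read a BedGraph depth file into a depth track
#'
#' @param path BedGraph path (columns chrom, start, end, depth; 0-based
#'   half-open).
#' @param accession accession name; defaults to the file name stem.
#' @return A [depth_track()].
#' @export
read_bedgraph <- function(path, accession = NULL) {
  if (is.null(accession))
    accession <- sub("\\.(bedgraph|bdg|bed)$", "", basename(path))
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "depth"),
                   colClasses = c("character", "integer", "integer",
                                  "integer"))
  depth_track(df, accession = accession)
}

#' Write a depth track as BedGraph
#'
#' @param track a [depth_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
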