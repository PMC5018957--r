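#' Build the missing-data-free bi-allelic genotype matrix
#'
#' Candidate sites are the union of the per-accession consensus SNP
#' positions. A site is kept iff
#' 1. at least one accession carries a consensus call there;
#' 2. read depth is at least `min_depth` at the position in *every*
#'    accession (so an uncalled accession is confidently reference);
#' 3. the fraction of accessions whose call carries an allele other than
#'    the site's majority alternative allele is below
#'    `max_third_allele_frac`.
#'
#' The site's alternative allele is the plurality alt among calling
#' accessions (ties broken alphabetically). Genotypes are haploid-coded:
#' 1 when the accession's consensus call matches the site alt, otherwise 0
#' (covered-but-uncalled accessions are reference; minority third-allele
#' carriers are recoded to 0 by default, or the site is dropped when
#' `third_allele = "drop_site"`). A reference accession row of all 0 is
#' appended.
#'
#' @param consensus named list of per-accession consensus [callset()]s.
#' @param depths named list of per-accession [depth_track()]s (every
#'   accession in `consensus` must be present).
#' @param min_depth per-accession depth required at a site (default 5).
#' @param max_third_allele_frac tolerated fraction of accessions carrying a
#'   third allele, strict upper bound (default 0.10).
#' @param reference_name name of the appended all-reference accession row
#'   (`NULL` to omit).
#' @param third_allele `"recode"` (default) or `"drop_site"`.
#' @return Object of class `biallelic_matrix`: list with `G` (accessions x
#'   sites binary matrix, accession row names) and `sites`
#'   (`data.frame(chrom, pos, ref, alt)`, (chrom, pos)-sorted).
#' @export
build_biallelic_matrix <- function(consensus, depths, min_depth = 5L,
                                   max_third_allele_frac = 0.10,
                                   reference_name = "reference",
                                   third_allele = c("recode", "drop_site")) {
  third_allele <- match.arg(third_allele)
  acc <- names(consensus)
  missing_depth <- setdiff(acc, names(depths))
  if (length(missing_depth))
    stop("no depth track for accession(s): ",
         paste(missing_depth, collapse = ", "))

  all_calls <- do.call(rbind, lapply(acc, function(a) {
    cs <- consensus[[a]]
    if (!nrow(cs)) return(NULL)
    data.frame(accession = a, chrom = cs$chrom, pos = cs$pos, ref = cs$ref,
               alt = cs$alt, stringsAsFactors = FALSE)
  }))
  empty <- list(G = matrix(0L, length(acc) + !is.null(reference_name), 0L,
                           dimnames = list(c(acc, reference_name), NULL)),
                sites = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   stringsAsFactors = FALSE))
  if (is.null(all_calls) || !nrow(all_calls)) {
    warning("no consensus calls; returning an empty matrix")
    return(structure(empty, class = "biallelic_matrix"))
  }

  sites <- unique(all_calls[, c("chrom", "pos", "ref")])
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  skey <- paste(sites$chrom, sites$pos)
  ckey <- paste(all_calls$chrom, all_calls$pos)

  # criterion ii: depth >= min_depth in every accession
  dep_ok <- rep(TRUE, nrow(sites))
  for (a in acc) {
    d <- depth_at(depths[[a]], sites$chrom, sites$pos)
    dep_ok <- dep_ok & d >= min_depth
  }

  # site alt allele: plurality among calling accessions, A<C<G<T tie-break
  alt_of <- vapply(split(all_calls$alt, factor(ckey, levels = skey)),
                   function(al) {
                     if (!length(al)) return(NA_character_)
                     tab <- table(al)  # names are A<C<G<T sorted
                     names(tab)[tab == max(tab)][1]
                   }, "")
  # criterion iii: third-allele carriers among all accessions
  n_other <- vapply(seq_along(skey), function(i) {
    al <- all_calls$alt[ckey == skey[i]]
    sum(al != alt_of[i])
  }, 0L)
  third_ok <- n_other / length(acc) < max_third_allele_frac

  keep <- dep_ok & if (third_allele == "drop_site") n_other == 0L else third_ok
  sites <- sites[keep, , drop = FALSE]
  sites$alt <- alt_of[keep]
  skey <- skey[keep]
  rownames(sites) <- NULL

  if (!nrow(sites)) {
    warning("no site passed the bi-allelic criteria; returning an empty matrix")
    return(structure(empty, class = "biallelic_matrix"))
  }

  G <- matrix(0L, length(acc), nrow(sites), dimnames = list(acc, NULL))
  for (a in acc) {
    cs <- all_calls[all_calls$accession == a, , drop = FALSE]
    m <- match(paste(cs$chrom, cs$pos), skey)
    hit <- !is.na(m) & cs$alt == sites$alt[m]
    G[a, m[hit]] <- 1L
  }
  # criterion i: at least one accession carries the site alt after recoding
  seg <- colSums(G) >= 1L
  G <- G[, seg, drop = FALSE]
  sites <- sites[seg, , drop = FALSE]
  rownames(sites) <- NULL
  if (!is.null(reference_name)) {
    G <- rbind(G, matrix(0L, 1L, ncol(G), dimnames = list(reference_name)))
  }
  structure(list(G = G, sites = sites), class = "biallelic_matrix")
}

#' @export
print.biallelic_matrix <- function(x, ...) {
  cat(sprintf("<biallelic_matrix> %d accession(s) x %d bi-allelic site(s)\n",
              nrow(x$G), ncol(x$G)))
  invisible(x)
}

#' Pairwise proportion of identical genotypes
#'
#' Entry (a, b) is the fraction of matrix sites at which accessions a and b
#' carry the same allele; the complement of [p_distance()].
#'
#' @param M a `biallelic_matrix`.
#' @return Symmetric accessions x accessions matrix with unit diagonal.
#' @export
pairwise_identity <- function(M) {
  stopifnot(inherits(M, "biallelic_matrix"), ncol(M$G) > 0)
  G <- M$G
  S <- ncol(G)
  # matches = S - hamming; hamming via cross products of G and 1-G
  H <- tcrossprod(G, 1L - G)
  ham <- H + t(H)
  (S - ham) / S
}

#' Write a bi-allelic matrix as a multi-sample VCF
#'
#' Haploid GT field (0 = ref, 1 = alt), one sample column per accession.
#'
#' @param M a `biallelic_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_vcf <- function(M, path) {
  acc <- rownames(M$G)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popsnp",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", acc), collapse = "\t"))
  gt <- apply(M$G, 2, function(col) paste(col, collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  M$sites$chrom, M$sites$pos, M$sites$ref, M$sites$alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample haploid VCF into a bi-allelic matrix
#'
#' Round-trips the output of [write_matrix_vcf()].
#'
#' @param path VCF path.
#' @return A `biallelic_matrix`.
#' @export
read_matrix_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)  # INFO not needed here
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v)
  G <- t(matrix(as.integer(gt), nrow = nrow(gt),
                dimnames = dimnames(gt)))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  structure(list(G = G[, ord, drop = FALSE],
                 sites = sites[ord, , drop = FALSE]),
            class = "biallelic_matrix")
}

#' Write / read a plain genotype table
#'
#' TSV with columns chrom, pos, ref, alt followed by one 0/1 column per
#' accession.
#'
#' @param M a `biallelic_matrix`.
#' @param path file path.
#' @return `path` (writer) or a `biallelic_matrix` (reader).
#' @export
write_matrix_tsv <- function(M, path) {
  df <- cbind(M$sites, as.data.frame(t(M$G)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  sites <- df[, c("chrom", "pos", "ref", "alt")]
  G <- t(as.matrix(df[, setdiff(names(df), names(sites)), drop = FALSE]))
  storage.mode(G) <- "integer"
  ord <- order(sites$chrom, sites$pos)
  structure(list(G = G[, ord, drop = FALSE],
                 sites = sites[ord, , drop = FALSE]),
            class = "biallelic_matrix")
}
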