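#' Classify consensus SNPs against an independent technology
#'
#' Each SNP of `rnaseq_consensus` is assigned to exactly one of five
#' categories, evaluated in precedence order so they partition the set:
#'
#' * `identical_A` — same (chrom, pos, alt) in the exome consensus (called
#'   and filter-passing in all three exome callers);
#' * `identical_B` — same (chrom, pos, alt) in one or two of the filtered
#'   per-caller exome sets, but not all three;
#' * `identical_C` — same (chrom, pos, alt) only in the raw (pre-filter)
#'   union of exome calls;
#' * `different_call` — the raw exome union has a call at the position with
#'   a different alternative allele;
#' * `rnaseq_only` — no exome call at the position.
#'
#' @param rnaseq_consensus consensus [callset()] from RNA-seq.
#' @param exome_consensus consensus [callset()] from the exome data.
#' @param exome_filtered_by_caller list of the three filtered per-caller
#'   exome [callset()]s.
#' @param exome_raw_union [callset()]-like records of all raw exome calls
#'   (union over callers, pre-filter).
#' @param min_exome_depth optional gate: positions whose raw exome depth is
#'   below this are not treated as exome-covered (default 0, no gate).
#' @return Object of class `concordance_result`: list with `counts`
#'   (named integer vector over the five categories), `proportions`,
#'   `total` and `category` (per-SNP factor).
#' @export
classify_concordance <- function(rnaseq_consensus, exome_consensus,
                                 exome_filtered_by_caller, exome_raw_union,
                                 min_exome_depth = 0L) {
  stopifnot(inherits(rnaseq_consensus, "callset"),
            length(exome_filtered_by_caller) == 3L)
  x <- rnaseq_consensus
  ref_of <- function(cs) setNames(cs$ref, paste(cs$chrom, cs$pos))
  # inconsistent reference alleles at shared positions are a coordinate bug
  shared <- intersect(paste(x$chrom, x$pos),
                      paste(exome_raw_union$chrom, exome_raw_union$pos))
  if (length(shared)) {
    r1 <- ref_of(x)[shared]
    r2 <- ref_of(exome_raw_union)[shared]
    bad <- which(r1 != r2 & !is.na(r1) & !is.na(r2))
    if (length(bad))
      stop("inconsistent reference alleles at shared position(s): ",
           paste(utils::head(shared[bad], 3L), collapse = ", "))
  }
  raw <- exome_raw_union
  if (min_exome_depth > 0L)
    raw <- raw[raw$depth >= min_exome_depth, , drop = FALSE]

  key <- function(cs) paste(cs$chrom, cs$pos, cs$alt, sep = ":")
  poskey <- function(cs) paste(cs$chrom, cs$pos, sep = ":")
  k_x <- key(x); p_x <- poskey(x)
  in_cons <- k_x %in% key(exome_consensus)
  n_filt <- rowSums(vapply(exome_filtered_by_caller,
                           function(cs) k_x %in% key(cs),
                           logical(length(k_x))))
  if (length(k_x) == 0L) n_filt <- integer(0)
  in_raw <- k_x %in% key(raw)
  pos_raw <- p_x %in% poskey(raw)

  cat_levels <- c("identical_A", "identical_B", "identical_C",
                  "different_call", "rnaseq_only")
  category <- factor(rep("rnaseq_only", nrow(x)), levels = cat_levels)
  category[pos_raw] <- "different_call"
  category[in_raw] <- "identical_C"
  category[n_filt >= 1L & n_filt < 3L] <- "identical_B"
  category[in_cons] <- "identical_A"

  counts <- table(category)
  counts <- setNames(as.integer(counts), names(counts))
  total <- nrow(x)
  props <- if (total > 0) counts / total else counts * NA_real_
  structure(list(counts = counts, proportions = props, total = total,
                 category = category),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>", x$total, "consensus SNP(s)\n")
  df <- data.frame(category = names(x$counts), count = x$counts,
                   proportion = round(x$proportions, 4))
  rownames(df) <- NULL
  print(df)
  invisible(x)
}
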