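# shared fixture builders (everything generated in code; no files on disk)

pure_names <- function(group, n) sprintf("%s_%02d", group, seq_len(n))

# two-group model with optional admixed accessions
two_group_model <- function(n_per_group = 10, F = 0.3, n_sites = 300,
                            chrom_len = 1e6, n_chrom = 1, admixed = NULL,
                            recomb_rate = 2e-4, seed = 1) {
  population_model(
    n_chromosomes = n_chrom, chromosome_lengths = chrom_len,
    n_sites = n_sites,
    groups = data.frame(name = c("A", "B"), n = c(n_per_group, n_per_group),
                        F = c(F, F)),
    admixed = admixed, recomb_rate = recomb_rate, seed = seed)
}

# wrap true genotypes as a biallelic_matrix (no caller noise)
truth_matrix <- function(truth) {
  structure(list(G = truth$G, sites = truth$sites),
            class = "biallelic_matrix")
}

# a callset built from explicit vectors with less typing
mk_calls <- function(pos, alt, alt_reads, depth, chrom = "chr1H",
                     ref = "A", accession = "acc", caller = "c1") {
  callset(chrom = rep_len(chrom, length(pos)), pos = pos,
          ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
          alt_reads = rep_len(alt_reads, length(pos)),
          depth = rep_len(depth, length(pos)),
          accession = accession, caller = caller)
}

# constant-depth track over one chromosome
flat_track <- function(depth, len = 1e6, chrom = "chr1H", accession = "acc") {
  depth_track(data.frame(chrom = chrom, start = 0L, end = as.integer(len),
                         depth = as.integer(depth)),
              accession = accession)
}

# write a small VCF from raw lines
write_vcf_lines <- function(body, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, body), path)
  path
}
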