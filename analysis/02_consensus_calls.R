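#!/usr/bin/env Rscript
# Per-accession consensus SNP calling: read each caller's VCF and the
# shared depth track from scratch/panel/, apply the homozygous filter
# (depth >= 5, alt fraction > 90%) and intersect the three callers.
# Writes consensus VCFs under scratch/consensus/ and a per-accession
# caller/consensus count table (the layout of a multi-caller comparison
# table) under results/.
suppressPackageStartupMessages(library(popsnp))

truth <- read.table("scratch/panel/truth.tsv", header = TRUE, sep = "\t")
accessions <- unique(truth$accession)
callers <- c("freebayes", "glfMultiples", "samtools")
dir.create("scratch/consensus", showWarnings = FALSE)

rows <- lapply(accessions, function(a) {
  calls <- lapply(callers, function(cl)
    read_vcf(file.path("scratch/panel", paste0(a, ".", cl, ".vcf")),
             accession = a, caller = cl))
  depth <- read_bedgraph(file.path("scratch/panel", paste0(a, ".bedgraph")),
                         accession = a)
  cons <- consensus_calls(calls, depth = depth)
  write_callset_vcf(cons$consensus,
                    file.path("scratch/consensus", paste0(a, ".consensus.vcf")))
  cons$summary
})
summary <- do.call(rbind, rows)
write.table(summary, "results/02_consensus_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(head(summary))
cat(sprintf("Consensus is the smallest column for every accession: %s\n",
            all(summary$consensus <=
                pmin(summary$filtered_freebayes, summary$filtered_glfMultiples,
                     summary$filtered_samtools))))
cat("-> results/02_consensus_summary.tsv, scratch/consensus/*.vcf\n")
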