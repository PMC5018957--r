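#!/usr/bin/env Rscript
# Simulate the study panel: two diverged sub-populations ("oriental",
# "occidental") plus an admixed "marginal" group, then derive three-caller
# call sets and depth tracks per accession. Writes the panel under
# scratch/panel/ (VCF + BedGraph + truth table) and a site summary under
# results/.
suppressPackageStartupMessages(library(popsnp))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

seed <- 20260930L
model <- demo_three_group_model(seed = seed)
truth <- simulate_populations(model)
print(truth)

# fp_rate is per Mb of genome; the demo panel is SNP-sparse, so keep the
# absolute number of false calls well below the planted count
profiles <- list(caller_profile("freebayes", 0.05, 0.1, 30),
                 caller_profile("glfMultiples", 0.02, 0.3, 30),
                 caller_profile("samtools", 0.04, 0.2, 30))
# 5-kb depth tiles: coarse enough to keep the written tracks small for a
# 210-Mb genome, fine enough for per-site depth variation
outputs <- simulate_caller_outputs(truth, profiles, seed = seed + 1L,
                                   tile = 5000L)
write_simulated_panel(truth, outputs, "scratch/panel")

per_acc <- data.frame(
  accession = rownames(truth$G),
  group = truth$group_of,
  n_alt_sites = rowSums(truth$G))
write.table(per_acc, "results/01_panel_accessions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Panel: %d accessions, %d sites over %d chromosomes -> scratch/panel/\n",
            nrow(truth$G), ncol(truth$G), model$n_chromosomes))
cat("Accession summary -> results/01_panel_accessions.tsv\n")
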