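#!/usr/bin/env Rscript
# Population structure from the bi-allelic matrix: p-distance
# neighbour-joining tree (newick) and Patterson-normalised PCA scores.
suppressPackageStartupMessages(library(popsnp))

M <- read_matrix_vcf("scratch/biallelic_matrix.vcf")
tree <- nj_tree(M)
write_newick(tree, "results/05_nj_tree.nwk")

truth <- read.table("scratch/panel/truth.tsv", header = TRUE, sep = "\t")
grp <- setNames(truth$group[!duplicated(truth$accession)],
                unique(truth$accession))
ori <- names(grp)[grp == "oriental"]; occ <- names(grp)[grp == "occidental"]
# admixed intermediates sit between/inside the clades by construction, so
# judge group separation on the pure accessions only
pure_tree <- ape::keep.tip(tree, c(ori, occ))
cat(sprintf("Pure groups form two clades (admixed removed): %s\n",
            ape::is.monophyletic(pure_tree, ori) &&
              ape::is.monophyletic(pure_tree, occ)))

pca <- run_pca(M)
scores <- data.frame(accession = rownames(pca$scores),
                     group = c(grp, reference = "reference")[
                       rownames(pca$scores)],
                     round(pca$scores[, 1:4], 4))
write.table(scores, "results/05_pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ev <- pca$eigenvalues
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
            100 * ev[1] / sum(ev), 100 * ev[2] / sum(ev)))
adm <- names(grp)[grp == "admixed"]
cat(sprintf("Admixed accessions between the pure groups on PC1: %s\n",
            all(pca$scores[adm, 1] > min(max(pca$scores[ori, 1]),
                                         max(pca$scores[occ, 1])) &
                pca$scores[adm, 1] < max(min(pca$scores[ori, 1]),
                                         min(pca$scores[occ, 1])))))
cat("-> results/05_nj_tree.nwk, results/05_pca_scores.tsv\n")
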