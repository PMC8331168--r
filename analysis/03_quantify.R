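#!/usr/bin/env Rscript
# Step 3 — relative protein abundance and phosphosite stoichiometry.
#
# Protein abundance is the sum of the retained fragment areas over all
# targeted proteotypic peptides, expressed relative to the WT/control mean.
# Phosphosite stoichiometry is the percentage of phosphopeptide signal over
# the summed phospho + nonphospho signal across both charge states, plus
# the WT/control-relative phosphorylation level. The printed comparison
# against the injected ground truth is possible only because this is a
# simulated study.

library(phosquant)

dataset <- read_dataset("results/dataset")
areas <- read.csv("results/fragment_areas.csv", stringsAsFactors = FALSE)

reference <- list(genotype = dataset$config$reference_genotype,
                  condition = dataset$config$reference_condition)
protein_quant <- quantify_proteins(areas, dataset$design, reference)
phospho_quant <- quantify_phospho(areas, dataset$design, reference)
write.csv(protein_quant, "results/protein_quant.csv", row.names = FALSE)
write.csv(phospho_quant, "results/phospho_quant.csv", row.names = FALSE)

cell <- sub("_r[0-9]+$", "", protein_quant$sample_id)
fold <- aggregate(relative_abundance ~ protein + cell,
                  cbind(protein_quant, cell), mean)
cat("mean relative abundance per cell (truth: mut = 2.5, WT = 1):\n")
print(fold, row.names = FALSE)

pcell <- sub("_r[0-9]+$", "", phospho_quant$sample_id)
occ <- aggregate(P_percent ~ site + pcell, cbind(phospho_quant, pcell), mean)
cat("\nmean stoichiometry per cell (truth: control 12%, treated 40%):\n")
print(occ, row.names = FALSE)
cat("\nwritten: results/protein_quant.csv, results/phospho_quant.csv\n")
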