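#!/usr/bin/env Rscript
# Step 1 — generate the synthetic targeted-MS study.
#
# Design: 2 genotypes (WT, mut) x 2 conditions (control, treated) x 3
# replicates. The mutant carries a 2.5-fold protein abundance increase; the
# regulatory phosphosite on protein P01 moves from 12% occupancy (control)
# to 40% (treated). Chromatograms carry 10% multiplicative point noise, a
# drifting baseline and tailed (EMG) peaks. Everything downstream of this
# script works only from the files written here.

library(phosquant)

seed <- 1L
config <- sim_config()
dataset <- simulate_dataset(config, seed = seed)

dir.create("results", showWarnings = FALSE)
write_dataset(dataset, "results/dataset")
write_transition_csv(dataset$transitions, "results/transition_list.csv")
write_protein_fasta(dataset$proteins, "results/proteins.fasta")

cat("samples:     ", nrow(dataset$design), "\n")
cat("proteins:    ", length(dataset$proteins), "with",
    sum(dataset$targets$role == "quant"), "proteotypic peptides targeted\n")
cat("phosphosite: ", unique(na.omit(dataset$targets$site)), "\n")
cat("transitions: ", nrow(dataset$transitions),
    "(2+/3+, top", config$k_fragments, "fragments per form)\n")
cat("chromatogram points:", nrow(dataset$xics), "\n")
cat("written: results/dataset/, results/transition_list.csv,",
    "results/proteins.fasta\n")
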