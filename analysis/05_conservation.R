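#!/usr/bin/env Rscript
# Step 5 — phosphosite conservation analysis.
#
# A SYNTHETIC ortholog alignment (12 species, 60 columns) stands in for a
# curated MSA: a conserved core with an R-x-x-S kinase motif whose serine
# is retained in one clade and replaced by alanine in the other, plus
# per-species substitutions and a gappy N-terminus. The analysis maps the
# reference serine through the alignment, flags which species keep it,
# scores the surrounding window with BLOSUM62 categories, builds the
# Jukes-Cantor/UPGMA tree with bootstrap support, and scans for the motif.

library(phosquant)

seed <- 1L
make_synthetic_msa <- function(seed) {
  aa <- setdiff(rownames(blosum62()), c("C", "W"))
  with_seed <- function(s, expr) {
    set.seed(s)
    expr
  }
  with_seed(seed, {
    core <- sample(aa, 54, replace = TRUE)
    core[25:28] <- c("R", "Q", "V", "S")  # R-x-x-S with Ser at position 28
    clade_a <- paste0("spA", 1:6)
    clade_b <- paste0("spB", 1:6)
    rows <- character(0)
    for (i in seq_along(c(clade_a, clade_b))) {
      s <- core
      in_b <- i > 6
      if (in_b) {
        s[28] <- "A"                       # serine lost in clade B
        s[seq(2, 54, by = 6)] <- sample(aa, 9, replace = TRUE)
      }
      s[sample(setdiff(1:54, 25:28), 3)] <- sample(aa, 3, replace = TRUE)
      lead <- if (i %% 3 == 0) "------" else paste(sample(aa, 6,
                                                          replace = TRUE),
                                                   collapse = "")
      rows <- c(rows, paste0(lead, paste(s, collapse = "")))
    }
    setNames(rows, c(clade_a, clade_b))
  })
}

msa <- as_msa(make_synthetic_msa(seed))
ref <- "spA1"
dir.create("results/conservation", recursive = TRUE, showWarnings = FALSE)

# the reference serine is residue 34 of spA1 (6 leading + position 28)
hit <- map_reference_position(msa, ref, 34)
report <- data.frame(species = names(hit$residues),
                     residue = unname(hit$residues),
                     is_ser = unname(hit$is_ser))
write.table(report, "results/conservation/site_report.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("reference Ser maps to alignment column", hit$column, "\n")
cat("species retaining the Ser:", sum(hit$is_ser), "of", length(msa), "\n")

window <- (hit$column - 5):(hit$column + 5)
sim <- window_similarity(msa, window)
write.table(sim, "results/conservation/window_similarity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("window categories:\n")
print(table(sim$category))

bs <- bootstrap_support(msa, n_reps = 1000, seed = seed)
ape::write.tree(bs$tree, "results/conservation/upgma_bootstrap.nwk")
cat("bootstrap support for the clade split:",
    round(unname(bs$support[paste(sort(paste0("spB", 1:6)),
                                  collapse = "|")])), "%\n")

ungapped <- gsub("-", "", msa[ref])
hits <- motif_scan(ungapped, "R-x-x-S")
cat("R-x-x-S motif in", ref, "at residue(s):", paste(hits, collapse = ", "),
    "\n")
cat("written: results/conservation/{site_report.tsv,",
    "window_similarity.tsv, upgma_bootstrap.nwk}\n")
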