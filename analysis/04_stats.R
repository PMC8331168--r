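#!/usr/bin/env Rscript
# Step 4 — the statistical layer.
#
# Group comparisons as they appear in targeted-proteomics figures: one-way
# ANOVA with Tukey HSD compact letters across all genotype x condition
# groups, Kruskal-Wallis with Conover rank-LSD/Bonferroni letters as the
# nonparametric counterpart, and per-genotype Student's t tests of treated
# versus control. A small qPCR table normalized to two reference genes
# (NRQ) rounds out the layer.

library(phosquant)

protein_quant <- read.csv("results/protein_quant.csv",
                          stringsAsFactors = FALSE)
phospho_quant <- read.csv("results/phospho_quant.csv",
                          stringsAsFactors = FALSE)
design <- read.csv("results/dataset/design.csv", stringsAsFactors = FALSE)

group_of <- function(ids) sub("_r[0-9]+$", "", ids)

stats_rows <- list()
pair_rows <- list()
for (p in unique(protein_quant$protein)) {
  q <- protein_quant[protein_quant$protein == p, ]
  g <- group_of(q$sample_id)
  ld <- anova_tukey_letters(q$relative_abundance, g)
  kw <- kruskal_lsd_letters(q$relative_abundance, g)
  s <- ld$summary
  s <- data.frame(measure = p, s, letters_tukey = ld$letters[s$group],
                  letters_kw = kw$letters[s$group])
  stats_rows[[p]] <- s
  pair_rows[[p]] <- data.frame(measure = p, ld$pairwise,
                               method = "tukey_hsd")
  cat("\n==", p, "relative abundance ==\n")
  print(ld)
}

q <- phospho_quant
g <- group_of(q$sample_id)
ld <- anova_tukey_letters(q$P_percent, g)
site <- unique(q$site)
stats_rows[[site]] <- data.frame(measure = site, ld$summary,
                                 letters_tukey = ld$letters[ld$summary$group],
                                 letters_kw =
                                   kruskal_lsd_letters(q$P_percent,
                                                       g)$letters[
                                                         ld$summary$group])
pair_rows[[site]] <- data.frame(measure = site, ld$pairwise,
                                method = "tukey_hsd")
cat("\n==", site, "stoichiometry (%) ==\n")
print(ld)

cat("\n== treated vs control Student's t (per genotype) ==\n")
for (p in unique(protein_quant$protein)) {
  for (gt in unique(design$genotype)) {
    q <- protein_quant[protein_quant$protein == p, ]
    a <- q$relative_abundance[grepl(paste0("^", gt, "_control"), q$sample_id)]
    b <- q$relative_abundance[grepl(paste0("^", gt, "_treated"), q$sample_id)]
    r <- two_group_test(a, b)
    cat(sprintf("%-4s %-4s t = %6.2f  p = %.4f %s\n", p, gt, r$t, r$p_value,
                if (r$significant) "*" else ""))
  }
}

write.csv(do.call(rbind, stats_rows), "results/stats.csv", row.names = FALSE)
write.csv(do.call(rbind, pair_rows), "results/pairwise.csv",
          row.names = FALSE)

# qPCR: a transcript induced 4-fold in treated samples, Cq shifted by -2
# cycles at efficiency 2, two stable polyubiquitin-like reference genes
cq <- expand.grid(gene = c("target", "refUBC", "refUBQ10"),
                  sample = design$sample_id, stringsAsFactors = FALSE)
cq$cq <- ifelse(cq$gene == "target", 26, 22)
treated <- grepl("treated", cq$sample) & cq$gene == "target"
cq$cq[treated] <- cq$cq[treated] - 2
set.seed(14)
cq <- do.call(rbind, lapply(1:3, function(i) {
  tech <- cq
  tech$cq <- tech$cq + rnorm(nrow(tech), 0, 0.05)  # technical triplicate
  tech
}))
out <- nrq(cq, reference_genes = c("refUBC", "refUBQ10"))
write.csv(out, "results/nrq.csv", row.names = FALSE)
tgt <- out[out$gene == "target", ]
cat("\n== NRQ (target, mean per condition; truth: 4-fold induction) ==\n")
print(aggregate(nrq ~ grepl("treated", sample), tgt, mean), row.names = FALSE)
cat("\nwritten: results/stats.csv, results/pairwise.csv, results/nrq.csv\n")
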