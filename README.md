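# phosquant

Label-free targeted-proteomics quantification for plant stress-signalling
studies: parallel reaction monitoring (PRM) protein abundance, phosphosite
stoichiometry from paired phospho/nonphospho peptide forms, the
accompanying statistics (Tukey / Kruskal–Wallis letter displays, Student's
t, qPCR NRQ normalization), and phosphosite conservation analysis
(Jukes–Cantor + UPGMA trees with bootstrap support, BLOSUM62 window
similarity, degenerate motif scanning). A synthetic-data generator with
known ground truth makes the whole pipeline testable end to end without any
instrument data.

## Who this is for

Groups quantifying a handful of proteins and a regulatory phosphosite
across genotype × condition designs (n ≈ 3) with scheduled PRM, who want
the arithmetic between "Skyline peak areas" and "figure panel" to be
explicit, tested code rather than spreadsheet steps — and a simulator to
validate that arithmetic against injected truth.

## The two formulas at the core

Relative protein abundance, from the targeted proteotypic peptides *p* and
each peptide's retained most-intense fragment areas *f<sub>pk</sub>*:

    A = Σ_p Σ_k f_pk            (reported relative to the WT control mean)

Phosphosite stoichiometry, from phospho-form areas *pt* and
nonphospho-form areas *t* summed over fragments and charge states (2+ and
3+ are both targeted):

    P = 100 · Σ pt / (Σ t + Σ pt)      (percent, in [0, 100])

plus the WT-control–relative phosphorylation level P / mean(P_ref).

## Worked example

The `analysis/` scripts run the whole study in order; each is a thin driver
over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic study, ground truth on disk
Rscript analysis/02_integrate.R     # XICs -> fragment peak areas
Rscript analysis/03_quantify.R      # Eq. A and P per sample
Rscript analysis/04_stats.R         # letters, t tests, qPCR NRQ
Rscript analysis/05_conservation.R  # site mapping, similarity, tree
```

`03_quantify.R` prints the recovery of the injected conditions (mutant
fold 2.5; occupancy 12% control → 40% treated). With seed 1:

```
mean relative abundance per cell (truth: mut = 2.5, WT = 1):
 protein        cell relative_abundance
     P01 mut_control          2.5009006
     P02 mut_control          2.5178325
     P01 mut_treated          2.4922180
     P02 mut_treated          2.4876498
     P01  WT_control          1.0000000
     ...
mean stoichiometry per cell (truth: control 12%, treated 40%):
    site       pcell P_percent
 P01_S40 mut_control  12.23367
 P01_S40 mut_treated  40.08266
 P01_S40  WT_control  11.90677
 P01_S40  WT_treated  39.81381
```

i.e. the pipeline recovers the injected fold within ~1% and the injected
occupancies within ~0.3 percentage points under 10% multiplicative point
noise. `04_stats.R` then prints the letter display separating the two
occupancy levels (`a`/`b`) and a qPCR target whose 4-fold induction is
recovered by NRQ normalization (ratio 4.02).

Library calls mirror the scripts:

```r
library(phosquant)
ds    <- simulate_dataset(sim_config(), seed = 1)
areas <- integrate_chromatograms(ds$xics, ds$transitions)
quantify_proteins(areas, ds$design)   # A and relative abundance per sample
quantify_phospho(areas, ds$design)    # P and relative phosphorylation
```

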