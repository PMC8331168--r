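---
title: "Label-free PRM quantification, phosphosite stoichiometry and conservation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free PRM quantification, phosphosite stoichiometry and conservation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosquant)
```

## The measurement model

`phosquant` implements the computational core of a label-free targeted
proteomics study built around parallel reaction monitoring (PRM). A small set
of proteotypic peptides is scheduled per protein, the instrument records an
extracted-ion chromatogram (XIC) per fragment ion, and each XIC is reduced to
one background-subtracted peak area. Two quantities are then formed.

**Relative protein abundance.** For a protein with targeted proteotypic
peptides $p = 1, 2, \dots$ and retained fragment areas $f_{p1}, f_{p2},
f_{p3}$ (the three most intense fragments of each peptide, summed over the
targeted precursor charge states),

$$A = \sum_p \sum_k f_{pk},$$

reported relative to the mean $A$ of the wild-type control replicates. The
sum runs over *all* targeted peptides of the protein, whether three or four
were selected: the selection rule admits either count, and a fixed-three sum
would silently drop signal whenever four peptides are scheduled.

**Phosphosite stoichiometry.** The phosphorylated and nonphosphorylated
forms of the site-bearing peptide are both targeted, each at 2+ and 3+. With
phospho-form areas $pt_i$ and nonphospho areas $t_j$ summed over fragments
and charge states,

$$P = 100 \cdot \frac{\sum_i pt_i}{\sum_j t_j + \sum_i pt_i},$$

a percentage in $[0, 100]$, plus the ratio of $P$ to the wild-type control
mean ("relative phosphorylation"). $P$ is invariant to global intensity
scaling and, in the generative model below, equals the injected occupancy
exactly when both forms share a fragmentation response.

Both formulas are deliberately trivial arithmetic; the package's value is
that every term is produced by an explicit, testable chain (digestion →
selection → scheduling → simulation → integration), and that the formulas
are verified against brute-force summation oracles to $10^{-12}$ relative.

## The synthetic-data generator

Real acquisitions for this kind of study live in proteomics repositories and
are not desk-reproducible, so the package ships a generator whose defaults
*are* the study conditions the analysis assumes:

* design: 2 genotypes × 2 conditions × 3 biological replicates;
* a 2.5-fold protein abundance increase in the mutant genotype;
* phosphosite occupancy moving from 12% (control) to 40% (treated);
* 10% multiplicative log-normal point noise, a 5 a.u. baseline with
  0.05 a.u./min drift;
* exponentially modified Gaussian (EMG) peaks, $\sigma = 0.05$ min,
  $\tau = 0.02$ min, with a 0.02 min per-sample RT jitter;
* a 0–60 min gradient sampled every 0.01 min inside 5-min scheduled
  windows; fragment patterns drawn once per peptide from a symmetric
  Dirichlet (concentration 2) and frozen as the "spectral library";
  charge shares fixed at 0.7/0.3 for 2+/3+.

Replicate scatter comes solely from per-point noise and RT jitter — the
noise model the boundary-detection and integration stages must survive.
Peak areas, not heights, carry the quantity: the EMG is the convolution of
a Gaussian with an exponential tail, so its area equals the Gaussian's
$A_{\textrm{apex}}\,\sigma\sqrt{2\pi}$ for any $\tau$, which gives every
integration test a closed form.

Synthetic proteins are assembled from unique random tryptic peptides
(8–14 residues, no internal K/R, no Met, terminated by K/R), plus one
peptide shared across proteins and one Met-containing peptide so the
proteotypic-selection rules are exercised, and one serine-bearing peptide
annotated as the phosphosite. Because proteins are concatenations of their
designed peptides, the zero-missed-cleavage digest is known by
construction.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: interference from co-eluting analytes,
isotope envelopes, ionization suppression, differing response factors
between phospho and nonphospho forms (real occupancy estimates from
intensity ratios carry exactly that assumption), missing peptides,
cross-run RT drift beyond a rigid shift, and saturation. The stochastic
acceptance check says the *pipeline* adds less than a percent of bias under
its own noise model, not that PRM ratios on an instrument are that good.

## Numerical choices

* **EMG evaluation.** The textbook EMG form overflows for small $\tau$; we
  evaluate through the scaled complementary error function, switching to an
  asymptotic series for arguments above 25 (the naive `erfcx` saturates
  there), and fall back to the Gaussian for $\tau < 10^{-10}\sigma$.
* **Baseline.** Mean of the lowest decile of window intensities, clipped at
  zero — robust while any peak occupies less than ~90% of the window.
* **Peak boundaries.** From the apex outward to the first point at ≤ 1% of
  the baseline-subtracted apex, or to a *valley*: a running minimum below
  half height followed by a climb exceeding 1.5× the valley height plus 3×
  the trace MAD. A bare local-minimum stop truncates peaks at the first
  noise dip (median area recovery 38% at 10% CV in our profiling); the
  valley conditions restore the intent — stop at the saddle before a
  neighbouring peak — while leaving noise-free boundaries exactly at the 1%
  cutoff, where ≥ 99.7% of the analytic Gaussian area is recovered.
* **Detection threshold.** Apex must exceed background + 3× MAD of the
  trace, the conventional 3σ rule; otherwise the trace yields a "no peak"
  result that contributes area 0 with a propagated flag, so the sums in
  $A$ and $P$ stay defined and replicate vectors stay aligned.
* **Integration.** Trapezoidal on the clipped, background-subtracted
  signal — grid-step independent, linear in the trace.
* **Ties.** Top-$k$ fragments break ties by ion label; proteotypic ranking
  by summed library intensity breaks ties alphabetically; UPGMA joins tied
  pairs by the lexicographically smallest pair of cluster representative
  labels; compact-letter columns are lettered in group input order. All
  outputs are deterministic given the root seed, from which every stream
  is derived by stable named sub-seeding.

## The statistical layer

Student's *t* is the pooled-variance form (the classical "Student's t
test"), with zero-variance conventions $p = 1$ (equal means) and $p = 0$
with a warning (unequal). One-way ANOVA uses `stats::aov` with Tukey HSD
adjusted pairwise *p*-values; the nonparametric route is Kruskal–Wallis
with the Conover rank-based least-significant-difference procedure and
Bonferroni correction over all pairs. Rank-based LSD was chosen over
raw-data LSD because the omnibus test is rank-based; the post hoc runs only
when the omnibus *p* < α (the conventional protected-LSD gate), otherwise
all groups share one letter and pairwise *p*-values are reported NA.

Compact letter displays use insert-and-absorb: start from one letter
covering all groups, split on each significant pair, absorb subset columns.
The construction guarantees the defining biconditional — two groups share a
letter iff their adjusted $p \ge \alpha$ — which the suite verifies
exhaustively for up to six groups.

qPCR normalized relative quantities follow the efficiency-corrected model:
$RQ_{g,s} = E_g^{\,\overline{Cq}_g - Cq_{g,s}}$ centred on the per-gene
mean Cq (a named calibrator sample is available as an option),
normalization factor = geometric mean of the reference-gene RQs, $NRQ =
RQ/NF$. Mean-centring makes NRQ invariant to uniform per-sample Cq shifts
when efficiencies are shared; standard errors propagate first-order from
technical-replicate scatter, treating gene terms as independent.

## Conservation analysis

The conservation module consumes a precomputed protein MSA (alignment
computation is out of scope). Distances are *p*-distances with pairwise
gap deletion, corrected by the Jukes–Cantor model generalized to a
$k = 20$ state alphabet,

$$d = -\tfrac{19}{20}\,\ln\!\left(1 - \tfrac{20}{19}\,p\right),$$

the standard Poisson-corrected equal-rates form for proteins; $p \ge 19/20$
is reported as saturation rather than extrapolated. UPGMA is implemented
directly (size-weighted cluster averaging, node height $d/2$) with the tie
rule above, and is cross-checked in the tests against both a naive
re-implementation and average-linkage `hclust`. Bootstrap support resamples
columns with replacement, rebuilds the tree, and scores each original
internal bipartition by its replicate frequency; supports are keyed by
bipartition identity, so they are invariant to taxon input order. The
full-alignment topology is kept as the display tree with supports as node
labels — the conservative reading of "consensus tree" for an ultrametric
method.

Site mapping walks the reference row's non-gap characters to find the
alignment column of a residue of interest and flags which species retain a
serine there. Window similarity scores each column's non-gap residues
against the modal consensus (ties by higher BLOSUM62 self-score, then
alphabetically) with threshold 1, and assigns display bands **black =
100%**, **dark-grey [80, 100)**, **light-grey [60, 80)**, **uncoloured
< 60%** — the published band edges overlap at their endpoints, and
half-open intervals with exact-100 reserved for black are the only
unambiguous reading. The motif scanner accepts degenerate patterns such as
`R-x-x-S` (wildcards and bracketed alternatives) and reports overlapping
matches.

## Problem sizes and limitations

The test suite and acceptance script run the full design (12 samples, 48
transitions, ~289k chromatogram points) once noise-free and across 100
seeds at 10% CV; oracle equivalences use 1,000 random tables; UPGMA is
checked on 200 random 6-taxon matrices; bootstraps use 1,000 replicates on
a 6-taxon, 200-column alignment; the *t*-test size check uses 10,000 null
simulations. These sizes make every empirical claim in this vignette a
quantity the suite itself computes.

Known limitations: no deconvolution of co-eluting isomers and no smoothing
(by design); occupancy assumes equal phospho/nonphospho response; the
Conover LSD is one of several defensible rank post hocs; NRQ standard
errors ignore covariance between a reference gene and itself when a
reference is also the target; and the acquisition-schedule defaults
(points per peak, window width) are field-typical values, not estimates
from any particular instrument.
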