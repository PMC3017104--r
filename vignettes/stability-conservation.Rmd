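---
title: "Linking thermodynamic stability to evolutionary conservation with stabcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking thermodynamic stability to evolutionary conservation with stabcons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabcons)
```

## The question the package addresses

Buried and interface residues of a protein complex can be conserved for
two quite different reasons: because substitutions destabilize the fold
or the interface (a thermodynamic constraint), or because the position
does something else — catalysis, a binding epitope, an allosteric relay
(a functional constraint). `stabcons` implements a pipeline that puts
the two on the same scale. From a per-position ΔΔG mutational scan it
derives the amino-acid distribution that thermodynamics alone would
tolerate; from a multiple sequence alignment it measures the
distribution evolution has actually retained. Positions where evolution
is far more conservative than stability requires, or where pairs of
positions covary beyond what the phylogeny explains, are candidates for
function beyond stability. The motivating system is the histone fold —
H3/H4 of the nucleosome, where buried-core conservation famously exceeds
what stability accounts for — but every stage is generic.

## The model, stage by stage

### Burial and interface classification

Solvent accessibility is computed with a deterministic dot-surface
algorithm: `n_dots` quasi-uniform points (a Fibonacci spiral lattice, so
no RNG is involved) are placed on each atom's probe-expanded sphere of
radius $r_{vdW} + r_{probe}$, a dot is exposed if it lies outside every
neighbour's expanded sphere, and

$$\mathrm{SASA} = 4\pi (r_{vdW}+r_{probe})^2 \cdot
  \frac{\#\text{exposed dots}}{n_{dots}}.$$

Defaults: `n_dots = 1024`, water probe `probe_radius = 1.4` Å, Bondi
van der Waals radii (all configurable; the radius table ships as
`default_vdw_radii()`). A residue is **buried** when its whole-residue
SASA is strictly below 1 Å² — the threshold is an area even though such
cutoffs are sometimes misprinted with volume units — computed on the
full complex. Whole-residue rather than side-chain-only SASA is used
because the scan tables the pipeline consumes are whole-residue
quantities. **Interface** residues come from a geometric surrogate
(any heavy atom within 4.5 Å of the partner chain), since contact
persistence in long simulations cannot be recomputed here; an explicit
override list is accepted for studies where the interface set is known.

### Boltzmann sequence entropy from ΔΔG

Amino-acid propensities at a position are assumed Boltzmann-distributed
over the mutant stabilities:

$$p_i \propto e^{-\Delta\Delta G_{wt \to i}/k_BT}, \qquad
  H(k) = -\sum_i p_i \ln p_i,$$

with $k_B = 0.0019872$ kcal/(mol·K) and $T = 300$ K by default (the
physiological range; entropy is monotone non-decreasing in $T$, which
the test suite checks on a thousand random scans). The alphabet is the
native residue (at ΔΔG = 0) plus the 17 scanned mutants — cysteine and
proline are conventionally excluded from such scans — yet entropies are
normalized by $\ln 20$, the maximal possible entropy, so a flat scan
reaches $\ln 18/\ln 20 \approx 0.965$, not 1. Whether the propensity
alphabet should include the native (18 letters) or not (17) is genuinely
open; we include it, since the native's ΔΔG of zero is as much a
statement about tolerance as any mutant's value. Propensities depend
only on ΔΔG *differences* (shift invariance), another tested property.

**Native recapitulation** is the fraction of positions whose
minimum-ΔΔG amino acid is the native; ties count as recapitulated.

### Evolutionary entropy and the entropy–entropy comparison

Column frequencies are weighted with the Henikoff position-based
scheme — each sequence receives $1/(rs)$ per column ($r$ distinct
symbols, $s$ copies of the sequence's symbol), summed and normalized —
so dense clades of near-identical sequences do not masquerade as
conservation. Gaps are excluded and the amino-acid mass renormalized
(the HSSP convention); treating the gap as a 21st symbol is available
for the MI machinery via `gap_as_symbol`. Entropies are again
normalized by $\ln 20$.

The calculated and evolutionary entropies are compared by Pearson
correlation with the exact-null t-transform p-value
($t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided — the transform reproduces
the printed p-values of both correlations the analysis is checked
against). `partition_positions()` then splits positions into three
sets: **outliers** (normalized evolutionary entropy ≥ 0.2 — variable
positions whose conservation is better explained by tree structure),
**correlated** (within 2 RMS residuals of the line fitted to the
remainder; the slope is reported), and **over-conserved** (the rest —
conservation exceeding what stability predicts). The two thresholds are
unavoidably conventional; they are reported with the labels and
configurable.

### Coevolution: normalized MI with a tree-based null

For columns $i, j$:

$$MI(i,j) = H(i) + H(j) - H(i,j), \qquad
  MI_N(i,j) = \frac{MI(i,j)}{H(i,j)},$$

the joint entropy being the best normalizer in that it bounds the score
to $[0,1]$ and decouples it from per-column variability. Z-scores
standardize $MI_N$ against its mean and SD over *all* analyzed pairs
(restricting the reference population to a subset of interest is
possible by passing `positions`); $z \ge 4$ flags candidate
coevolution.

Phylogeny alone generates mutual information, so candidates are vetted
against a **tree-based shuffling null**: the symbols of column $j$ are
swapped between sequence pairs $(a,b)$ drawn with probability
proportional to $e^{-\lambda d(a,b)}$, where $d$ is the Kimura-corrected
genetic distance, column $i$ is held fixed, and 100 replicates of 2000
swaps each rebuild the $MI_N$ null. Because close relatives trade
symbols preferentially, the null preserves tree-wide conservation
structure while destroying the specific $i$–$j$ pairing. The decay
rate $\lambda$ defaults to $1/\bar d$ (the exponential form and this
scale are our choices, recorded in every result's metadata; $\lambda=0$
recovers a uniform permutation null, which the acceptance suite
verifies against a naive permutation oracle). The empirical p-value is
the null exceedance fraction; an exact zero is reported as
$1/(n_{iter}+1)$, the resolution of a 100-replicate null. p < 0.05 is
called significant. When a structure is supplied, significant pairs are
annotated proximal/distant at a Cβ–Cβ (Cα for glycine) cutoff of 8 Å.

### Phylogenetic profiles

Protein distances use the Kimura correction
$d = -\ln(1 - p - p^2/5)$ on the mismatch fraction $p$ (gapped columns
excluded); pairs past the correction's domain raise a saturation error
rather than returning a fabricated distance. Trees are built by
neighbor joining (`ape::nj`; negative branch lengths clamped to zero
and counted). NJ over Kimura distances is a reproducible surrogate for
the guide-tree machinery of alignment programs, which is not otherwise
recomputable. `node_conservation_profile()` gives, for every internal
node, the column's frequency vector over the node's leaf descendants;
a position is called **tree-determinant** when two disjoint clades,
each ≥ 10% of the leaves, prefer different amino acids at within-clade
frequency ≥ 0.8 (thresholds configurable — no published convention
exists).

### Phenotype classification

Mutations with ΔΔG ≥ +3 kcal/mol are predicted lethal. The comparison
is `>=`, so a mutation printed exactly at the threshold is called
lethal, matching how such borderline interface mutations are tabulated
in practice. Lethal-vs-viable ΔΔG distributions are compared with a
one-tailed pooled-variance Student's t-test (Welch behind a flag);
the degenerate zero-variance/equal-means case returns p = 0.5.

## What the synthetic generators emulate

The generators exist so every stage runs end-to-end, with ground truth,
offline.

* `gen_toy_structure()` builds a cubic cluster of single-carbon
  pseudo-residues at 2.8 Å spacing: interior residues are provably
  enclosed (SASA exactly 0), shell residues sit far above 1 Å².
* `gen_ddg_scan()` designs scans by inverse solving: heterogeneous
  mutant gap directions are rescaled by 1-d root finding until the
  Boltzmann entropy matches a target drawn from a `ddg_spread`-scaled
  family. The returned targets are the achieved entropies of the
  planted values, so the round-trip check (CSV serialization →
  parsing → propensities → entropy) must close to ~1e-9, which it
  does only if every stage is numerically faithful.
* `gen_msa()` simulates columns down an ultrametric tree, resampling
  each site from its stationary distribution (mass `q` on a dominant
  letter) at rate 1 per unit branch length; root-to-tip depth defaults
  to 2 expected substitutions, close to stationarity at the leaves.
  The default tree is **balanced** (pruned deterministically to any
  *n*): balanced shapes give many effectively independent lineages,
  so empirical column entropies track their expectations. The
  coalescent shape is available and is the more realistic model of a
  species sample — but precisely because its ancestry concentrates in
  a few deep lineages, empirical entropies are much noisier there.
  Planted coevolving pairs inherit a binary latent state down the same
  tree and emit compatible letter pairs with probability ε; the
  coupling is therefore phylogeny-aware and the tree-based null is
  exercised non-trivially. An `iid` mode (no tree) supports null
  calibration.
* `gen_phenotype_table()` draws lethal ΔΔG from
  N(μ + effect, σ²) and viable from N(μ, σ²), defaulting to 27 and 35
  samples (the sizes of the published mutant compilation), μ = 1
  kcal/mol, σ = 2 kcal/mol and effect = 3 kcal/mol — the scale of the
  lethality threshold itself.

What passing tests on these data do **not** show: real mutational scans
have correlated replicate error and backbone-relaxation artifacts; real
alignments have gaps, indel-driven column misassignment and
non-stationary composition; real trees are neither balanced nor
ultrametric. The generators are deliberately simple — sufficient to
validate the estimators' statistical behaviour, not to certify
performance on any particular protein family.

## Numerical choices and degenerate inputs

* Dot placement is a seedless Fibonacci lattice: reproducible, and
  rotation changes any atom's SASA by at most a dot or two.
* MI is clipped at 0 against floating-point negatives; `mi_norm` is 0
  by convention when H(i,j) = 0.
* Sequences gapped at either column of a pair are dropped and weights
  renormalized (configurable to 21-symbol mode).
* Z-scores error out (rather than returning ±Inf) when the MI_N
  spread across pairs is zero.
* All-gap columns yield flagged `NA` entropies.
* Every stochastic routine takes an explicit seed and records it in
  its output; generators are byte-reproducible given their spec.

## Problem sizes used by the checks

The test and acceptance runs use sizes chosen to exercise the
statistics at meaningful power while staying desk-sized: null
calibration over 20 alignments of 500 sequences × 50 i.i.d. columns;
planted-pair recovery at ε = 0.9 in 200 sequences × 40 columns over 20
seeds (top-1% ranking) with shuffle p-values at the full 100 × 2000
default on 3 seeds; entropy fuzzing at 10³ scans; MI identity fuzzing
over >10⁴ column pairs; phenotype-null calibration over 200 seeds.

## Known limitations

* The SASA routine is a dot-surface approximation, not an analytic
  area; accuracy is bounded by `n_dots` (the two-sphere oracle shows
  <2% at 1024 dots).
* ΔΔG values are inputs; the package does not compute them from
  structure, and inherits whatever biases the upstream force field has
  (e.g. fixed-backbone native bias).
* The Z-score reference population conflates signal pairs with null
  pairs; with many strong couplings the mean/SD inflate and z is
  conservative.
* The shuffle null's swap kernel is one member of a family of
  distance-decaying kernels; only its λ = 0 limit is canonical.
* NJ is distance-based; for very saturated or highly rate-heterogeneous
  families a likelihood tree would be preferable, and the per-node
  profiles are descendant frequencies, not ancestral reconstructions.
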