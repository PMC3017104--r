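# stabcons

**Does thermodynamic stability explain a protein's conservation, or is
something else holding its sequence in place?**

`stabcons` is an R package for structural bioinformaticians and
molecular evolutionists who have (i) a structure of a protein complex,
(ii) a per-position ΔΔG mutational scan (from any stability predictor),
and (iii) a multiple sequence alignment of the family — and want to ask,
position by position, whether evolution tolerates exactly the amino
acids thermodynamics tolerates. It was built around the histone-fold
problem (buried H3/H4 residues are conserved far beyond what nucleosome
stability requires), but every stage is generic.

## What it computes

| Stage | Core quantity |
|---|---|
| Burial/interface | Dot-surface SASA, 1024 dots/atom; buried = whole-residue SASA < 1 Å²; interface by 4.5 Å inter-chain contact (or explicit list) |
| Stability entropy | Boltzmann propensities `p_i ∝ exp(−ΔΔG_i / k_B T)` at 300 K over native + 17 mutants; positional entropy `H = −Σ p ln p`, normalized by ln 20 |
| Evolutionary entropy | Henikoff position-based weights `1/(rs)`; weighted column entropy, gaps excluded, normalized by ln 20 |
| Comparison | Pearson r with the t-transform p-value; three-set partition (outlier / correlated / over-conserved) |
| Coevolution | `MI(i,j) = H(i)+H(j)−H(i,j)`, normalized by the joint entropy; Z-scores over all pairs (z ≥ 4 = candidate); tree-based shuffling null (swap probability ∝ `exp(−λ·d(a,b))`, 100 iterations × 2000 swaps, p < 0.05) |
| Phylogeny | Kimura protein distance `d = −ln(1 − p − p²/5)`; neighbor-joining tree; per-node conservation profiles and tree-determinant calls |
| Phenotype | Lethal if ΔΔG ≥ +3 kcal/mol; one-tailed pooled t-test of lethal vs viable ΔΔG |

Seeded synthetic generators (`gen_toy_structure`, `gen_ddg_scan`,
`gen_msa` with planted coevolving pairs, `gen_phenotype_table`) emulate
every input class with known ground truth, so the whole pipeline runs
and validates offline.

## Worked example

Simulate a full input bundle — a toy structure with a known buried
core, a designed ΔΔG scan, a 120-sequence alignment with one planted
coevolving pair (ε = 0.9 at columns 4 and 19), and a 27/35
lethal/viable phenotype table — then run every stage:

```r
library(stabcons)

spec <- synthetic_spec(seed = 42, n_positions = 30, n_sequences = 120,
                       planted_pairs = data.frame(i = 4, j = 19, epsilon = 0.9))
bundle <- write_synthetic_bundle(spec, "demo")

report <- run_full_analysis(pipeline_config(
  structure = bundle$structure, ddg_table = bundle$ddg_table,
  alignment = bundle$alignment, phenotype_table = bundle$phenotype_table,
  output_dir = "demo/run", seed = 42))
str(report$summary)
```

```
List of 12
 $ seed                 : num 42
 $ n_buried             : int 1
 $ n_interface          : int 0
 $ native_recapitulation: num 1
 $ entropy_correlation_r: num -0.0921
 $ entropy_correlation_p: num 0.628
 $ partition_slope      : num -0.0124
 $ n_significant_pairs  : int 2
 $ profiled_position    : int 8
 $ lethal_sensitivity   : num 0.815
 $ viable_specificity   : num 0.914
 $ ttest_p              : num 2.29e-08
```

Reading the numbers: the cube's single interior residue is classified
buried (`n_buried = 1`, matching the generator's ground truth); every
designed scan position keeps its native as the most stable letter
(`native_recapitulation = 1`); the ΔΔG-derived and evolutionary
entropies are uncorrelated here (`r = −0.09, p = 0.63`) because the
scan and the alignment were simulated independently — on real data this
correlation is the central readout; the phenotype classifier recovers
81.5% of lethal and 91.4% of viable mutants at the +3 kcal/mol cutoff,
and the lethal/viable ΔΔG separation is overwhelming (`p = 2.3e-08`).
The coevolution stage finds the planted pair at the top:

```r
read.delim("demo/run/coevolution_significant.tsv")
```

```
  i  j        mi joint_entropy   mi_norm         z  p_shuffle spatial_class
1 4 19 0.9026715     1.0059217 0.8973576 12.044406 0.00990099      proximal
2 1 21 0.1999783     0.5836681 0.3426233  4.067836 0.00990099      proximal
```

The planted pair (4, 19) stands at z = 12 with the minimum attainable
shuffle p (1/101); the second pair is a borderline z = 4.07
phylogenetic coincidence — exactly the kind of candidate the tree-based
null and the z ≥ 4 threshold are there to police. Per-stage TSVs
(burial, entropies, comparison table, full pair list, Newick tree,
node profiles, PWMs for logo rendering) land in `demo/run/`.

A thin CLI covering simulation and full runs lives at
`inst/cli/stabcons.R`:

```sh
Rscript inst/cli/stabcons.R simulate --seed 1 --out-dir sim
Rscript inst/cli/stabcons.R run-all --config cfg.yaml --out-dir run
```

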