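# rnatopo

Contact-map **topology** analysis for RNA tertiary-structure prediction.

## The problem

RNA structure prediction pipelines commonly work in two steps: predict a
residue–residue *contact map* from evolutionary data (DCA or a neural
network), then fold the molecule with a physics-based engine (e.g. SimRNA)
using the predicted contacts as distance restraints. Prediction quality has
traditionally been judged by the positive predictive value (PPV) of the
contact map alone. But two maps with identical PPV can restrain a folding
simulation very differently: neural predictors tend to emit contacts in
tight *clusters*, which pin down one region of the molecule and leave the
rest unrestrained, while spatially *dispersed* contacts of the same count
and accuracy guide the global fold far better.

`rnatopo` provides the machinery to quantify, construct and evaluate
contact-map topologies:

- **Gauss score** Ω — a kernel-inverse-density measure of contact
  dispersion. With contact positions r_i = (i, j) in the upper triangle of
  the map,

      ν_i = Σ_{j ∈ C} exp(−‖r_i − r_j‖² / σ²),   ω_i = 1/ν_i,
      Ω   = Σ_{i ∈ C} ω_i,                        σ² = 4 by default.

  Isolated contacts contribute ω = 1; contacts buried in a cluster are
  devalued, so 1 ≤ Ω ≤ |C|, with large Ω meaning dispersed topology.
  Ω/L normalizes across molecule sizes, and a soft variant accepts
  real-valued contact probabilities (for use as a loss-function term in
  contact predictors).
- **Contact extraction** from PDB/mmCIF under the two standard contact
  definitions: N1/N9 nitrogen atoms ≤ 9.5 Å, or closest heavy atoms
  < 10 Å, with a configurable minimum sequence separation (default 4).
- **Three selection schemes** for choosing L/2 restraints from a native
  map: `clustered` (drain clusters largest-first — the CNN-like extreme),
  `random` (uniform), and `gauss` (greedy + single-swap maximization
  of Ω).
- **False-contact injection** at a target error rate λ, drawn uniformly
  from non-native pairs, so that PPV = 1 − λ by construction.
- **Evaluation**: PPV, error rate, the Hopkins clustering-tendency
  statistic, the beneficial fraction ξ (share of molecules whose
  restrained-folding RMSD is strictly lower than unrestrained, with a
  size-threshold partition), and Kabsch superposition RMSD.
- **Restraint export** in a SimRNA-style column format with flat-bottom,
  cost-capped penalty metadata.
- **Synthetic generators** (toy hairpin structures, planted-cluster contact
  maps, RMSD tables) so everything above runs without any downloads.

## Worked example

```r
library(rnatopo)

cm <- generate_planted_cluster_map(L = 80, n_stems = 3, n_patches = 4, seed = 7)
cm
#> Contact map: L=80, 86 contacts (external, min_sep=4)
find_clusters(cm)$sizes
#> [1] 26 18 16 12  8  6

n <- default_selection_size(cm)   # L/2 = 40 restraints
for (scheme in c("clustered", "random", "gauss")) { ... }
#> clustered Omega=  8.38  Hopkins=0.940
#> random    Omega= 17.16  Hopkins=0.851
#> gauss     Omega= 22.60  Hopkins=0.825
```

The three schemes pick the same number of contacts from the same native
map, yet their topologies differ sharply: the clustered selection has a low
Gauss score (contacts devalue each other) and a Hopkins statistic near 1
(strong spatial clustering), while the Gauss-optimized selection approaches
the dispersed ideal — the same ordering (clustered > random >
Gaussian-optimized in Hopkins, reversed in Ω) seen when the schemes are
applied to experimentally determined RNA structures.

```r
sel <- select_gauss_optimized(cm, 18, seed = 1)
inj <- inject_false_contacts(cm, sel, lambda_target = 0.25, seed = 2)
ppv(inj, cm)            #> 0.75   (= 1 - lambda, exactly)
error_rate(inj)         #> 0.25

tab <- generate_rmsd_table(56, p = 0.7, seed = 3)   # synthetic folding benchmark
beneficial_fraction(tab)                            #> 0.679
partitioned_beneficial_fraction(tab, 100)$xi_large  #> 0.660 (47 molecules)

rs <- build_restraint_set(inj, rep_len(c("G", "C", "A", "U"), 80))
writeLines(head(write_simrna_restraints(rs), 5))
#> # dialect=generic
#> # penalty=flat-bottom-capped cap=19.5
#> # scheme=gauss seed=2 lambda=0.25
#> A 5 N9 A 28 N1 0 9.5 1
#> A 7 N9 A 26 N1 0 9.5 1
```

## Command line

A thin CLI over the same functions ships with the package:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "rnatopo.R", package = "rnatopo"))')
Rscript $cli extract-contacts --pdb structure.pdb --out contacts.txt
Rscript $cli select --contacts contacts.txt --scheme gauss --n 20 --seed 7 --out sel.txt
Rscript $cli inject --selection sel.txt --native contacts.txt --lambda 0.25 --seed 5 --out noisy.txt
Rscript $cli ppv --selection noisy.txt --native contacts.txt
Rscript $cli hopkins --contacts contacts.txt --seed 3
Rscript $cli make-fixtures --dir fixtures --seed 1
```

All stochastic verbs require `--seed`; JSON output embeds the parameters
(mode, threshold, min_sep, σ², seed) for provenance. Exit codes: 0 success,
2 usage error, 3 data error.

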