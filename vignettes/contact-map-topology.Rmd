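---
title: "Contact-map topology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-map topology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatopo)
```

## Why topology, not just accuracy

A contact map is a binary relation on residue indices `1..L` marking pairs
whose defining atoms are spatially close. When predicted contacts are fed
to a folding engine as distance restraints, the *positions* of the chosen
contacts on the map matter as much as their accuracy: restraints packed
into one cluster over-constrain a single structural element, while the same
number of dispersed restraints constrain the global fold. `rnatopo`
operationalizes this distinction.

## Contact definitions

Two conventions are supported by `contact_definition()`:

* **nitrogen** — residues are in contact when their glycosidic nitrogens
  (N9 for purines A/G, N1 for pyrimidines C/U) are at most **9.5 Å**
  apart. The comparison is inclusive (`<=`), reading "no more than" as a
  closed bound.
* **heavy** — in contact when the *closest* pair of non-hydrogen atoms is
  under **10 Å**; here the bound is strict (`<`), matching the convention
  of the machine-learning predictors that use this definition. Both the
  threshold and the inclusivity are configurable.

Pairs with sequence separation `|i - j| < min_sep` are never counted. The
default `min_sep = 4` removes the trivial near-diagonal band (a chain is
always in "contact" with its sequence neighbours); the exact exclusion
width is not standardized in the field, so it is an explicit flag and is
recorded in every output header. All structures are renumbered `1..L` in
file order across chains, with original chain ids and author numbers kept
as metadata, so a multi-chain file behaves as one index range. Multi-model
files reduce to the first model; alternate locations resolve to the
highest-occupancy copy; modified residues map to parent bases through an
editable table (`options(rnatopo.modified_residues = ...)`) and unmapped
names raise errors rather than being silently skipped, since a silently
dropped residue would shift every downstream index.

## The Gauss score

Each contact occupies a position $r_i = (i, j)$, $i < j$, in the upper
triangle of the map. Define

$$\nu_i = \sum_{j \in C} \exp\left[-\frac{(r_i - r_j)^2}{\sigma^2}\right],
\qquad \omega_i = \nu_i^{-1}, \qquad \Omega = \sum_{i\in C}\omega_i .$$

The kernel variance $\sigma^2$ defaults to **4** (squared index units): at
that width a contact two cells away contributes $e^{-1} \approx 0.37$ and a
contact five cells away essentially nothing, which makes $\Omega$ sensitive
to exactly the cluster scale that convolutional predictors produce. The
self-term $\exp(0) = 1$ is included in $\nu_i$, which bounds
$\omega_i \in (0, 1]$ and yields $1 \le \Omega \le |C|$; without it an
isolated contact would have infinite weight. Distances are measured between
upper-triangle representatives only — including the mirrored lower-triangle
copies would rescale $\Omega$ by a map-dependent factor without adding
information.

Useful closed forms, used throughout the test suite: a single contact has
$\Omega = 1$; two contacts at index distance $d$ have
$\Omega(d) = 2/(1 + e^{-d^2/\sigma^2})$, strictly increasing in $d$; $n$
mutually distant contacts approach $\Omega = n$.

`soft_gauss_score()` is the continuous relaxation for real-valued contact
probabilities $w \in [0, 1]$ (cells with $w = 0$ drop out; $\nu$ becomes a
$w$-weighted kernel sum and the score $\sum_p w_p/\nu(p)$). It reduces
exactly to the binary score on 0/1 maps, which is the property a
loss-function term must satisfy. The package deliberately ships no
autograd machinery or training loop — the score is the quantity; embedding
it in a learning framework is the caller's concern.

```{r}
cm <- contact_map(20, rbind(c(2, 10), c(2, 12)))
gauss_weights(cm)$omega
gauss_score(cm)          # 2/(1 + exp(-1))
```

## Clusters and the three selection schemes

Two contacts are in the same cluster when a path of pixel-adjacent
contacts connects them. On a pixel grid "adjacent" naturally includes
diagonal neighbours, so **8-connectivity is the default** (4-connectivity
is a flag). Clusters are reported size-descending with lexicographic
tie-breaks. Because the near-diagonal band is already excluded by
`min_sep`, simple connected components suffice — no k-means or
density-based machinery is needed.

Given a native map and a restraint budget `n` (default
$\lfloor L/2 \rfloor$, the standard half-length budget):

* `select_clustered()` draws randomly from the largest cluster until it is
  exhausted, then moves to the next cluster in descending-size order.
  (The alternative reading — jumping to the literal smallest cluster after
  the largest — would disperse the selection and contradict the clustered
  intent, so descending order it is.)
* `select_random()` samples uniformly without replacement.
* `select_gauss_optimized()` maximizes $\Omega$: greedy construction
  seeded with the pair of contacts at maximal index distance, then
  single-swap hill climbing until no exchange of a chosen for an unchosen
  contact improves $\Omega$. The procedure is deterministic (lexicographic
  tie-breaks) and its verifiable contract is *single-swap local
  optimality*; on small instances (up to 12 contacts, subsets of up to 4)
  it matches the exhaustive optimum in well over 90% of random instances
  and is never observed below 0.95 of it. Exact subset optimization is
  NP-hard in general, and a deterministic local search keeps results
  reproducible across platforms.

## False contacts and evaluation

`inject_false_contacts()` augments a selection with
$k = \mathrm{round}(\lambda |C| / (1-\lambda))$ pairs drawn uniformly from
the non-native part of the `min_sep`-respecting index domain. The achieved
error rate $k/(|C|+k)$ is recorded (rounding can move it slightly off the
target) and PPV against the native map equals $1-\lambda$ by construction
— an identity the acceptance suite checks end to end at
$\lambda \in \{0, 0.1, 0.25, 1/3, 0.5\}$ with base sizes chosen so the
rounding is exact.

The **Hopkins statistic** measures clustering tendency of the selected
positions over the admissible triangle
$\{(i,j): 1 \le i,\; i + \mathrm{min\_sep} \le j \le L\}$. Per repetition,
$m = \max(1, \lceil 0.1\,n\rceil)$ uniform probes and $m$ sampled real
points yield nearest-neighbour sums $\sum u$ (probe to data) and $\sum w$
(data to other data), and $H = \sum u / (\sum u + \sum w)$; the mean over
**100 repetitions** is returned. Plain Euclidean distances are used (not
the dimension-powered variant), probes are drawn by standard triangle
sampling, and all of `reps`, the 10% sample fraction and the seed are
explicit arguments recorded in CLI output, since Hopkins conventions vary
across implementations. Uniform point sets give $H \approx 0.5$; a single
tight patch gives $H > 0.9$.

The **beneficial fraction** $\xi$ is the share of molecules whose
restrained-folding RMSD is *strictly* lower than the unrestrained RMSD:
$\Theta(0) = 0$, a tie is not a benefit. The size-partitioned variant
splits at a residue threshold with "small" meaning $L \le$ threshold; an
empty group reports `NA` rather than 0 — coercing an undefined fraction to
zero would fabricate a signal from a sample of none.

**RMSD** uses Kabsch superposition (SVD of the cross-covariance with the
determinant sign correction) over atoms matched by chain, residue number
and atom name; the default policy matches all common heavy atoms, with an
N1/N9-only policy available to mirror the contact definition. The test
suite cross-checks it against an independent quaternion
(eigendecomposition) implementation to $10^{-9}$.

## Restraint export

`build_restraint_set()` needs only the sequence: each contact becomes a
record between the two residues' reference atoms with lower bound 0, upper
bound defaulting to the contact-definition threshold, and unit weight. The
penalty is flat-bottom with a capped cost — zero inside the bound, rising
beyond it, constant above a cap distance (default upper + 10 Å) so a
single unfulfillable restraint cannot dominate the folding energy. The cap
and profile are emitted as header metadata rather than hard-coded energy
terms, because penalty functional forms differ across folding-engine
versions; the writer is byte-deterministic and sorts records by position.

## What the synthetic generators emulate — and what they do not

* `generate_toy_structure()` builds idealized hairpins: 5.9 Å
  along-strand steps, 8.6 Å cross-strand reference-atom distance (inside
  the nitrogen threshold), loops of at least 3 residues so designed pairs
  clear the `min_sep` band, plus small Gaussian jitter. It emits its
  ground-truth pairing for oracle tests. It is *not* A-form geometry: no
  base-pair geometry, no sterics, no physical realism — just coordinates
  whose extracted contact map provably contains the designed pairs.
* `generate_synthetic_contact_map()` plants the two motifs real maps show:
  anti-diagonal stem runs and Bernoulli-filled tertiary patches.
  `generate_planted_cluster_map()` wraps it to produce the clustered
  topology typical of CNN predictors (for L = 80: three stems of 5–8
  cells, four dense patches, ~60–90 contacts).
* `generate_rmsd_table()` draws unrestrained RMSDs from a lognormal
  distribution (meanlog $\log 15$, sdlog 0.3 — a realistic spread for
  coarse-grained RNA folding, roughly 8–28 Å) and applies a ±2 Å effect
  with benefit probability `p`.

Passing tests on these fixtures shows that the *operations* are correct
(scores match closed forms, selections obey their contracts, the scheme
ordering clustered > random > Gaussian-optimized holds for mean Hopkins
and reverses for mean Ω). It does not show that any particular real
molecule folds better — that claim requires folding simulations on
experimentally determined structures, which are outside this package's
scope (no SimRNA invocation, no replica-exchange, no trajectory
clustering).

## Numerical choices and degenerate inputs

* Empty contact maps: `gauss_weights`/`gauss_score` raise an error
  (Ω of nothing is undefined), `find_clusters` returns an empty partition,
  `soft_gauss_score` of an all-zero map is 0, and PPV of an empty
  prediction is an error, not 0.
* Hill climbing accepts a swap only if it improves Ω by more than
  $10^{-12}$, preventing tie-cycling; a pass cap of 100 bounds runtime.
* Kernel distances are clamped at 0 before exponentiation to absorb
  floating-point negatives from the quadratic expansion.
* Seeds are mandatory for every stochastic operation and each invocation
  uses its own RNG stream, leaving the caller's `.Random.seed` untouched.
* Problem sizes in the shipped suites: planted maps at L = 80 with ~40
  selected contacts, 30 maps for the scheme comparison, 100 Hopkins
  repetitions, 1 000 random maps for the Ω-bounds property, 50 instances
  for the optimizer-versus-enumeration check — sizes at which every
  distributional claim in the tests is stable across seeds.

## Known limitations

* Contact extraction assumes the reference atoms exist; structures with
  missing N1/N9 atoms fail loudly in nitrogen mode (heavy mode is the
  fallback for incomplete residues).
* The Gauss-optimized selection is a local optimum; pathological maps can
  in principle hold it below the global optimum, though never below
  single-swap optimality.
* The Hopkins statistic is itself stochastic; comparisons between schemes
  should use means over repetitions and multiple maps, as the acceptance
  script does.
* No secondary-structure annotation, base-pair classification, structure
  repair or mmCIF writing; contact tables and restraint files are the
  exchange formats.
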