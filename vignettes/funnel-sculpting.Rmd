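---
title: "Funnel sculpting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Funnel sculpting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelpot)
```

# The model

`funnelpot` trains residue-pair potentials whose native–decoy energy gaps
mimic a chosen structural distance measure. Write $\Delta E_{i,j}(\theta)$
for the energy difference between decoy $j$ of protein $i$ and that
protein's native structure, and $d_{i,j}$ for a native–decoy distance. The
ideal potential satisfies the funnel condition
$\Delta E_{i,j} \approx c_i\, d_{i,j}$ with a positive per-protein constant
$c_i$: energy grows linearly with distance from the native, for every
protein simultaneously. The trainer minimizes

$$\sum_{i,j}\bigl(\Delta E_{i,j}(\theta) - c_i d_{i,j}\bigr)^2
  \;+\; \beta\|\theta\|^2,
  \qquad c_i \ge c_\mathrm{bound},$$

jointly over the coefficient table $\theta$ and the constants $c_i$. Because
the energies are linear in $\theta$ (see below), this is a convex quadratic
program.

## The energy model

Each of the $\binom{20}{2} + 20 = 210$ unordered amino-acid pairs carries a
smooth potential of the Cα–Cα distance, expanded in a uniform cubic B-spline
basis: 12 knots at $1, 2, \dots, 12$ Å give exactly 8 cubic basis functions,
each $C^2$, nonnegative, supported inside $[1, 12]$ Å, and summing to 1 on
$[4, 9]$ Å. The potential therefore has $210 \times 8 = 1680$ parameters; it
is modeled freely in the physically most populated window 4–9 Å and decays
smoothly to zero at 12 Å, so pairs farther apart contribute nothing.
Distances below 1 Å likewise contribute nothing — no extra clash term is
added, since Cα pairs never get that close in practice and the trainer
would have no data there.

Two pair sums are available. **PPD** counts every residue pair with sequence
separation $|i-j| \ge$ `min_sep`. **PPE** restricts the sum to a consensus
contact map computed from the decoy ensemble being scored, the idea being
that contacts conserved across many decoys are the informative ones. Both
energies are sums of per-pair basis evaluations, hence linear in $\theta$ —
the property the whole training formulation rests on — and depend only on
intra-model distances, hence are rigid-motion invariant.

## Distance measures

* **RMSD** uses the closed-form SVD (Kabsch) superposition with reflections
  excluded. For degenerate point sets (collinear chains) the rotation about
  the degenerate axis is fixed by the deterministic SVD convention.
* **GDT-TS** needs, per cutoff $c \in \{1,2,4,8\}$ Å, the largest residue
  subset superposable within $c$. No exact polynomial algorithm is known, so
  the search is made deterministic: superpositions are seeded from every
  contiguous fragment of lengths 3, 5, 7 and $N$ (starts strided by 2 when
  $N > 200$), each refined by re-superposing on the current inlier set until
  it is stable (at most 10 rounds), and the cutoff count is the maximum
  inlier count over all seeds. This reproduces the usual
  maximal-superposable-subset semantics without randomness. GDT-TS and Q are
  similarities; evaluation always uses the starred distance forms
  $1 - \mathrm{GDT\text{-}TS}$ and $1 - Q$.
* **Q*** counts only the native's contacts (9 Å, `min_sep` 3), so decoy-only
  contacts never change it. A native with zero contacts yields $Q = 1$ by
  convention, avoiding 0/0 — such chains carry no contact signal at all.
* **FlexE/MT** place unit springs on the native contact map. The anharmonic
  per-pair term $(k/b^2)(e^{-b\Delta} - 1 + b\Delta)$, $\Delta = d^D - d^N$,
  $b = 0.5$, vanishes with zero slope at $\Delta = 0$, has second-order
  Taylor expansion $(k/2)\Delta^2$ (the harmonic term), and penalizes
  compression more than extension — the three properties that pin down the
  intended behavior. Using the *native* map for every comparison keeps the
  measure well defined and asymmetric in the right way.

All contact-based machinery shares one separation filter, `min_sep = 3`
(configurable): $|i-j| \le 2$ Cα distances are fixed by covalent geometry
and carry no discriminative signal.

## The consensus contact map

Starting from the full ensemble, iterate: (1) compute the fraction
$M_{ij}$ of currently selected decoys whose own 9 Å contact map has contact
$(i,j)$; (2) threshold $S = [M \ge \mu]$ with $\mu = 0.25$; (3) re-select
the 25% of decoys (of the *full* ensemble) with the smallest upper-triangle
Hamming distance to $S$, ties broken by decoy order. Stop when $S$ is stable
or after `max_iter = 20` rounds. Re-selecting from the full ensemble rather
than the shrinking subset keeps the subset size stable and makes the
algorithm a fixed-point iteration on $S$; with fewer than 8 decoys a 25%
subset would contain one decoy or none, so a single averaging pass is used
instead.

## Solving the training problem

No dedicated QP solver is assumed. The objective is quadratic in $\theta$
for fixed $c$, so $\theta$ is eliminated in closed form through one Cholesky
factorization of $\Phi^\top\Phi + \beta I$ (1680 × 1680, where $\Phi$ stacks
the per-decoy feature gaps), leaving a small box-constrained quadratic in
the $M$ constants $c_i$ solved with L-BFGS-B. An independent
alternating-minimization route (ridge solve for $\theta$, closed-form
$c_i = \max(c_\mathrm{bound}, \sum_j \Delta E_{ij} d_{ij} / \sum_j d_{ij}^2)$)
is provided and used in the tests as a cross-check; convexity guarantees
both land on the same optimum.

Design choices in the formulation:

* **$c_i \ge 1$** (default `c_bound`). Without a positive lower bound the
  regularized objective is minimized trivially by $\theta = 0, c = 0$; the
  bound both excludes that solution and fixes the arbitrary energy scale.
* **$\beta$ default** is $10^{-3} \times$ the number of rows when not given:
  regularization should not vanish relative to the data term as ensembles
  grow. Any fixed value can be passed instead.
* **No per-protein row weighting**: proteins with more decoys weigh more.
  This mirrors plain row-stacking; a weighting hook would be the natural
  extension but is deliberately not silently applied.
* **No sign constraints on $\theta$**: trained pair potentials are expected
  to have both attractive and repulsive regions.
* Degenerate inputs error out early: all-zero or constant target distances
  admit no funnel and are rejected rather than silently fit.

## Evaluation

The R-score compares the lowest-energy decoy $s_E$ with the best decoy
$s_d$: $R = (\langle d\rangle - d(s_E)) / (\langle d\rangle - d(s_d))$,
clamped below at $-1$ so a single outlier cannot produce arbitrarily large
negative values. $\langle d\rangle$ is the mean over *all* decoys (the
natural reading; excluding $s_E$ would make the score depend on the energy
argmin twice). Argmin ties break to the first decoy index so reports are
deterministic. Zero-variance energies or distances make the correlation or
R-score undefined; these are reported as `NA` flags and excluded (with a
count) from aggregation rather than raised as errors, since batch
evaluations routinely meet degenerate ensembles. Dispersion is summarized
by the mean absolute deviation around the mean ($\ell_1$), which weighs
outliers less than the standard deviation.

# The synthetic generator

`gen_native` builds a compact self-avoiding walk: consecutive Cα spacing
exactly 3.8 Å, non-adjacent pairs at least 4 Å apart, steps steered toward
the running centroid, and whole walks rejected until the radius of gyration
is below $1.15 \times 2.7\,N^{1/3}$ Å — globular scaling, so that 40-mers
carry a realistic number of 9 Å contacts. `gen_decoys` adds per-coordinate
Gaussian noise smoothed along the chain with a window-3 moving average
(roughly preserving bond lengths), then applies a random rigid motion so
that extrinsic (RMSD, GDT-TS*) and intrinsic (Q*, FlexE, MT) measures are
exercised differently. The default noise grid $\sigma \in \{1, 2, 4\}$ Å
spans near-native to clearly non-native decoys while keeping all of them
recognizably derived from the native — the regime the funnel condition is
about.

**Planted funnels.** A recovery experiment needs targets that are exactly
realizable energy gaps under known coefficients $\theta^\*$. Hand-picked
coefficient tables (e.g. a quadratic well in distance, exported as
`make_well_potential`) turn out to be sign-indefinite on random
perturbations: a compact model has many pairs on the decaying 9–12 Å flank
of any admissible spline, where perturbations lower the energy as often as
they raise it, so roughly a quarter to a half of decoys would get negative
gaps and be destroyed by the nonnegativity floor. The generator therefore
constructs $\theta^\*$ from the generated decoys themselves, as the
minimum-norm ridge interpolant of their RMSD to the native: with fewer
feature rows than 1680 coefficients the interpolation is exact, so the
planted targets equal the (nonnegative) RMSD values while being exactly
linear in the features. The floor $\varepsilon = 10^{-6}$ then only guards
held-out extrapolations. Target noise, when requested, is added on top and
re-floored.

**What passing the synthetic suite does not show.** The generator produces
isotropic, secondary-structure-free perturbations of a single topology; real
decoy sets contain alternative topologies, systematic method biases,
compact-but-wrong folds and heterogeneous chain lengths. Recovery of a
planted linear funnel demonstrates the correctness of the featurization,
the solver and the evaluation chain — not that a potential trained on real
decoys will discriminate real misfolds.

# Problem sizes and numerics

The bundled recovery experiment uses 10 proteins of 40 residues with 100
training and 100 held-out decoys each (2000 feature rows of width 1680),
solved with $\beta = 10^{-8}$ and `c_bound` 1; the whole acceptance script
runs in well under a minute on one CPU, and the test suite in a few tens of
seconds. Numerical tolerances follow from the representations involved: PDB
round-trips are exact to the format's 3-decimal precision; superposition
identities hold to $10^{-9}$; spline partition of unity to machine
precision; solver agreement between the two routes to $10^{-6}$ relative on
the objective.

# Preprocessing contract

PDB input keeps the first MODEL, ignores HETATM, resolves altlocs by
occupancy then file order, maps unambiguous modified residues (MSE → M, …)
to their parents and drops other non-standard residues with a warning. A
residue is backbone-complete iff N, CA, C and O are all present; incomplete
residues are removed before harmonization, and the same rule is applied to
the native (symmetric treatment — the simplest self-consistent choice).
Harmonization allows end gaps only: under an identity-match scoring with
mismatches forbidden, global alignment reduces to an offset scan, and any
internal mismatch or gap is an error naming the offending decoy — residue
substitutions cannot be fixed by trimming, and silently accepting them
would corrupt every pair feature downstream.

# Known limitations

* GDT-TS is a heuristic lower bound on the maximal superposable subset; the
  fragment-seed search can in principle miss the optimum (the tests bound it
  against an exhaustive-seed oracle at small $N$).
* PPE's consensus map is recomputed per evaluated ensemble, so PPE energies
  are ensemble-relative, not transferable single-model scores.
* The trainer holds $\Phi^\top\Phi$ densely (1680², ~22 MB); millions of
  decoy rows stream through `crossprod` fine, but the design assumes the
  1680-parameter model, not larger bases.
* Multi-chain complexes and mmCIF input are out of scope; the first protein
  chain is used unless a chain is named.
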