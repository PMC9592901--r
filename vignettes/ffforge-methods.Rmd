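---
title: "Shell-descriptor force-field generation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell-descriptor force-field generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffforge)
```

## The problem

Classical molecular dynamics needs a complete set of force-field parameters
for every small molecule it simulates: atom-centered partial charges,
Lennard-Jones types, harmonic bond and angle constants, and periodic
dihedral terms. For proteins these come from curated libraries, but each
drug-like molecule is its own chemical fragment, and deriving its charges
from quantum calculations costs hours per molecule. ffforge implements the
alternative: describe each atom by a fixed-width numeric summary of its
bonded neighborhood, train regression/classification heads on labeled
atoms, and assemble the predictions into a simulation-ready GROMACS
topology in seconds.

The bonded energy model the topology feeds is the standard additive form

$$V = \sum_{\text{bonds}} K_b (r - r_0)^2
    + \sum_{\text{angles}} K_\theta (\theta - \theta_0)^2
    + \sum_{\text{dihedrals}} K_\phi [1 + \cos(n\phi - \gamma)]
    + \text{nonbonded terms},$$

with Lennard-Jones parameters taken from a GAFF-style table keyed by atom
type (van der Waals parameters are deliberately *not* refit — they are the
most delicate part of any force field and the packaged table reuses
published GAFF values). Note the harmonic terms carry no 1/2: the GROMACS
writer emits `2*K` so that files follow the GROMACS $(k/2)(r-r_0)^2$
convention, and `evaluate_bonded_energy()` evaluates the form above.

## Descriptors: three bonded shells, width 241

Every atom is encoded as exactly 241 numbers. The reference block (22
entries) carries the element one-hot over the supported vocabulary {C, H,
O, N, S, P, F, Cl, Br}, Pauling electronegativity, covalent radius,
valence, hybridization indicators (sp/sp2/sp3; anything else encodes as all
zeros), and aromatic/ring/fused-ring/chiral/axial/donor/acceptor flags.
Around it, the first, second and third bonded shells contribute 4, 8 and 12
fixed slots of 9 features each (presence bit, atomic number,
electronegativity, bond order and bond length to the parent shell,
aromatic, ring, sp2, sp3), plus one overflow flag per shell:
22 + 24×9 + 3 = 241. Absent neighbors stay at the padding value 0 with
presence 0, so the width never varies — a fixed input size is what lets a
single model serve all elements and molecules.

Within a shell, members are sorted by their complete slot vector
(lexicographically), which makes the descriptor invariant to the input atom
order; ties are genuinely identical slots, so the vector is unchanged under
any tie-break. If a shell overflows its slots (rare below three heavy-atom
branches), the canonically-first members are kept and the shell's overflow
flag is set. Torsion descriptors concatenate the four atoms' full vectors
and append the signed dihedral (965 entries); the quadruple is
canonicalized so a torsion and its reversal share one representation.

The layout lives in a versioned `DescriptorManifest`, serialized as JSON
next to any trained model; prediction refuses a manifest whose width is not
241.

## Model heads

* **Charges** — a random forest (`ranger`, 800 trees, maximum depth 100,
  single-threaded for reproducibility) regressing charge (e) on the
  241-vector. Mean squared error is the validation loss.
* **Atom types, torsion phase, torsion periodicity** — feed-forward
  classifiers with ReLU hidden layers (256, 128 by default), softmax
  output, log-loss, and Adam at learning rate 0.001. No installed R
  package provides this architecture, so the package carries a compact
  implementation (`mlp_fit()`); training is minibatch (32) and fully
  deterministic given a seed. The phase head's vocabulary is {0°, 180°};
  periodicity classes come from the training labels (the convention table
  yields {1, 2, 3}).
* **Force constants** — random forests on smaller bonded descriptors
  (the two end-atom reference blocks plus bond order/length, width 46;
  center + flank blocks plus the angle, width 67). Equilibrium values
  $r_0$ and $\theta_0$ are never predicted: they are read off the input
  geometry. Dihedral barriers $K_\phi$ are not learned either — they come
  from the parameter table keyed by the central-bond type pair, with the
  classifier heads supplying only $\gamma$ and $n$. This is the
  minimal-assumption split between learned and tabulated quantities.

All train/validation splits are stratified **by molecule** (20% of
molecules held out; 5-fold cross-validation folds likewise
molecule-level). Atoms of one molecule are near-duplicates of each other,
so an atom-level split would leak and inflate every score.

## Synthetic labels: what they are and are not

Real training labels for charges are quantum-chemical ESP fits, which
cannot be recomputed on a desktop for thousands of molecules. The package
therefore ships a deterministic label oracle for every head, making the
entire pipeline trainable and testable offline:

* **Charges** — electronegativity equalization (EEM): minimize
  $\sum_i (\chi_i q_i + \eta_i q_i^2) + \sum_{i<j} J_{ij} q_i q_j$ subject
  to $\sum q_i = Q$, a linear solve. $\chi$/$\eta$ are Pearson
  electronegativity/hardness values (eV); $J_{ij} = 14.4/\sqrt{r_{ij}^2 +
  d^2}$ eV with damping $d = 2$ Å couples the solution to the 3D geometry
  so charges depend on the neighborhood, not just the element. EEM has the
  qualitative behavior the descriptors must capture (density flows to
  electronegative atoms, attenuating with distance) but its values are
  **not** DFT/ESP charges, and recovery scores against it say nothing
  about accuracy versus quantum references.
* **Atom types** — an ordered, first-match-wins GAFF-style rule set over
  the perceived environment (carbonyl `c`, aromatic `ca`, sp3 `c3`,
  hydrogen subtypes by the parent's electron-withdrawing neighbor count,
  etc.). Within the mutually confusable aromatic/conjugated sp2 pairs
  (cc/cd, ce/cf, cp/cq) the rules always emit the first member; both
  members share Lennard-Jones parameters, so Lennard-Jones assignment is
  unaffected, and evaluation treats within-pair differences as equivalent.
* **Torsions** — a convention table on the central bond: sp2–sp2 or
  aromatic bonds get (180°, n = 2) to preserve planarity, sp3–sp3 get
  (0°, n = 3), sp2–sp3 mixes (0°, n = 2), and bonds at an sp center
  (0°, n = 1).
* **Force constants** — a lookup of GAFF-like magnitudes keyed by element
  pair and bond-order class (bonds) or center element/hybridization and
  hydrogen-flank count (angles).

## The fixture generator

`fixture_molecules()` builds a deterministic library: some fifty named
molecules chosen to span the functional groups of interest — alkanes and
rings, aromatics (including the fused-ring case naphthalene), alcohols
(including the aliphatic stress case 1-octanol), amines, amides, thiols,
sulfoxide/sulfone, a phosphine oxide, nitriles, nitro compounds, halides,
aldehydes/ketones/acids, and two ions — plus `n_generated` randomly
decorated chain/ring skeletons (seeded; substituents drawn from thirteen
groups). Defaults used by the test suite and the acceptance script: 450
generated molecules on top of the named set (505 total, ~8,700 atoms),
mirroring at desk scale the role of the large training corpus a production
run would use.

Geometries are idealized templates, not embeddings: reference bond
lengths, canonical valence angles (109.47°/120°/180°), staggered chains,
regular polygons for single rings, and an explicit two-hexagon template
for naphthalene. This is deterministic and dependency-free, and it is also
a known limitation: conformational diversity, strained geometries, and
crystal-quality bond lengths are absent, so passing tests demonstrate
pipeline correctness and label recovery, not performance on experimental
structures. For the same reason multi-fragment inputs are rejected rather
than trimmed, and the generic builder refuses multi-ring systems it cannot
lay out honestly.

## Numerical choices and degenerate inputs

* Coordinates are Ångström internally; conversion to nm (and kcal→kJ,
  K→k/2) happens only in the GROMACS writer, and the validating reader
  inverts it, so a write/read/re-write cycle is bit-identical.
* Aromaticity is a Hückel-style rule on 5/6-rings (every member
  π-capable, 4n+2 electron count); hybridization follows bond orders.
  The descriptor's "axial" flag is undecidable without conformer
  analysis and is always `FALSE`; chirality is a cheap
  four-distinct-element heuristic, not CIP.
* Hydrogen-bond donors are N/O/S bearing hydrogen; acceptors are N/O with
  an available lone pair. These are stand-in definitions, pinned by tests.
* 1–4 pairs are the first/fourth atoms of torsions filtered to graph
  distance exactly 3, which removes the ring artifacts (in cyclopentane
  every formal 1–4 ring pair is also 1–2 or 1–3 the short way around).
* Impropers: one per three-coordinate sp2 carbon, center third, fixed
  (180°, n = 2), barrier 10.5 kcal/mol at carbonyl-like centers and 1.1
  otherwise (GAFF practice).
* BAR solves the acceptance-ratio balance by monotone bracketing to 1e-8
  kcal/mol — the balance is strictly increasing in ΔG, so the root is
  unique whenever the work distributions overlap; underflow of all Fermi
  weights is detected and reported as insufficient overlap. The standard
  error is the asymptotic variance evaluated at the solution (the
  uncertainty recipe is our choice; per-window error estimation is not
  otherwise specified by the protocol). β defaults to 298 K in
  kcal/mol units. The default decoupling schedule is 5 uniform Coulomb
  states (Δλ = 0.25) followed by 15 non-uniform van der Waals states —
  20 windows.
* EEM degeneracy (singular system) and missing element parameters are
  hard errors, as are unparameterizable atom types at Lennard-Jones
  lookup.

## What the tests show

The suite checks every layer against independent oracles written in the
test files: breadth-first shell distances, brute-force internal-coordinate
enumeration, a scalar per-term energy loop, a bisection BAR solver, and
hand-solved EEM closed forms. The acceptance-scale run (505 fixtures, seed
7) recovers the EEM oracle with held-out R² ≈ 0.99 and the typing rules
with held-out accuracy ≈ 0.99, with residual errors concentrated in
hydrogen subtypes and conjugated-carbon pairs — the same confusion
structure expected of the approach at production scale. Quantities that
require the quantum training corpus or explicit-solvent simulation
(per-element accuracy against DFT charges, experimental solvation
free-energy agreement, protein–ligand trajectories) are out of scope and
no test claims them.
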