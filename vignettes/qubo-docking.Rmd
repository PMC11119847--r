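---
title: "Fragment-based docking as a QUBO: model, parameters and design choices"
author: "quboDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based docking as a QUBO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quboDock)
```

## The model

Flexible docking of a drug-like compound is reduced to a discrete
selection problem. The compound is decomposed into rigid fragments
$f_1, \dots, f_K$ (substructures with no internal rotatable bond, each cut
valence capped with a hydrogen). Independent rigid docking of each
fragment produces candidate placements $p_i$, each carrying a
binding-free-energy score $\Delta G_i$ (kcal/mol) against the target
protein. One binary variable $x_i \in \{0, 1\}$ decides whether placement
$p_i$ is part of the reconstructed pose, and the objective is

$$H = A H_1 + B H_2 + C H_3 + D H_4$$

* $H_1 = \sum_i \Delta G_i x_i$ — the compound score is the sum of its
  selected fragment scores (the additivity assumption of fragment-based
  docking);
* $H_2 = \sum_{i<j} \mathrm{clash}(i,j)\, x_i x_j$ with
  $\mathrm{clash} \in \{0,1\}$ — co-selected placements must not collide;
* $H_3 = \sum_{i<j} \mathrm{conn}(i,j)\, x_i x_j$ with
  $\mathrm{conn} \in \{-1,0\}$ — a reward when two placements of
  covalently bonded fragments sit so that the bond can actually form;
* $H_4 = \tfrac12 \sum_k \bigl(\sum_{i \in S_k} x_i - 1\bigr)^2
  + \tfrac12 \sum_i x_i (1 - x_i)$ — exactly one placement per fragment
  group $S_k$. For binary $x$ the second sum vanishes identically; it is
  kept in the direct evaluator for fidelity to the constraint's written
  form (it matters only to continuous-relaxation solvers), and it
  contributes nothing to the QUBO coefficients.

The assumptions worth keeping in mind: fragment scores are additive and
protein-mediated placement–placement interactions beyond sterics are
ignored; fragments are rigid, so ring conformers and bond-length/angle
relaxation enter only through the binarized pair terms; and the protein
appears exclusively through the $\Delta G_i$ scores.

## Pairwise terms and their binarization

For a placement pair the package computes, with the UFF force field
(via OpenBabel):

* $E_{NB}$: the energy of the two capped fragments as one system with no
  added bond, minus each fragment's internal energy at the same
  coordinates;
* $E_B$ (bonded fragment pairs only): the energy of the merged molecule —
  the two cap hydrogens at the attachment removed and the covalent bond
  added, coordinates frozen — minus the same two internal energies. It
  contains the bond-stretch, angle and dihedral distortion created by the
  merge plus the intramolecular non-bonded terms.

Binarization applies two rules in order, against the tolerance
`thE` (default **500 kcal/mol**): `conn = -1` iff the fragments are bonded
and $E_B \le thE$; then `clash = 1` iff `conn = 0` and $E_{NB} > thE$.
The tolerance is deliberately loose: placements come from a finite grid,
so near-bonding geometries are always somewhat distorted, and the
threshold must forgive tens to hundreds of kcal/mol of strain while still
rejecting outright atomic overlap. The two indicators are mutually
exclusive by construction (`clash * conn = 0`).

Two design choices here were genuinely open:

* **The energy zero.** The raw force-field energy of a two-fragment
  system includes each fragment's internal strain, which is irrelevant to
  the pair decision. Both $E_{NB}$ and $E_B$ therefore subtract the
  isolated-fragment energies at identical coordinates, making them pure
  interaction/distortion energies with an exact distant-pair limit of 0.
  This also reconciles the "full merged molecule" and "inter-fragment
  only" readings of $E_B$: they differ by constant internal terms that
  cancel in the subtraction.
* **Engine.** UFF as implemented in OpenBabel. Absolute UFF energies
  differ by a few kcal/mol between implementations (torsion and
  out-of-plane conventions); with a 500 kcal/mol tolerance these
  differences never flip an indicator in practice. One `obenergy` process
  is run per system: OpenBabel's force-field state is not reliably reset
  between records of a multi-molecule file, which we found to contaminate
  batched energies.

A distance **prefilter** (default cutoff 8 Å) decides far-apart pairs as
`(0, 0)` without any force-field call, and fixes `conn = 0` for bonded
pairs whose attachment atoms are too far to bond (> 3 Å). A fully
**geometric mode** replaces energies with distances: `conn = -1` iff the
attachment atoms lie inside a bond window (default **[1.2, 2.0] Å**),
else `clash = 1` iff the minimum heavy-atom distance falls below a clash
distance (default **2.0 Å**). The window brackets typical single-bond
lengths (C–C 1.54 Å) with room for grid distortion; 2.0 Å is just below
the sum of van-der-Waals radii of two carbons, i.e. a genuine collision.

## Decomposition rule

The cut rule had to be reconstructed, since "cut at rotatable bonds"
underdetermines what happens to single-atom linkers (a methylene between
two rings would be isolated by cutting both of its bonds). The package
marks as candidates all single, non-ring bonds whose two heavy end atoms
each have at least two heavy neighbours, then cuts them **greedily** in a
fixed priority order — bonds with fewer ring-member ends first, then
bonds with a heteroatom end, then input order — skipping any cut whose
end has already dropped below two heavy neighbours. The effect is that a
linker CH~2~ keeps exactly one of its bonds, preferentially the one to a
ring carbon: a CF~3~ group caps to `FC(F)F`, a carboxyl to `OC=O`, an
N–CH~2~–heteroaryl linker stays with the heteroaryl ring as a methyl, and
n-hexane splits into three ethanes. Every resulting fragment is rigid
(decomposing it again returns it unchanged), the fragments partition the
parent's heavy atoms, and re-joining them at the recorded attachment
records restores the parent graph — all three properties are enforced by
tests. Canonical SMILES of the capped fragment (OpenBabel) is the
fragment identity key, which is what makes fragment reuse across a
library meaningful.

## Placement management

The docking box (default geometry: a cube, e.g. 14 Å edge) is tiled by
cubic subregions (default **2 Å** cells, half-open intervals anchored at
the box corner, so each point belongs to exactly one cell; a 14 Å box
gives $7^3 = 343$ subregions). Ingested poses keep only negative scores
(threshold 0 kcal/mol), are assigned to the subregion containing their
heavy-atom centroid, and are capped per fragment per subregion at the 20
best. Cross-subregion near-duplicates are removed by best-score-first
greedy clustering on identity-mapping heavy-atom RMSD (default threshold
**1.0 Å**): survivors are pairwise at least the threshold apart and each
cluster keeps its best score, so the global best placement of a fragment
always survives and the filter is idempotent.

## QUBO assembly and evaluation

With $x_i^2 = x_i$, the constraint term expands per fragment group to
$-D/2$ on each linear coefficient, $+D$ on each in-group pair and $+D/2$
on a constant offset. The offset is tracked explicitly so that reported
energies are the Hamiltonian's, not a shifted QUBO value; for the
all-zero selection $H = D\,K/2$ exactly. Pairwise sums run over unordered
pairs $i<j$ with a single contribution per pair (any double-counting
convention is absorbable into $B$ and $C$). Two independent evaluation
routes — the reduced coefficient form and the direct term-by-term sums —
are both exported, and their agreement to $10^{-9}$ relative tolerance on
random instances is a standing test. Default weights
$(A,B,C,D) = (1, 5, 5, 25)$: the two pairwise terms share a scale, and
the constraint weight dominates any realizable score sum so that
constraint-violating minima are never competitive.

## Solvers

`bruteForce()` enumerates all $2^n$ selections with an incremental
Gray-code walk (refusing $n > 25$ by default) and is the exact oracle.
`simulatedAnneal()` runs independent restarts of single-bit-flip
Metropolis annealing with a geometric schedule; the initial temperature
is an upper bound on any single-flip $|\Delta H|$
($\max_i |h_i| + \sum_j |J_{ij}|$), the final temperature is $10^{-3}$ of
it, and each restart ends in a zero-temperature quench, so every recorded
state is a local minimum. The pool keeps distinct vectors sorted by $H$
(ties broken lexicographically); all randomness flows through R's RNG, so
a seed fixes the pool exactly, and because restarts are sequential on one
stream, enlarging the restart budget replays the shorter run first —
the best found $H$ is monotone in the budget. A hardware or vendor
annealer can be substituted by exporting the instance
(`exportQUBO()`: lossless JSON, qbsolv-style text, dense matrix) and
re-importing its solutions. The validity filter then keeps the solutions
selecting exactly one placement per fragment; with a quench in place the
retained fraction is typically near 1, higher than reported for
quench-free annealers.

## Reconstruction and RMSD

A valid solution is assembled by concatenating the selected placements,
deleting the two cap hydrogens at every inter-fragment bond and adding
the bond — coordinates are *not* moved, so the assembled pose retains the
grid distortion; removal of that distortion is delegated to
`minimizePose()` (OpenBabel steepest descent, UFF). Redocking RMSD is
computed over heavy atoms **without superposition** (both poses live in
the protein frame) and is by default minimized over graph automorphisms
consistent with elements and bond orders, so chemically equivalent atoms
(CF~3~ fluorines, benzene rotations) do not inflate it; ring bonds share
one edge colour so that the two Kekulé structures of an aromatic ring
compare equal. The conventional acceptability bound for a redocked pose
is 2.5 Å.

`minimizePose()` is ligand-only: no installed R-stack force field
accepts a rigid protein environment, so the relaxation removes internal
strain but cannot re-optimize protein contacts. This is the package's
main deliberate simplification; the protein enters the method only
through the $\Delta G_i$ scores.

## The synthetic generator

`generateInstance()` stands in for the external fragment-docking engine
so every downstream stage is testable. It builds an ideal all-anti
alkane of $K$ ethane units (C–C 1.526 Å, C–C–C 112°, C–H 1.09 Å),
decomposes it into $K$ rigid fragments, and plants the native fragment
poses as one placement each — chain attachment distances sit at the bond
length, inside the bond window, and the planted selection is verified to
be valid, clash-free and fully connected ($H_4 = 0$, $H_2 = 0$,
$H_3 = -(K-1)$). Decoys are random rigid transforms (uniform rotations,
Gaussian translations of scale 3 Å by default), optionally relocated on
top of another fragment's planted pose to guarantee clashes. Scores are
negative-truncated Gaussians: planted $\mathcal N(-6, 0.5)$, decoys
$\mathcal N(-2, 1.0)$ kcal/mol — favorable and mediocre candidates
coexist, as in real fragment docking where low-interaction linker
placements must survive enumeration. Defaults $K = 4$, $m = 5$ mirror a
small four-fragment redocking case.

What the generator does **not** emulate: a real pocket's shape and score
field (scores are drawn, not computed from a protein), fragment diversity
(all fragments are ethane; the chemistry path is exercised separately on
real molecules), tautomer/ionization states, and the empirical score
distributions of any particular docking engine. Passing tests on planted
instances therefore demonstrate the correctness of the formulation and
solver machinery, not docking accuracy on real targets.

## Numerical choices and degenerate inputs

* SDF coordinates are written at the format's standard 4-decimal
  precision (0.1 mÅ), which bounds all file round-trip errors.
* Compounds with no cuttable bond decompose to a single fragment; an
  empty placement set yields an $n = 0$ QUBO whose single empty solution
  has $H$ equal to the offset; a fragment with no surviving placement
  keeps its constant $D/2$ in the offset (the instance is then
  infeasible, visibly: no solution reaches $H_4 = 0$).
* Solution ties are broken lexicographically for deterministic output.
* Score ties in deduplication are broken by insertion order
  (stable sort).

## Problem sizes

The test suite and the acceptance script run on instances of 2–5
fragments with 2–6 placements each (up to 24 variables), 50-instance
solver comparisons against the exact oracle, 20-seed recovery sweeps,
and a 400-restart annealing pool for the funnel analysis — sizes chosen
so the whole suite completes in well under a minute of solver time while
still exercising every code path, including the force-field route on
real fragment chemistry.
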