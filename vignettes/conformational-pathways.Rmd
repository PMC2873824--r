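---
title: "Planning conformational transition pathways with confpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning conformational transition pathways with confpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confpath)
```

## The problem and the model

Given two conformations of one protein — a *start* and a *goal* — confpath
searches for sequences of backbone dihedral rotations that carry the start
to within a tolerance of the goal while keeping every intermediate below an
energy ceiling. The method rests on two assumptions worth stating up front:

* secondary-structure elements do not melt or rearrange internally during
  the transition, so they can be treated as rigid bodies; and
* the flexibility lives in the loops connecting them, so a small set of
  phi/psi dihedrals near the element junctions suffices to describe the
  motion.

Both are good approximations for hinge- and shear-type domain motions;
they fail for transitions involving partial unfolding, which is outside
this package's scope.

The representation is deliberately coarse: backbone N, CA, C, O plus
C-beta (glycine has none; a missing C-beta is rebuilt at the ideal
tetrahedral position, 1.53 Å from CA with L-chirality). Elements come from
PDB HELIX/SHEET headers when available, otherwise from a dihedral
heuristic (>= 4 consecutive residues with phi in [-100°, -30°] and psi in
[-80°, -5°] are a helix; >= 3 consecutive residues in the extended region,
phi in [-180°, -90°] and psi in [90°, 180°], are a sheet). Loop residues
join the element whose end is nearest in sequence; an equidistant residue
joins the preceding element, a fixed tie-break chosen purely for
determinism. Elements known not to move relative to one another can be
merged via `merge_groups` to shrink the search space.

The element graph connects sequence-adjacent elements (never across a
chain break — an articulation through a physical gap is meaningless). Its
spanning tree is rooted at the element with the smallest per-element CA
RMSD after a whole-chain superposition of start onto goal, i.e. the part
expected to move least; ties resolve to the lowest element id after
rounding the RMSDs at 1e-6 Å so that exactly-identical elements tie
cleanly. The tree is grown breadth-first, visiting neighbours in
increasing id order — the graph construction is what matters physically;
the visit order is fixed only so that results are reproducible.

## Kinematics

Each tree edge contributes the phi/psi angles of its two junction residues
plus `window - 1` sequential neighbours on each side (default `window = 2`,
eight DOFs per junction). How many neighbours to include is genuinely open;
it is exposed as a parameter rather than hard-coded. Rotating a DOF moves
the entire distal subtree rigidly about the bond axis (N–CA for phi, CA–C
for psi); the junction-window residues between the bond and the subtree
deform with it, which is exactly the loop flexibility the model intends.
A consequence worth knowing: rigidity guarantees apply to the *cores* of
elements, not to the few loop residues inside the DOF windows.

Coordinates are recomputed eagerly from the rotation on each move, so a
conformation's coordinates are a deterministic function of its DOF offsets
alone — applying a conformation's recorded offsets to the start state in
any order reproduces it to floating-point accuracy, because each rotation
changes exactly one internal coordinate.

## The distance metric

Per mobile element *i* the score is the sum over other mobile elements *j*
of `w_angle * |alpha_ij - alpha*_ij| + w_dist * |d_ij - d*_ij|`, with
starred values measured in the goal. Helix axes are principal axes of the
element's CA set, oriented N- to C-terminal; sheet (and merged) elements
use the least-squares plane normal, whose sign is arbitrary, so angles
against them are folded into [0°, 90°]. Distances are between element
centers of mass over all retained atoms.

Two choices here were made under ambiguity and are isolated behind
`metric_params`:

* the functional form uses absolute differences (a squared-difference
  variant is available via `form = "squared"`); the absolute form is the
  simplest that satisfies the defining properties — zero exactly at the
  goal geometry, and the norm of the feature vector acting as the distance
  to the goal;
* the weight 5 multiplies the *angle* term and 1 the *distance* term:
  angle differences are bounded by pi radians while domain-scale distance
  changes are several Angstrom, so 5·radians and Angstrom are the same
  order of magnitude — the opposite assignment would not be.

The resulting conformation distance is a *pseudometric*: it is invariant
under any global rigid transform and under any internal motion that
preserves all mobile pair geometries, so zero distance does not imply
identical coordinates. With few mobile elements this slack is visible —
on the two-element toy below, the planner drives the normalized metric
distance to 0.1 while the Cartesian lRMSD to the goal stays near 1 Å,
because a 2-dimensional feature vector pins only the hinge geometry. With
realistic mobile sets (tens of pair terms) the metric is much tighter.
Angles are radians internally; degrees appear only at interfaces.

## The energy function and its gates

The six-term potential is a concrete, fully parameterized implementation
(every constant lives in `energy_params` and can be overridden):

* **soft vdW** — 12-6 Lennard-Jones over atom pairs at least 3 residues
  apart, with AMBER-style per-class parameters, each pair capped at
  `vdw_cap` (10 kcal/mol). Below the cap-crossing radius the curve is
  continued flat, so even a fully clashed conformation has finite energy
  and the gradient vanishes inside the clash region rather than exploding.
* **hydrogen bonds** — backbone N(i)...O(j) pairs, |i-j| >= 3, rewarded by
  `-hb_epsilon` inside 2.6-3.4 Å with a cosine switch over 0.4 Å.
* **burial** — C-beta contact counts within 8 Å, weighted by a
  hydropathy-proportional per-residue scale (hydrophobic burial is
  favourable).
* **water shell** — pairs of C-beta atoms held at solvent-separated
  distances (6.5-9.5 Å) pay a penalty proportional to the product of their
  hydropathies, disfavouring hydrophobic residues parked at water-bridged
  separation.
* **bond + angle** — harmonic terms with AMBER ff03 backbone constants
  (shipped as a small CSV), evaluated over the junction-window residues
  only: dihedral moves never deform any other bonds or angles, so those
  terms would be additive constants.

The search uses energies only through the gate: a move is rejected when
the conformation exceeds the *global start* energy by more than
50 kcal/mol (relative to the global start rather than each cycle's start —
the ceiling should not ratchet upward across cycles; this is configurable).
At or above +100 kcal/mol, 20 steepest-descent steps over bond, angle and
soft-vdW terms of the moved elements are applied before re-gating. The
descent uses backtracking from a step scale of 0.01 Å per unit gradient,
halving until the objective does not increase, so the repair objective is
non-increasing by construction; the step scale is a numerical choice, not a
physical one.

## The PDST search

The planner keeps a tree of pathway *segments*; the root is a pathway of
length zero holding the start. Each iteration:

1. **selects** a segment — deterministically, the one minimizing
   priority / cell-volume (ties to the lowest id), where cells come from a
   binary subdivision of the feature-vector projection of all stored
   conformations; in a random 10% of iterations the choice is instead
   uniform over the 10 segments ending nearest the goal (goal biasing);
2. **propagates** — from a uniformly random conformation on the segment, a
   uniformly random DOF is stepped in 2° increments (random sign) until
   the energy gate fires or 20 steps are taken; the accepted prefix
   becomes a new segment;
3. **subdivides** the selected segment's cell at the midpoint of a
   round-robin dimension; segments whose projections span the new boundary
   are split into chained pieces, so no sample ever spans two cells and
   path replay stays intact.

The selected segment's priority is updated to `2p + 1` and new segments
take their creation iteration as priority: the canonical scheme that
favours samples in large, sparsely covered cells and guarantees every
segment is selected eventually. The root projection box is the bounding
box of the start's feature vector and the origin, inflated twofold, and is
grown lazily (stretching the boundary cells) if a projection escapes it.

The planner runs in cycles: each cycle re-seeds a fresh tree from the best
conformation found so far and ends early once some conformation is closer
to the goal than 0.85 of the *cycle-start* distance (configurable; the
threshold is read relative to the cycle's own start, which is what makes
restarting meaningful). The search succeeds when the normalized distance
reaches `tau`. Per-system thresholds in the literature for this family of
benchmarks range from 0.08 to 0.18; the toy problems here use 0.2. Note an
arithmetic consequence: with only 3 cycles and a 0.85 cycle threshold the
best reachable normalized distance is 0.61, so deep convergence requires
either long cycles that overshoot the cycle threshold within one
propagation, or (as in the tests here) many short cycles under one total
iteration budget.

All randomness flows from one seed through a single stream with a fixed
draw order (bias coin, pool choice, conformation index, DOF, sign), so a
`planner_config` seed fixes the entire run.

The random-walk comparator shares the move generator and the gate but
selects moves by the Metropolis criterion on the similarity score:
improvements always accepted, worsening moves with probability
`exp(dS / T)` where `dS` is the (negative) improvement. The sign
convention — improvement positive — and the explicit temperature (default
1 score unit) pin down what "proportional to e^dS" means; `T -> 0` gives
pure greedy descent.

## Symmetric complexes

Rings with exact C_n symmetry are represented by one monomer plus the
group of n rotations about the ring axis. Replication is exact by
construction, so a monomer move re-replicated stays exactly symmetric.
Distant subunits of a ring do not interact: metric and energy cross terms
are restricted to adjacent units, with non-adjacent interactions exactly
zero rather than down-weighted. Symmetry is also the efficiency lever —
intra-unit terms are computed once and multiplied by n, and one
representative adjacent pair stands for all n of them. The ring axis must
be supplied (or estimated from a deposited assembly); nothing in a single
monomer determines it.

## Pathway analysis

* `lrmsd` — CA-only least RMSD via Kabsch superposition restricted to
  proper rotations (a mirror image has nonzero lrmsd). Residues are paired
  by index after trimming to the common set.
* `delta_d_rmsd` — `lrmsd(C, open) - lrmsd(C, closed)`, the standard
  open/closed progress coordinate.
* `theta_angle` — the angle at the hinge center of mass between the two
  domain centers of mass; computed over all retained atoms by default with
  a CA-only mode, since the literature values it is compared against do
  not state which convention their centers of mass used.
* `pmf_profile` — pathway samples are decimated to at least one metric
  distance unit apart along each pathway (decorrelation), binned, and each
  bin scored `-ln(count/total)`. This is a raw binned-density profile, not
  a reweighted free energy: the samples carry no umbrella biases that a
  WHAM-style estimator could unweight, so plain density is the faithful
  desk-scale analogue. Empty bins are masked as `NA`, never `-ln(0)`.
* `compare_paths` — per-conformation nearest-neighbour lrmsd of one path
  against a reference path, with max/mean/endpoint summaries.

## The synthetic generator, and what the tests do not show

`make_toy_transition` builds ideal poly-alanine helices (12 residues,
phi = -57°, psi = -47°) joined by 4-residue extended loops (phi = -120°,
psi = 130°), and creates the goal by applying known hinge rotations at the
junction psi angles. The goal therefore lies *exactly* in the planner's
move space: a failed search indicts the planner or metric, never the
representation. Goals that collapse sterically (any interatomic distance
under 1 Å) are rejected and re-jittered, with an error after 10 attempts.
The generator passes its secondary-structure annotation explicitly (the
ranges are known at construction) rather than through the dihedral
heuristic — the extended loops match the heuristic's sheet rule and would
otherwise become spurious rigid elements.

What the fixtures do not emulate: real loop torsional preferences,
side-chain packing, sequence diversity (everything is alanine), chain
breaks, and the high-dimensional mobile sets of real domain motions.
Passing tests demonstrate the machinery — kinematic exactness, metric
properties, gate soundness, planner bookkeeping and the planner-vs-walk
ordering — on landscapes far smoother than a real protein's; they do not
certify accuracy on deposited structures, which is exercised separately by
checks that download reference PDB entries.

Problem sizes used by the test suite were chosen as the smallest that
still discriminate: 28-residue two-element toys for unit properties, a
40-residue three-element fixture for disjoint-subtree kinematics, 20
seeded planner runs with a 2000-iteration budget for the end-to-end
comparison, and order-3 rings for brute-force symmetry cross-checks
(order 7 for replication exactness).

## Known limitations

* No loop closure: cyclic chains and internally constrained loops are
  unsupported; bond lengths/angles are never DOFs.
* The metric degenerates for |K| < 2 (scores are identically zero) and is
  slack for small mobile sets, as discussed above.
* Energy terms are a parameterized coarse model; absolute values are not
  comparable to all-atom force fields, only differences within a run are
  meaningful to the gate.
* No pathway clustering or ensemble post-processing; single pathways are
  hypotheses, not mechanisms.
* Secondary-structure melting is out of scope by assumption.
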