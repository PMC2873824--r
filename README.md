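# confpath

Tracing large-scale conformational transitions in proteins with a
robotics-inspired, sampling-based planner.

Many proteins work by moving between conformational states — a ligand-binding
domain closing over its substrate, a chaperonin ring opening to receive a
client. The intermediate states are rarely observable, and brute-force
simulation of the transition is expensive. `confpath` targets users who have
*two* structures of the same molecule (a start and a goal state) and want
plausible low-energy pathways between them, at coarse resolution, in minutes
rather than GPU-days.

## The model

The molecule is reduced to its backbone plus C-beta atoms (glycine keeps only
its backbone). Residues are grouped into secondary-structure elements
(from PDB headers or a dihedral heuristic), each treated as a rigid body;
loop residues attach to the nearest element. The elements form a graph
`G = (V, E)` with an edge wherever two elements are sequence-adjacent; a
spanning tree rooted at the least-moving element (smallest per-element CA
RMSD after superposing start onto goal) orients the kinematics, and the
phi/psi dihedrals in a small window around each inter-element junction are
the degrees of freedom. Rotating a DOF moves the distal subtree rigidly.

**Distance.** For a mobile element *i*, the score against the goal is

    s_i = sum_{j in K, j != i} [ w' |alpha_ij - alpha*_ij| + w |d_ij - d*_ij| ]

where `alpha_ij` is the angle between the element axes (least-squares line
for a helix, plane normal for a sheet), `d_ij` the distance between element
centers of mass, starred quantities their goal values, and `K` the mobile
set (weights: `w' = 5` per radian, `w = 1` per Angstrom). The feature vector
`F(C) = (s_1, ..., s_|K|)` vanishes exactly at the goal geometry; the
distance between conformations is `||F(C1) - F(C2)||`, and `||F(C)||` is the
distance to the goal. Distances reported as *normalized* are on a 0-1 scale
where the start is at 1.

**Energy.** A coarse-grained potential

    E = E_soft-vdW + E_HB + E_burial + E_water + E_bond + E_angle

(capped 12-6 repulsion, backbone N...O hydrogen bonds, hydropathy-weighted
C-beta burial, a solvent-shell pair term, AMBER-style harmonic bond/angle
terms over the flexible loop windows) gates the search: conformations more
than 50 kcal/mol above the start energy are rejected, and those at or above
+100 kcal/mol first get 20 steps of steepest-descent repair over the bond,
angle and van der Waals terms of the moved elements.

**Search.** A Path-Directed Subdivision Tree (PDST) planner grows a tree of
pathway segments. Each iteration deterministically selects the segment
minimizing priority / cell-volume over a binary subdivision of the projected
feature space (goal-biased in 10% of iterations), propagates a random DOF
rotation from a random conformation on it until the energy gate fires, and
subdivides the selected cell. Cycles restart the tree from the best
conformation so far. A Metropolis random-walk baseline (`run_random_walk`)
optimizes the same similarity score under the same gate, accepting worsening
moves with probability `exp(dS/T)`.

## Worked example

```r
library(confpath)

# a synthetic transition: two ideal helices, one 30-degree hinge
toy <- make_toy_transition(n_elements = 2, hinge_deltas = 30, seed = 1)
toy$topology
#> pathway_topology: 28 residues, 2 rigid elements (root 1), |K| = 2, 8 DOFs

lrmsd(toy$start, toy$goal)
#> [1] 1.150626

cfg <- planner_config(iterations_per_cycle = 100, cycles = 20,
                      tau = 0.2, seed = 42)
res <- run_pdst(toy$start, toy$goal, config = cfg)
res
#> planner_result: success, best normalized distance 0.1017, 3 cycle(s), path length 49
```

The planner reached a conformation whose inter-element geometry is within
10% of the start-goal separation (`tau = 0.2` declares success at 20%),
after 3 restart cycles; `res$path` holds the 49 intermediate conformations
of the winning pathway, replayable move-by-move from the start state and all
within 50 kcal/mol of the start energy. Write and analyze it:

```r
write_pathway(res$path, "toy_path.pdb")
vals <- vapply(res$path, delta_d_rmsd, 0, open = toy$start,
               closed = toy$goal)
head(pmf_profile(vals, bins = 8), 3)
```

For real structures, `load_structure()` two PDB files, `build_topology()`
(optionally with HELIX/SHEET headers, merged rigid groups and a restricted
mobile set), then `run_pdst()` as above. `inst/cli/confpath` wraps the same
functions as `plan`, `walk`, `analyze` and `make-fixture` subcommands for
shell use. Ring complexes with exact cyclic symmetry are supported through
`symmetry_group()`, `build_complex()`, `complex_energy()` and
`symmetric_feature_vector()`, which restrict cross terms to adjacent
subunits.

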