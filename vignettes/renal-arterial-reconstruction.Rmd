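---
title: "Hybrid reconstruction of renal arterial networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid reconstruction of renal arterial networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the tree model and its assumptions, the cost function and the optimizer,
the image priors, what the synthetic phantom does and does not emulate,
and the numerical and design choices made where the method leaves freedom.

## The tree model and its assumptions

A vascular tree is a rooted directed acyclic graph: nodes are points in
3-D space (μm), each edge a straight cylindrical vessel carrying a radius
(μm) and a volumetric flow (μm³/s). Five modeling assumptions carry the
whole construction:

1. vessels are straight cylinders — constant radius, no curvature —
   between branch points; length is therefore always *derived* from the
   end-node positions and never stored (no stale state across moves);
2. all terminal arteries end in the renal cortex, their perfusion
   territory;
3. blood is incompressible and Newtonian, flow is laminar, so
   Hagen–Poiseuille resistance applies per vessel;
4. pressure losses at branch points are negligible;
5. flow is distributed equally over the terminal vessels.

Under these, flows follow Kirchhoff's zero-addition rule bottom-up from
Q_t = Q₀/N at the terminals, radii follow Murray's cube law
r_parent³ = Σ r_child³ bottom-up from the terminal radii, and the node
pressures follow a single root-to-leaf sweep of Poiseuille drops
Δp = 8 μ l Q / (π r⁴). Radii are *never* optimization variables: relaxing
the cube law into the cost function produces abrupt radius jumps at
branch points and degrades the order structure of the result, so the cube
law is kept as a hard constraint re-imposed after every topology change.

## Units

Everything internal is micrometre / second / Newton. The constants are
quoted in the units the physiology literature uses and converted exactly
once (`flow_ml_min_to_um3_s()` and friends):

| parameter | default | internal units | meaning |
|---|---|---|---|
| `w_c` | 5×10⁻⁸ | N μm⁻² s⁻¹ | material (blood-volume maintenance) weight; 5×10⁴ J s⁻¹ m⁻³ |
| `w_p` | 1 | — | power (viscous dissipation) weight |
| `mu` | 3.6×10⁻¹⁵ | N s μm⁻² | blood viscosity, 3.6 mPa s |
| `Q0` | 1.1667×10¹¹ | μm³ s⁻¹ | inlet flow, 7 ml/min |
| `p0` | 100 | mmHg | inlet pressure |
| `leaf_radius_mean/sd` | 10.08 / 0.14 | μm | afferent-arteriole radius distribution |

With these units the material and power terms of the cost sit on the same
scale (both in N μm s⁻¹, i.e. μW), which is what makes `w_p = 1`
meaningful. One conversion constant, 1 mmHg = 1.33322×10⁻¹⁰ N μm⁻²,
is used for all pressure reporting.

At desk scale the package keeps the *per-terminal* flow physiological
rather than the organ total: a phantom run with N terminals uses
Q₀ = N × 3.89×10⁶ μm³/s, so every terminal carries the real
afferent-arteriole flow of ≈3.9 nl/s. Splitting the full 7 ml/min over a
few hundred terminals would push two orders of magnitude too much flow
through 10-μm vessels and produce meaninglessly large pressure drops.

## Image priors

**Cortex shell.** The cortex is not directly visible in a typical
whole-kidney micro-CT, but terminal arteries end within a roughly
constant-thickness outer shell, so it is approximated as all foreground
voxels within R₁ = 2 mm of the organ surface (2 mm is a typical cortex
thickness for a 12–18-week rat) minus a ball of R₂ = 5.65 mm around the
root position, which excises the hilar region where no afferent
arterioles belong. Erosion is computed from an exact Euclidean distance
transform (separable lower-envelope algorithm, compiled code): a voxel
survives erosion by the ball of radius R₁ iff its distance to background
exceeds R₁. With isotropic voxels this is exact up to rasterization.

**Voxel convention.** Indices are 0-based with the *corner* of voxel
(0,0,0) at the mask origin: world = origin + index · voxel_size. Geometric
predicates (the hilar ball, phantom shapes) evaluate voxel centers. This
one convention is used by every reader, writer and sampler.

**Large-artery tree.** A skeletonization of a coarse vessel segmentation
arrives as an undirected graph with per-node radii (from the distance
transform of the segmentation) and may contain cycles and noise spurs.
The preprocessing chain is: (i) per-component maximum-total-radius
spanning tree (edge weight = −radius), which removes exactly the thinnest
edge of every cycle — spurious connections are thin; (ii) orientation
away from the root, keeping only the root's component; (iii) collapse of
degree-2 chain nodes into single straight vessels (chain radius: the
length-weighted mean of the constituent radii, which preserves the
distance-transform information; the straight-line length understates the
polyline length, negligibly at reasonable curvature); (iv) degree pruning
— a node keeps at most its 4 children with the geometrically deepest
subtrees, because branching into more than four daughters is not
anatomically plausible; (v) depth pruning at 10 000 μm cumulative
along-tree distance, because only the first few branch generations of a
coarse segmentation are trustworthy. "Deepest" in (iv) is measured in
along-tree μm, not edge count, so (iv) and (v) use the same metric. The
chain is idempotent.

## Terminal sampling

Terminals are placed by Bridson-style Poisson-disk sampling restricted to
the cortex mask: k = 30 candidates per active point, drawn uniformly from
the spherical annulus [r_min, 2 r_min], accepted only inside the mask and
at ≥ r_min from all accepted points (background grid with cell edge
r_min/√3). The minimum distance comes from the territory volume:
r_min = η (V/n)^(1/3) with packing factor η = 0.7, calibrated once on the
phantom cortex so that the sampler reaches at least 95% of the requested
count (random sequential packing saturates near 2n at η = 0.7, leaving
comfortable headroom). A cube-then-filter Monte-Carlo variant
(`method = "cube"`) is available for exact replication of the
whole-volume sampling description. Same seed ⇒ bitwise-identical points.

## The optimizer

Initialization connects every terminal to its nearest pre-built node
(ties to the lowest node id; `attach_to = "ending"` restricts candidates
to scaffold endpoints). The attachment node's id becomes the terminal's
*subtree label*: throughout the optimization a leaf can only ever live
under its initialization anchor. This confinement is what makes the
non-convex kidney workable — each anchored subtree occupies a
piece-wise-convex region that straight connections do not leave — and it
also preserves the subject-specific scaffold: pre-built nodes never move,
are never contracted away, and their edges are never re-hung.

Each outer iteration then applies, in order:

* **Relaxation** — each optimizer-created intermediate node is moved to
  the minimum of its local cost (a coefficient-weighted Fermat point of
  its neighbors) by BFGS with the analytic gradient, nodes processed
  consecutively in id order (Gauss–Seidel style). Per-node minimization
  starting at the current position makes the sweep cost non-increasing.
* **Merging** — where relaxation has effectively collapsed an edge (the
  shortest incident edge of a node is below `merge_ratio` = 0.2 of the
  second shortest), that edge is contracted. 0.2 is chosen so geometric
  near-coincidences merge while legitimate short branches survive; one
  deterministic sweep per pass.
* **Splitting** — for a node with ≥ 3 eligible children, the cheapest
  2-subset of children is found, then the subset grows one child at a
  time while the cost decreases; the new node starts at the centroid of
  the subset and the node and is locally relaxed; the split commits only
  on strict cost decrease. Candidate pairs and growth candidates are
  shortlisted at centroid placement and re-scored at the relaxed
  placement (shortlists of 6 pairs / top-3 starts / top-3 additions),
  which removes placement noise from the subset choice while keeping the
  O(n²) complexity of the published approximation. One split per node per
  sweep builds structure gradually across iterations — except that nodes
  with more than 4 eligible children (piles left by initialization or by
  prune reconnection, or a large subset hung under a freshly created
  node) stay on the worklist until no improving split remains.
* **Pruning** — within each initialization subtree, vessels deeper than
  g = `prune_initial_generations` + ⌊iteration/`prune_increment_every`⌋
  *branch generations* below the anchor are deleted, and every detached
  terminal is reconnected by a straight vessel to the nearest surviving
  node carrying its own subtree label (the anchor always survives).
  Generations count branching nodes (out-degree ≥ 2) on the path from the
  anchor, the reading that matches "keeping the first two branches";
  a hop-count alternative would prune branchless chains that cost nothing
  to keep. Reconnection may legitimately target the boundary node of the
  cut — that node is part of the pruned tree — after which the next
  split sweep re-decomposes the pile.

Flows and Murray radii are reassigned after every topology-changing pass
(merging and splitting maintain them exactly by construction; pruning
does not), so the cost is always evaluated on hemodynamically consistent
trees.

**Inner sweeps and convergence.** Relax/merge/split sweeps repeat within
one outer iteration until the total cost changes by less than
`convergence_rel_tol` = 10⁻³ (capped at `inner_sweeps` = 6), so each
outer iteration hands a fully re-equilibrated tree to the prune. With a
single sweep per iteration the cost trajectory sawtooths — the prune
damages faster than one sweep can rebuild — whereas re-equilibration
makes the logged per-iteration cost non-increasing after the first
iteration at the package's desk-scale defaults (up to ~500 terminals);
toward the upper desk range the sweep cap can leave residual upticks
below ~0.3%. The outer loop stops when the relative cost
change over a full iteration falls below the same tolerance, and the
final iteration ends after relax/merge/split with no terminal prune, so
the returned tree retains every terminal.

**Cost bookkeeping.** The total cost is defined as the sum of local
costs over all nodes, so each vessel is counted once per endpoint
(exactly twice). The convention is applied consistently; only
differences and ratios ever matter to the optimizer.

**Determinism.** One seeded generator drives the terminal-radius draws;
sweeps process nodes in id order; new nodes take monotonically increasing
ids. The same inputs and seed reproduce the output tree exactly.

## The phantom

The phantom exists so that every stage is testable without a scan. It
emulates: the overall organ shape (a solid ellipsoid, default half-axes
8×5×4 mm, near rat-kidney size) with a concave hilar recess (a subtracted
paraboloid — parameter-light, and non-convex in exactly the way the
initialization must survive); a pre-built arterial tree of ~3 branch
generations rooted in the recess, with 2–3 children per node and Murray
radii from 30-μm tips, matching what large-artery extraction from a real
scan retains; and a noisy skeletonization of it — degree-2 sample nodes
subdividing edges, spurious *loop* edges (direct thin connections between
random nodes, as when a skeleton bridges adjacent vessels), and short
thin *tail spurs* extending tip nodes (skeleton endpoint artifacts). Loop
edges carry an explicitly thin edge radius, thinner than every true edge,
because a false bridge passes through thin voxels; that is what lets the
spanning-tree step remove exactly them. Tail spurs are absorbed by the
degree-2 collapse, so the preprocessing chain provably recovers the
generating leaf-to-root topology — the packaged ground-truth-recovery
test. Side spurs at interior nodes are *not* injected: the published
chain has no operation that removes a dangling branch at a node of
plausible degree, so such noise would survive preprocessing by
construction.

What the phantom does not emulate: medulla/pyramid/pelvis geometry, CT
intensities and segmentation error, anisotropic sampling density across
cortical depth, and realistic tortuosity. Tests passing on the phantom
therefore validate the algorithmic pipeline, not segmentation robustness
on real scans.

## Numerical choices and degenerate inputs

* Gradient singularities: the local-cost gradient is undefined at
  zero-length edges; implementations floor the distance at 10⁻⁹ μm, and
  the merge pass removes actual coincidences before they matter.
* BFGS: `reltol` 10⁻¹⁰, ≤ 200 iterations per node; an optimizer failure
  leaves the node unmoved and the sweep continues.
* A childless pre-built tip (a scaffold ending that received no
  terminals) terminates a vessel and participates in the equal flow
  split; its radius is its stored tip radius.
* Ties: nearest-attachment and degree-pruning ties break toward the
  lower node id; deterministic.
* An empty terminal set returns the hemodynamically assigned scaffold
  unchanged. An empty cortex, an empty mask, a root outside the mask, a
  depth threshold ≤ 0, anisotropic voxel spacing: explicit errors.
* Conservation residuals (Kirchhoff and cube law) are maintained to
  better than 10⁻⁹ relative at every node; the suite asserts this on
  every end-to-end run.

## Known limitations

* **Scale.** Desk-scale runs (hundreds of terminals, minimum separation
  ~600 μm) have geometry far sparser than a real kidney's 30 000
  terminals at ~270 μm separation. Two visible consequences: a few nodes
  keep 5–6 children because no single split lowers the cost at such wide
  fan-out angles (at full scale, dense terminals make improving splits
  abundant, and bifurcations/trifurcations dominate); and the outer loop
  converges in a handful of iterations.
* **Greedy splitting** is the published approximation to an O(n!)
  search: a child subset whose every monotone growth path passes through
  a non-improving intermediate state is unreachable for any greedy of
  this form. On random ≤ 5-child geometries it attains the
  enumeration optimum in the large majority of cases (the suite asserts
  ≥ 85%) and never commits a split that is worse than not splitting.
* **Hemodynamics** are steady-state, Newtonian, rigid-walled; no
  Fåhræus–Lindqvist effect, pulsatility, autoregulation or nephron
  models. Pressure is reported at vessel outlets.
* The cortex shell is a geometric approximation (constant thickness,
  hilar ball); no medullary exclusion constrains vessel paths beyond the
  subtree confinement inherited from the initialization.
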