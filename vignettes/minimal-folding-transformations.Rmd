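---
title: "Minimal folding transformations under non-crossing constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal folding transformations under non-crossing constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldnx)
```

## The model

`foldnx` treats folding as a purely geometric transformation between an
unfolded conformation *A* and a native conformation *B* of a
coarse-grained (one bead per residue, Cα) chain.  With no constraints at
all, the optimal transformation moves every bead on its straight chord,
and its per-bead distance is the MRSD — the mean of per-bead Euclidean
displacements, always ≤ RMSD.  Two physical constraints perturb this
ideal:

* **Link lengths.**  Strict link-length conservation would require local
  rotations whose extra distance is non-extensive.  We follow the
  approximation of dropping those rotations: beads move only along their
  straight chords, and link lengths are restored where that is possible
  without leaving the chord.  Where it is not, the bead simply waits
  (see *Numerical choices*), and the link length transiently deviates.
  The error of this approximation is small and shrinks with chain
  length; the package's own calibration (200 transformations between
  random 9-link self-avoiding walks) keeps the trajectory-averaged link
  length at ≈ 96% of its rest value, and a 10-bead L-shaped test
  transformation at 98% (σ ≈ 0.066).

* **Non-crossing.**  The evolving chain is a *ghost*: it may pass
  through itself, but every such event is recorded and its repair cost
  charged retroactively.  The repair vocabulary is the minimal set of
  uncrossing substructures of an open curve: legs, loops, and elbows.
  The cheapest ordered sequence of moves reversing every recorded
  crossing is found by depth-first branch-and-bound; its total is the
  non-crossing distance D_nx.

The decomposition reported per transformation is `D = N·MRSD + D_nx`,
with `INX = D_nx / (N·MRSD)` the fraction of motion forced by
non-crossing.

## Ghost evolution in detail

Per step, the unlocked bead furthest from its destination advances by
δ along its chord (δ = 0.02 link lengths by default — small enough
that no crossing is ever stepped over, which we verify by the
frame-rate-halving invariance test).  The move propagates outward: each
neighbor in turn moves to the point of its own chord that restores its
link length to the just-moved bead.  That point is the forward root of
a line–sphere intersection; three situations leave a bead stationary
for the step (blocking propagation past it):

* no real root exists (the sphere does not reach the chord),
* the nearest root lies behind the bead (beads never back up — motion
  along each chord is monotone, which also makes the per-bead path
  length equal the chord length and gives the bound
  |D_ghost − N·MRSD| ≤ N·δ),
* the root lies beyond the destination (the path simply ends there).

A stationary bead resumes — possibly catching up by more than δ in one
propagation — once a forward root reappears or it becomes the furthest
bead itself.  Any bead within δ of its destination snaps there exactly
and locks for good; the final frame therefore equals the target
bit-for-bit.

## Crossing bookkeeping

The chain is parametrized by t ∈ [0, L], link k owning [k−1, k).  For
every non-adjacent link pair whose XY projections intersect, the
crossing matrix stores ±t on both links, negative when the
lower-indexed link passes under.  A true crossing is a sign flip of an
entry between consecutive frames *without passing through zero* —
entries that appear or disappear correspond to projected crossings
being created or destroyed, not to the chain passing through itself.
Two robustness refinements matter in practice:

* a crossing close to a bead can make the projected intersection slide
  off a segment end within a single step; such created/destroyed or
  near-miss entries are re-examined on linearly interpolated sub-frames
  (with a rigorous reach bound filtering pairs that cannot touch),
  which is what makes the detected event set independent of the
  projection plane on generic inputs;
* exactly degenerate projections (collinear overlapping segments) get a
  deterministic 1e-7 rotation about a generic axis; a fully collinear
  chain has no crossings by construction.

A link pair crossing twice is cancelled pairwise with a warning — only
the crossing parity must be repaired.

## Uncrossing moves and the search

For each residual (not yet repaired) event with encounters t₁ < t₂:

* **Legs** (`Ls`, `Le`) are always applicable.  A leg rooted at an
  event sends every bead between the terminus and the crossing point to
  the crossing and back (cost 2·Σ|r_b − r_x|), and undoes *every*
  residual event with an encounter on the leg — compound repair for the
  price of the deepest root.
* **Loops** (`R`) require the two encounters to be consecutive among
  residual encounters.  The optimal realization of the Reidemeister-I
  twist is a pinch: interior beads collapse to the crossing point and
  reopen, 2·Σ|r_b − r_x|, strictly cheaper than a rigid half-turn
  (π·Σ|r_b − r_x|).
* **Elbows** (`E`) require two events whose four encounters pair into
  two chain-adjacent same-sense pairs; the longer-arc pair segment is
  the elbow and each of its beads visits its nearest point on the
  obstructing strand, 2·Σ|r_b − q_b|, undoing both events.

Costs are evaluated on the snapshot taken just before the relevant
crossing; compound moves use the chronologically last constituent's
snapshot (the conformation at which the final constraint bound).  The
crossing point itself is taken as the midpoint of the two encounter
positions on that snapshot — the strands coincide there to within one
step size.

The search expands moves in a canonical order (`Ls < Le < R < E`, then
root id), prunes any branch reaching the incumbent (initialized by the
greedy all-legs repair, which always exists), and expands commuting
sibling pairs in canonical order only.  On every tangle small enough to
enumerate exhaustively the search returns the enumeration optimum, and
its cost scales exactly linearly with the snapshot coordinates.

## Unfolded ensembles

Ensembles are generated from the native trace by a native-biased pivot
algorithm.  A uniformly random interior residue is pivoted: its bond
angle is redrawn from a density ∝ exp(−k_θ(θ−θ⁰)²/kT) on (0, π) and
its dihedral from ∝ exp(−[k₁(1−cos(φ−φ⁰)) + k₃(1−cos 3(φ−φ⁰))]/kT),
both centred on the native values; the downstream chain rotates
rigidly.  Moves leaving any non-neighbor bead pair closer than the
steric cutoff (the smaller of the minimum native-contact Cα distance
and the first link length) are rejected and a fresh residue drawn.  A
conformation is complete after n_pivot = 3(N−2) accepted moves, three
visits per interior residue on average.

Defaults: k_θ = 20, k₁ = 1, k₃ = 0.5, kT = 1 (dimensionless energies;
the dihedral constants are deliberately much softer than the bond-angle
one, so dihedrals scramble while local geometry persists).  These
constants follow the coarse-grained Gō-model convention the method is
built on; they are configurable, and the zero-stiffness limit is the
plain self-avoiding pivot algorithm (whose end-to-end exponent
ν ≈ 0.588 the test suite recovers), while the infinite-stiffness limit
returns the native chain unchanged.  Angle draws use inverse-CDF
sampling on a 4096-point grid — rejection-free, and reproducible.  Each
structure gets its own RNG stream derived from (seed, index) by an
integer hash, so ensembles are order-independent; R has no counter-based
generator, and an independently seeded stream per structure preserves
the intent.

A native contact is a residue pair (|i−j| ≥ 2; bonded neighbors are
trivially in contact and excluded) with any heavy-atom pair within
4.9 Å.  A contact counts as formed in a Cα-only conformation within
1.2× its native Cα distance — the usual Gō criterion, used for the
ensemble's fraction-of-native-contacts diagnostic Q.

## From PDB file to numbers

`read_calpha_trace()` keeps the first model, the first chain bearing
Cα atoms (or a requested chain), drops HETATM records, waters and
hydrogens, resolves altLocs to the highest occupancy (ties toward
`"A"`), and insists on one Cα per residue — chain breaks are an error
rather than silently bridged.  Coordinates are rescaled by the first
N-terminal Cα–Cα distance (the PDB distribution is sharply peaked near
3.76 Å), making one link the unit of length everywhere downstream.
Before evolution both conformations are smoothed by keeping every
other bead (termini always retained, rest lengths recomputed from the
native): in the spirit of the first steps of
Koniaris–Muthukumar–Taylor reduction, this removes potential crossings
whose loop or elbow would span fewer than three original links, and
quarters the crossing-detection work.

Contact-order metrics use their standard definitions: LRO counts Cα
pairs within 8 Å at sequence separation > 12, per residue; RCO/ACO
average the residue separation of heavy-atom contacts within 6 Å (at
separation ≥ 2, the same neighbor exclusion as the native contact set;
the exact exclusion in the original ACO/RCO definitions is ambiguous,
so it is exposed as an argument).  Class discrimination uses the
two-sided Welch t-test with no multiple-testing correction, matching
how such tables are conventionally reported; treat the p-values
accordingly.

## Pathway analyses

Each transformation record carries its ordered move sequence with
spans and costs.  The consensus analysis maps every record onto a
fixed 8-slot scheme — `Ls, Le, (R, E) × 3` — because at most one leg
move per side survives (same-side legs merge into the larger) and
three loop/elbow pairs suffice for nearly all transformations; one
loop splits half-and-half into the first and last R slots, two go
first and last, three in order, four or more have the middle ones
aggregated.  Records are classed by their largest move (start-leg-,
end-leg-, or miscellaneous-dominated), and the representative
transformation minimizes the normalized Euclidean deviation from its
class-mean slot vector.

The pathway overlap of two transformations matches same-kind moves
whose residue spans overlap (greedily by overlap size, each move used
once, a move overlapping two partners going to the larger overlap) and
computes χ = Σ_matched d_a d_b / (‖d_a‖‖d_b‖) over the full cost
vectors.  χ is 1 only when the matched cost vectors are proportional
and exhaust both records; identical move *sets* with different cost
profiles score below 1 under this normalization — the definition is
implemented literally, and the boundary convention (two move-free
records overlap perfectly; one move-free record overlaps nothing) is
explicit.  Records with no moves at all are excluded from ensemble
mean-χ comparisons, which otherwise would be dominated by trivial
unit overlaps between move-free pairs.

## What the synthetic generators do and do not show

All tests and calibrations run on chains built in code: random
self-avoiding walks (pivot, hard-sphere diameter of one link), an open
trefoil (equal-link resampling of the parametric trefoil curve), a
constructed 7-link pair whose ghost transformation crosses exactly
twice in a known order, ideal helices, a three-helix bundle, and a
four-strand β-meander.  These reproduce the *mechanisms* of real
folds — tertiary contacts, knotted topology, crossing chronology — at
sizes (≤ 40 residues) where every computation is exact or cheap to
verify.  They do not reproduce real side-chain packing, disulfides,
ligands, chain breaks, or the 50–170-residue scale of the reference
dataset, so passing tests demonstrate correctness of the machinery,
not biological calibration on deposited structures.  The shipped
per-protein reference table carries the published per-protein order
parameters for the 45-protein dataset; the class-statistics checks
recompute its derived columns and class means from it directly.

## Numerical choices and problem sizes

* δ = 0.02 link lengths; detection verified stable under δ/2.
* Alignment: RMSD by SVD Kabsch (proper rotations only; collinear
  inputs flagged and aligned by translation plus the best axis
  rotation); MRSD by iteratively reweighted Kabsch with Weiszfeld
  weights 1/max(d_i, 1e-9), converged at relative change < 1e-10
  (≤ 500 iterations, warning and best iterate otherwise).  Multi-start
  checks found no case where the RMSD-seeded iteration missed the
  global MRSD optimum.
* Ties in furthest-bead selection break toward the lower index;
  everything downstream of a fixed seed is bitwise reproducible.
* Test problem sizes: 9–12-link walks for trajectory properties, ≤ 5
  crossings for exhaustive-search comparisons, 200 walks × chain
  lengths 25–200 for the SAW exponent, ensembles of 4–15 structures
  for pipeline checks.  These sizes make every oracle exact or
  statistically sharp while keeping the default suite fast.

## Known limitations

* The minimal transformation is generally not kinetically realizable;
  commuting kinetically separated moves and the cornered uncrossing
  paths bias the distance in opposite directions.
* The chain has zero thickness: steric effects beyond the hard-sphere
  generation cutoff are not charged.
* Crossings are repaired to parity only — no knot-type classification.
* Disulfides, ligands and multi-chain assemblies are out of scope;
  domains are accepted as residue ranges supplied by the user.
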