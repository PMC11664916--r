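---
title: "Cavity-based discovery of photodecarboxylase candidates: methods and design"
author: "catalocavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavity-based discovery of photodecarboxylase candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catalocavity)
```

## The problem

Fatty acid photodecarboxylases (FAPs) are FAD-dependent photoenzymes of the
GMC-oxidoreductase fold that, under blue light, cleave the C–COOH bond of a
fatty acid bound with its carboxylate next to the flavin's N5 atom, releasing
an alka(e)ne and CO~2~. New family members are hard to find by sequence alone:
activity depends on the *shape and chemistry of the substrate tunnel* — a
narrow apolar channel ending at a positively polarised carboxylate pocket on
the re-face of the isoalloxazine ring — which can be conserved between
proteins whose sequences have diverged beyond easy recognition.

The discovery funnel implemented here therefore compares *cavities*: the
empty space of an active site is filled with virtual grid points, each
annotated with physico-chemical properties (a point cloud sometimes called a
catalophore), and candidate structures are ranked by how well their cavity
cloud superposes onto template clouds built from known FAP structures. The
cavity search is complemented by a sequence-side funnel (BLAST-hit filtering,
clustering, and a conserved-arginine filter) and by a docking-based ranking,
ending in a per-source shortlist.

All stages run on ordinary inputs — PDB files, tab-separated BLAST tables,
FASTA, docking cluster tables — and every stage has a deterministic synthetic
generator with planted ground truth, so the complete funnel can be validated
without database downloads or proprietary software.

## Structure preparation

`readStructure()` parses fixed-column PDB via bio3d. Alternate locations are
resolved by highest occupancy (ties to altloc `A`); residue numbers are kept
verbatim. Hydrogens are carried but ignored by all cavity and matching
computations, since most experimental structures lack them.

`locateFlavin()` fits a least-squares plane through the isoalloxazine core
atoms (`N5`, `N10`, `C4A`, `C5A`, `C9A`, `C10`; at least four must be
present — this subset is present in essentially every FAD entry, which is why
it was chosen over the full ring system). The resulting `FlavinFrame`
(N5 position, ring centroid, unit normal) anchors everything downstream. The
normal's sign is fixed toward the substrate: toward the ligand carboxyl
carbon when a ligand is known, otherwise away from the protein's atom
centroid. This gives the "re-face toward substrate" side a reproducible sign
for the orientation triage.

`truncateLigand()` shortens a long-chain bound fatty acid to a fixed carbon
count (default 8, i.e. octanoic acid). Templates built around a full-length
stearic acid would be dominated by the long apolar channel and match any
enzyme that binds aliphatic chains; truncating to C8 weights the carboxylate
binding region instead. Truncation removes atoms only — the package
deliberately does no energy minimisation or geometry repair, because input
coordinates are treated as authoritative and minimisation engines are out of
scope here.

## Cavity procreation and properties

The platform that inspired this workflow publishes neither its point
placement nor its property definitions, so the definitions below are this
package's own reconstruction with the same intent; they are consistent and
comparable across structures, which is all the downstream filters use.

`procreateCavity()` seeds a regular grid (default spacing 0.8 Å) over the
ligand's bounding box padded by `maxLigandDistance` (default 5 Å — small
clouds that emphasise the carboxylate region). A grid point is kept iff

* it clears every occluding heavy atom by that atom's van der Waals radius
  plus half the solvent probe radius (probe 1.4 Å, Bondi-style radii fixed in
  code: C 1.70, N 1.55, O 1.52, S/P 1.80),
* it lies within `maxLigandDistance` of a retained ligand heavy atom (the
  ligand itself is treated as empty space), and
* its buriedness reaches 0.4, which removes bulk-solvent points.

Two implementation details matter for reproducibility:

* **Frame-anchored grid.** The grid lattice lives in flavin-frame
  coordinates (origin N5, axes from the ring plane), with a half-cell
  offset from the origin. The cavity therefore travels rigidly with the
  protein — rotating a structure rotates its point cloud point-for-point —
  and no grid point can sit at an exact lattice tie with the cofactor atoms
  that define the frame. Without the half-cell offset such exact ties do
  occur, and a threshold comparison at an exact tie is the one place where
  floating-point noise can change a discrete result.
* **Spatial index with a brute-force twin.** Point placement uses a
  cell-list neighbour search; `bruteForceCavity()` re-implements the same
  keep rules as an all-pairs enumeration. The two must agree exactly, and
  the test suite and acceptance script verify that they do on seeded toy
  structures.

`annotateProperties()` fills the five-component property vector per point:

| property | definition | range |
|---|---|---|
| electrostatic | \(\sum_a q_a/(\varepsilon(r)\,r_a)\) with \(\varepsilon(r)=4r\), i.e. \(q/(4r^2)\), over charged sites within 12 Å | signed |
| hbond_donor | max over donor atoms of a linear ramp 1→0 between 2.5 and 4.0 Å | [0,1] |
| hbond_acceptor | likewise over acceptor atoms | [0,1] |
| hydrophobicity | fraction of heavy atoms within 4.5 Å that are apolar carbons | [0,1] |
| buriedness | fraction of 42 fixed ray directions (icosahedron vertices + edge midpoints, rotated into the flavin frame) hitting an atom within 8 Å | [0,1] |

Charges are residue-template integers: Arg/Lys +1 on the side-chain nitrogen
centre, Asp/Glu −1 on the carboxylate midpoint, His neutral, termini
ignored. This is parameter-free, deterministic and sign-correct — and the
funnel only ever uses the *sign* and relative magnitude of the potential.
The distance-dependent dielectric \(\varepsilon = 4r\) is a standard implicit
screening choice. Poisson–Boltzmann electrostatics, protonation assignment
and conformational sampling are intentionally out of scope.

`negativeChargeStabilization()` reports whether the mean potential over
points within 4 Å of N5 is strictly positive (a positive potential
stabilises the substrate carboxylate). With no points in range the result is
`NA` — explicitly inconclusive rather than a silent `FALSE`, because the two
cases call for different reviewer action.

## Cloud matching

`alignClouds()` initialises the rigid transform by superposing the two
flavin frames: N5 onto N5, ring normal onto ring normal, and the in-plane
rotation fixed by the centroid→N5 axis (the `FlavinFrame` stores exactly the
quantities needed for this; the centroid→N5 direction fixes the same
in-plane degree of freedom the ring's N10→N5 axis would). Every cavity of
interest contains a flavin, so frame superposition replaces a global
registration search and, by construction, never produces matches in which
the clouds align but the isoalloxazine rings do not. ICP refinement then
iterates nearest-neighbour pairing within \(2\varepsilon\) (ties to the lowest
point index, for determinism), a Kabsch least-squares update, and stops after
50 iterations or when the score improves by less than 10⁻⁶; the transform
with the best score along the trajectory is returned. If frame superposition
leaves no pair within \(2\varepsilon\), the result is the worst case (overlaps
0, score 1) rather than an error, so batch runs never abort on a hopeless
candidate.

`overlapFraction()` is the percentage of one cloud's points that have a
property-compatible partner within \(\varepsilon = 1\) Å (grid-spacing scale)
in the other cloud. Compatibility means: same electrostatic sign — values
inside a dead-band of 10 % of the moving cloud's maximum |potential| are
wildcards, which prevents sign flips from numeric noise — and donor/acceptor
scores within 0.5. A geometry-only switch (`useProperties = FALSE`) exists
because it is genuinely unknown whether the original platform's overlap
counts chemistry or only geometry.

The published workflow gates matches on a total score below 0.05 and
overlaps above 70 % (template in target) and 10 % (reverse; 30 % for larger
candidate pools, with "larger" exposed as a configuration option and
defaulting to pools above 100 targets), but no score formula is public.
`totalScore()` is therefore a documented reconstruction on [0,1]:

\[ s = 0.7\,(1 - \mathrm{symOv}/100) + 0.3\,\bar d_{\mathrm{prop}} \]

where symOv is the harmonic mean of the two directional overlaps (harmonic,
so either direction collapsing drives the geometry term toward 1) and
\(\bar d_{\mathrm{prop}}\) is the mean normalised property distance over
nearest-neighbour pairs within \(\varepsilon\) (1 if nothing pairs;
electrostatic deltas are normalised by the template's maximum |value| and
capped at 1). A self-match scores exactly 0 and fully disjoint clouds score
exactly 1, preserving the ordering semantics the strict `< 0.05` gate relies
on. The weights 0.7/0.3 encode that geometry dominates but chemistry must
agree; they are constructor arguments, not hidden constants.

`filterMatches()` applies the strict-inequality gates and *annotates* (never
removes by) the two automated triage flags that replace the published visual
inspection: `flavinSameSide()` — after superposition, the ring normals must
agree to within 90° and the target N5 must sit on the same side of the
template cloud's centroid plane as the template N5 — and the electrostatic
stabilisation tri-state above. Triage is annotation because the original
inspection criteria are narrative, and nothing should be silently dropped by
a heuristic reimplementation of a human step. Whether score filtering
preceded the visual triage is not documented; here filtering comes first and
triage second, which never changes the surviving set (triage removes
nothing).

## The sequence funnel

BLAST hits (tabular outfmt-6; coverage columns used when present, otherwise
computed from the aligned spans and sequence lengths) are filtered at ≥ 30 %
identity and ≥ 80 % coverage in *both* directions. The published criterion
says "bidirectional coverage (query)", which is ambiguous; the strictest
reading — both query and subject — is implemented, with both thresholds
exposed.

Clustering is greedy set cover in the CD-HIT style: sequences sorted by
length descending (ties by id), the longest unassigned sequence becomes a
representative, and every unassigned sequence with at least 70 % pairwise
identity to it joins. This deterministic, dependency-free scheme stands in
for cascaded MMseqs2 clustering with the same cutoff semantics; every member
is guaranteed ≥ 70 % identity to its representative.

Pairwise identity uses a global Needleman–Wunsch alignment with affine gaps
(Gotoh, implemented in C++): BLOSUM62, gap open 11 / extend 1 (a gap of
length L costs 11 + L), end gaps penalised. Identity is
100 · matches / alignment columns, gapped columns counting in the
denominator (an explicitly stated choice, since definitions vary; a
min-length denominator is available), and `X` never counts as a match. The
argument pair is canonically ordered before aligning, so identity is
symmetric regardless of tie-breaking inside the dynamic program.

`conservedResidueFilter()` maps a reference position through a single global
alignment per representative and keeps only sequences with exactly the
required residue (arginine at reference position 451 by default) in the
mapped column — a gap or any substitution fails, including the
lysine-for-arginine replacement seen in some related enzymes. The conserved
cysteine (432) and tyrosine (466) columns are reported alongside but never
filtered on. Single-alignment mapping (no profile) suffices because these
positions sit in well-conserved sequence blocks; the synthetic generator
reproduces exactly that situation (below).

## Docking evaluation

Docking engines are out of scope; their cluster tables are inputs. For each
candidate–ligand pair `selectCluster()` takes the cluster with minimal
carboxyl-carbon-to-N5 distance and uses *that cluster's* binding energy —
ties on distance go to the lower energy, then the lower cluster id. The
workflow's prose ("minimal distance and lower binding energy were taken into
consideration") is softer than its operational footnote; the footnote is
implemented because it is the rule a heat map can actually be built from.
The combined score is \(|E/d|\) (kcal·mol⁻¹ per Å), favouring poses that are
simultaneously tight and close to the flavin. `buildMatrix()` assembles the
candidate × ligand grid; missing pairs score 0 *and stay in the matrix*
(flagged), so per-candidate sums remain comparable across candidates with
unequal docking coverage. `topK()` returns the per-group top-k by summed
score (default 5 per source group, mirroring a 5 + 5 two-source shortlist),
ties broken by candidate id.

## Synthetic data: what it emulates, and what it does not

Every generator takes a single seed, draws all randomness inside a scoped
RNG (global RNG state is restored), and emits a manifest whose planted truth
fully determines the expected result of the stage it feeds.

* `makeToyEnzyme()` — a jittered cylindrical shell of apolar pseudo-atoms
  forming a buried tunnel, a linear fatty acid threaded inside, a planar
  six-atom flavin mimic at the tunnel head (ring normal toward the
  substrate), and optionally an arginine-like +1 or aspartate-like −1 site
  near N5. The manifest records atom counts and the brute-force cavity point
  count. The flavin's axial offset is chosen incommensurate with the grid
  spacing (see the half-cell note above).
* `makeCloudPair()` — cloud B is a known rigid transform of a subset of
  cloud A (subset size sets the planted overlap) plus decoys kept ≥ 2ε from
  every A point; A itself is sampled with ≥ 2.2ε separation. Both
  directional overlaps are therefore *exact* by construction, not merely
  expected.
* `makeBlastTable()` — exactly `nPass` rows satisfy the 30/80/80 rule; every
  failing row violates at least one threshold by a clear margin.
* `makeSequenceFamilies()` — families are heavy mutants (~65 % of mutable
  positions) of one common reference; members are light mutants (~3 %) of
  their family seed. Windows of ±10 residues around the conserved positions
  are never mutated — except for the planted arginine→lysine substitution
  itself — so global alignments stay anchored and position mapping is exact.
  Within-family identity stays ≳ 94 %, between-family ≲ 30 %, so the 70 %
  cutoff separates families with a wide margin.
* `makeDockingTable()` — planted energies/distances with the expected
  matrix, sums and top-k recomputed by an independent naive loop at
  generation time (and re-verified independently at test time).
* `makeSyntheticBundle()` — composes all of the above into one directory
  with a YAML config: one template, one true hit (the template rigidly
  translated), a short-ligand decoy that fails the template-in-target
  overlap gate, a wide-cavity decoy that passes overlap but fails the total
  score (the "large cavity" case the 10 % reverse gate exists for), four
  sequence families with one family lacking the arginine, and a docking
  table over the union of candidates.

What the generators deliberately do **not** emulate: real protein folds and
packing, BLOSUM-like substitution processes, indel evolution, docking-energy
physics, crystallographic noise, or alternate conformations. Passing tests
therefore demonstrate that the *funnel machinery* is correct — filters apply
stated thresholds exactly, oracles agree, plants are recovered — not that
the reconstructed property definitions would rank real proteomes identically
to the original proprietary platform.

## Numerical choices and degenerate inputs

* Strict inequalities at all match gates (a score of exactly 0.05 or an
  overlap of exactly 70 % fails), inclusive thresholds (≥) in the sequence
  funnel; both follow the wording of the respective criteria.
* ICP nearest-neighbour ties break to the lowest target index; cluster-
  selection ties to lower energy then lower id; top-k ties to id order —
  everything has a stated, deterministic tie-break.
* Buriedness is a discrete count (k/42). Re-deriving the frame after a
  rigid transform perturbs ray directions at the 10⁻¹⁵ level, so a ray that
  tangentially grazes an atom sphere can flip by one; equivariance of
  buriedness is therefore exact up to single-ray resolution, while the four
  smooth properties are equivariant to 10⁻⁶.
* Degenerate flavins (missing residue, fewer than four ring atoms, collinear
  ring atoms) raise typed errors; an empty cavity raises a dedicated error;
  a hopeless cloud match returns the worst-case result instead of erroring.
* Problem sizes in the shipped tests and acceptance script — toy enzymes of
  roughly 300 atoms, clouds of 150–250 points, 50 sequences of ~520
  residues, a 14 × 25 docking table — were chosen as the smallest sizes at
  which every stage still exercises its nontrivial geometry (multi-ring
  tunnels, partial overlaps, multi-family clustering).

## Known limitations

The five-property vector is a stand-in for an unpublished definition; scores
are comparable within this package but not numerically to the original
platform's (its published gate values are honoured as *semantics* — strict,
lower-is-better — on a score calibrated to the same [0,1] endpoints).
Homology modelling, Foldseek and BLAST execution, protonation, energy
minimisation and all wet-lab stages are outside the package: their outputs
enter as ordinary files. Greedy clustering can split a family that a
cascaded clusterer would merge when identities straddle the cutoff; the
generators avoid that regime deliberately, and real-data users should treat
cluster counts near the cutoff with care.
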