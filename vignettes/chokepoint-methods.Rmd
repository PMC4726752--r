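---
title: "Methods: channel geometry, descriptor scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel geometry, descriptor scoring and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chokepoint)
```

`chokepoint` answers a geometric question about enzyme ensembles: which
conformations of a buried active site are open and arranged well enough
to bind substrate? This vignette documents the models behind each
module, the tunable parameters with their defaults and why, what the
synthetic generators do and do not emulate, and the numerical choices a
user relying on the results should know about.

## The active-site descriptor and score

A catalytically competent active site is summarised by a small set of
site atoms — in the flavoprotein monooxygenase use case, the side-chain
and backbone oxygens that hydrogen-bond the aromatic substrate plus the
reactive flavin C4X atom — and by all pairwise distances between them
measured in a reference holo structure. With k atoms that is k(k−1)/2
distances; for k = 4 the six distances fix the geometry up to
chirality. Each frame of an ensemble is scored by

$$S = \sum_{ij} \left| d_{ij}(\text{frame}) - d_{ij}(\text{ref}) \right|$$

**Absolute-value convention.** A raw signed sum of differences would let
a pair that is too long cancel a pair that is too short, so a distorted
site could score as well as a faithful one, contradicting the intended
reading that low S means high similarity to the reference. Deviations
therefore enter as absolute values; `score_frames(..., signed = TRUE)`
exposes the raw signed sum for comparison experiments. S is
nonnegative, zero exactly when every pair matches the reference, and
invariant under rigid motion of the frame (distances only).

**All pairs, not a subset.** Which distance subset best captures a given
site is system-specific and not recoverable in general; using the full
pair set is the only parameter-free choice and over-determines the
geometry harmlessly. Users wanting a subset can build a descriptor from
fewer site atoms.

Cross-homolog scoring (reference from one protein, frames from another)
takes a mapping: either a residue map from `align_pair()` applied to
residue numbers, or an explicit named vector of atom-spec replacements
when atom names differ between residue types (a serine's OG standing in
for a threonine's OG1, for example).

## Tunnel detection

`detect_tunnels()` is a declared grid method, not a reimplementation of
any published tunnel tool: Voronoi-based algorithms give exact
medial-axis tunnels, but a clearance-field grid search is transparent,
dependency-free and accurate to its spacing, which is the right
trade-off for an analysis whose acceptance band is one grid spacing.

1. A regular grid (default spacing 0.5 Å) covers the heavy-atom
   bounding box plus a margin; the grid is translated so the start
   point is itself a node, which matters for narrow apertures centred
   on the start's axis — without the shift a 1.5 Å aperture can be
   missed entirely by a 1.4 Å probe.
2. Every node's clearance is its distance to the nearest heavy-atom van
   der Waals surface. Radii are the Bondi set shipped as a plain-text
   table (`vdw_radii_table()`), so diameters are reproducible
   bit-for-bit; unknown elements are an error, never a default.
3. Nodes with clearance below the probe radius (default 1.4 Å, a water
   molecule) are removed; the rest form a 6-connected graph with edge
   weight equal to the smaller endpoint clearance.
4. A boundary node is a bulk-solvent exit when the sphere of radius
   `shell_radius` centred `shell_depth` outward of it (along the
   direction away from the protein centroid) contains no protein atom.
   The 6 Å / 6 Å defaults are the conventional shell parameters for
   this kind of search.
5. The widest path (maximise the minimum clearance) from start to every
   reachable exit comes from a maximum spanning tree of the grid graph,
   on which bottleneck values propagate in one breadth-first pass.
6. Exits within `shell_radius` of one another are merged (cell binning
   at the shell length scale with adjacent-cell linkage — a conservative
   approximation of single-linkage clustering at that cutoff, chosen so
   merging stays linear in the number of exits); each merged mouth keeps
   its widest representative. Tunnels are returned widest-first with
   full centerline profiles.

The probe radius, shell parameters and spacing are all recorded in the
result's attributes. Accuracy: on synthetic tubes the recovered
bottleneck converges to the analytic clearance as the spacing shrinks
(tested at 1.0 / 0.5 / 0.25 Å), and rigid-motion invariance holds to
within one spacing.

## Choke points, classification, salt bridges

Published per-frame channel-diameter traces are parameterized by a
bottleneck residue pair, but the atom convention behind such traces is
rarely stated. The default here is the *closest-heavy-atom
surface-to-surface distance*: the minimum over atom pairs of
d(a, b) − r_vdw(a) − r_vdw(b). It is deterministic, rigid-motion
invariant, equals the free diameter for atoms flanking a circular
aperture, and can go negative when surfaces interpenetrate (a strongly
blocked state). A side-chain centroid mode is available; the mode is
recorded in the series attributes.

`classify_channel()` needs an open/closed threshold. No universal
number exists; the default 4.0 Å is the clearance an aromatic ring
needs to pass edge-on with van der Waals contact, and the same default
feeds `select_frames()` so "open enough to select for docking" and
"open" in classification agree. `blocked_persistently` is defined
strictly: no frame open at all, the signature separating a stable
channel-spanning salt bridge from mutants that merely fluctuate between
open and closed states.

Salt bridges are called on side-chain nitrogen/oxygen distances only
(Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 against Glu OE1/OE2, Asp OD1/OD2)
at a 4.0 Å N–O cutoff, the conventional upper bound for a
charge-assisted hydrogen bond. A residue lacking its charged side-chain
atoms raises an error rather than returning "no bridge": a truncated
model and an absent interaction must not be confounded.

## Sequence layer

`align_pair()` wraps Needleman–Wunsch global alignment with affine gaps
(gap of length L costs open + extend·L; defaults 10 and 0.5 with
BLOSUM62), returning the residue correspondence used for cross-homolog
superposition, descriptor mapping and mutation transfer. Tests pin the
score to an exhaustive enumeration over all alignments for short
sequences; traceback tie-breaking among co-optimal alignments follows
the underlying library and is deterministic, though not guaranteed to
follow any particular preference order among co-optimal paths.

`column_conservation()` is a *declared simplified substitute* for
tree-aware evolutionary-rate methods: 1 − H/log 20, with H the Shannon
entropy of the column's amino-acid frequencies, gaps excluded. It
ignores phylogenetic correlation and substitution similarity, which is
acceptable for ranking columns as more or less conserved but not for
absolute rate estimates; every profile carries its method tag, columns
with more than 50 % gaps are flagged unreliable, and all-gap columns
are NA. Projection onto a structure writes per-residue scores into
B-factors (sentinel −1 for unmapped residues), matching structure
residues in order 1:1 to the ungapped target sequence and warning on
residue-identity mismatches rather than failing, since homology models
routinely carry numbering quirks.

## Assay arithmetic

The quantification module implements Beer–Lambert concentration,
cofactor occupancy, NADH-oxidation rate/turnover and internal-standard
recovery correction, with molar units and cm path lengths enforced at
the boundary. The free-FAD extinction coefficient is recorded as
11300 M⁻¹cm⁻¹ (= 11.3 mM⁻¹cm⁻¹, the standard value; source texts
sometimes print the mM label with the M-scale number — both readings
are noted in `extinction_coefficients()` documentation). All operations
are homogeneous of degree 1 in their amount arguments, and the
internal-standard correction exactly inverts any uniform loss fraction,
both verified by property tests.

## The synthetic generators, and what passing tests mean

`make_tunnel_ensemble()` builds the canonical test geometry: carbon
pseudo-atoms on a cylindrical lattice (spacing 1.2 Å, dense enough that
a 1.4 Å probe cannot leak between atoms), one capped end, a cofactor
marker at the base, and a constriction ring whose radius is programmed
per frame. **Radius convention:** the constriction radius r(t) is the
*free* (clearance) radius — ring atom centers sit at r(t) + 1.70 Å.
This makes the generator self-consistent with both analyses: the
detected tunnel bottleneck equals r(t) exactly, and the gate residues
placed diametrically across the constriction have a surface-to-surface
choke diameter of exactly 2·r(t). (Under the alternative convention,
where r(t) is the atom-center radius, the free radius is r(t) − 1.70
and sub-3 Å constrictions would be closed to a water probe, making
closed-loop recovery tests impossible; the free-radius convention is
the one under which both quantities stay analytically known.) Noise is
applied to the ring radius, not per atom, so the analytic bottleneck
remains known per frame and is returned in an attribute.

The default geometry (free base radius 5 Å, length 20 Å, constriction
at 0.6 of the length, start 6 Å above the base marker) keeps the
start's own clearance above the largest tested constriction, so the
constriction — not the start environment — always governs the measured
bottleneck. `make_blocked_variant()` extends the gate side chains
(Arg NH1, Glu OE1) into the lumen at a fixed 3.0 Å N–O separation:
salt-bridge persistence 1, choke diameter ≈ −0.07 Å, persistently
closed at any sensible threshold.

`make_reference_site()` embeds an exact target distance matrix by
classical multidimensional scaling (residual checked against 1e-6 Å;
unrealizable matrices are an error) plus decoys ≥ 8 Å away.
`make_msa()` draws each column from a one-consensus-residue categorical
distribution whose normalized-entropy conservation equals the requested
target exactly in expectation (the consensus probability is solved per
column by root finding).

These fixtures emulate the *geometry* of channels, active sites and
alignments — not protein energetics, side-chain packing, solvent, or
phylogenetic structure. A passing suite therefore demonstrates that the
geometric operations are correct and self-consistent at Å scale; it
does not validate force fields, sampling quality, or conservation
inference on real families. Problem sizes in the tests — tubes of a few
hundred atoms, ensembles of 1–10 frames, grids at 1.0/0.5/0.25 Å,
100-sequence alignments of 80 columns, 200 alignment-oracle trials —
were chosen as the smallest sizes at which every property is
non-trivially exercised.

## Numerical choices and degenerate inputs

* Coordinates parse at the PDB fixed-column precision (0.001 Å);
  round-trips are exact at that precision. Frames are 0-indexed;
  residue numbering follows the file verbatim.
* Alternate locations keep the highest-occupancy conformer, ties to the
  first in file — deterministic and standard practice.
* Hydrogens are retained in the data model but excluded from every
  heavy-atom computation (clearances, bottlenecks, descriptor defaults).
* Superposition uses the closed-form SVD construction with the
  determinant sign correction, so reflections are never returned; fewer
  than 3 paired atoms is an underdetermined error.
* Frame selection breaks score ties by lower frame index; an empty
  eligible set returns an empty selection with a warning, never an
  error.
* Multi-model files must share one topology; a missing atom in any
  model is a topology error naming the frame, not a silent drop.
* The pipeline validates its whole configuration before computing and
  reports every problem at once; a failing choke pair is flagged and
  skipped rather than aborting the run.

## Known limitations

* Grid tunnels are accurate to one spacing and cost memory cubically in
  the box size; very large proteins call for a coarse pass first.
* The entropy conservation score underestimates conservation spread at
  small alignment depth (sample-entropy bias) and knows nothing of
  substitution similarity.
* Choke-point diameters depend on the chosen residue pair; the package
  reports the pairing and mode but cannot decide biological relevance.
* Cross-homolog superposition pairs atoms by name within aligned
  residues; atoms renamed between residue types (OG vs OG1) pair only
  through an explicit mapping.
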