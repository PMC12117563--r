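---
title: "Antibody structure curation, interface analysis and pose scoring with fvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antibody structure curation, interface analysis and pose scoring with fvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvkit)
```

## The problem

Antibody specificity lives in the Fv region: the paired heavy (VH) and
light (VL) variable domains whose three complementarity-determining
regions (CDRs) per domain form most of the paratope. Crystal structures
of antibodies deposit in many inconsistent shapes — several copies of a
complex in one asymmetric unit, constant domains attached, scFv
constructs, antigens that are sometimes genuine oligomers and sometimes
crystal-packing neighbours. A machine-learning-ready dataset needs one
biological complex per file, a consistent numbering scheme and chain
naming, and per-residue features. `fvkit` implements that curation
pipeline, the docking-preparation computations around it, and a
DockQ-style pose quality metric, all testable offline against synthetic
structures with exact ground truth.

## The standardization procedure and its parameters

An entry flows through three steps.

**Numbering and renaming.** Chains are scanned by a *numbering engine* —
any function from a one-letter sequence to zero or more domain hits with
per-residue Martin positions. The engine seam keeps profile-HMM
numbering (an external tool) out of the package: production users plug
in a parsed numbering table (`read_numbering_table()` reads the common
tabular layout), while all tests use a deterministic table-driven engine
fed by fixture ground truth. Only residues covered by the number map are
kept, so constant regions and scFv linkers are trimmed. CDR spans
default to Kabat-style intervals under Martin numbering (H1 31–35, H2
50–65, H3 95–102; L1 24–34, L2 50–56, L3 89–97); no published CDR
definition is canonical here, so the spans are a configurable argument
and membership is decided on the Martin number, which places inserted
residues (100A) inside their parent span.

**VH/VL pairing.** The Cα distance between the conserved cysteines at
Martin H92 and L88 decides which domains belong to the same antibody;
22 Å is the pairing radius, inclusive (the invariant is
`cys_distance <= cutoff`). When an entry carries several Fv copies the
matching is greedy by ascending distance — each step pairs the globally
closest remaining VH/VL couple, which is always a mutual-nearest pair —
with ties broken by chain-id order. A global optimal assignment was
considered and rejected: at 22 Å the distance matrix of real entries is
block-diagonal (copies sit far apart), greedy and optimal coincide, and
greedy decisions are easier to audit in the manifest. A domain whose
pairing cysteine lacks a Cα is unpairable and becomes a single-chain
antibody.

**Antigen state and complex construction.** Non-antibody chains are
grouped by classifying every pairwise interface as biological or
crystallographic and taking the transitive closure of the biological
relation. The default classifier calls an interface biological when the
buried surface area is at least 800 Å² *and* at least 10 inter-chain
residue pairs have heavy atoms within 5.5 Å. Those two numbers are the
classic separation scales between specific interfaces and lattice
contacts (crystal-packing patches are typically a few hundred Å²); the
classifier is a plain `function(model, chain_a, chain_b)` so a trained
external classifier can replace it, and a classifier failure falls back
conservatively to monomer treatment. Complexes are then built by
counting Cα–Cα pairs under 7.5 Å between pooled CDR residues (all six
CDRs of a paired antibody) and antigen residues; the comparison is
strict (`< 7.5`), "within" being read as an open interval, and the
boundary behaviour is configurable for audit. One contact suffices.
Antigens must have *more than* 50 residues (strictly; an exactly
50-residue chain is excluded, oligomer length summed over members).
Output files are named `XXXX_n` with `n` assigned in a deterministic
order (antibody chain ids, then antigen ids), so reruns are
byte-identical.

Entries with missing heavy atoms in any standard residue are rejected
whole, matching the dataset-level filter the pipeline models (a
per-chain salvage was considered; whole-entry rejection is the
conservative reading of "remove structures" and keeps the complex
bookkeeping simple). Completeness is judged against a fixed per-residue
heavy-atom dictionary (backbone N/CA/C/O plus canonical side chain; OXT
and hydrogens ignored); non-standard residues are kept when
peptide-linked but exempt from the check. Entries where one chain
carries two same-type variable domains (dual-variable-domain constructs)
are rejected as unusual formats.

## Docking preparation

For restraint-based docking the two antibody chains must not collide in
residue number: the heavy chain is renumbered sequentially from 1 and
the light chain from 500, insertion codes removed, with the
original↔new mapping returned (the renumbering is a bijection and is
covered by a round-trip test). Active residues of the antibody are its
CDRs. For blind docking the antigen contributes passive residues: all
residues with relative SASA ≥ 0.15 on the isolated antigen — 15% is the
common exposure convention for restraint selection; the threshold is an
argument. For site-directed docking the epitope is defined by burial:
residues losing more than 1.0 Å² of accessible area between the
isolated and complexed antigen become active. The 1.0 Å² floor exists
only to suppress sampling noise of the surface estimator (at 960 sphere
points per atom the per-residue resolution is of order a tenth of an
Å²); whether the original protocol used an absolute or relative change
is not documented, so the absolute form with a configurable floor was
chosen as the simplest auditable rule.

## Pose quality

A pose is scored against its reference complex with receptor = antigen
and ligand = antibody (the assignment is fixed and documented; nothing
in the metric depends on it beyond which partner anchors the LRMS fit):

* **Fnat** — fraction of the reference's interfacial residue pairs (any
  heavy-atom distance < 5 Å) recovered by the pose;
* **LRMS** — backbone (N, CA, C, O) RMSD over the ligand after a
  least-squares fit on the receptor backbone;
* **iRMS** — backbone RMSD over the reference-defined interface
  (residues of either partner with heavy atoms within 10 Å of the other
  partner) after an optimal fit on that interface;
* **DockQ** = mean of Fnat, `1/(1+(iRMS/1.5)²)` and `1/(1+(LRMS/8.5)²)`,

classified high (≥ 0.80), medium (≥ 0.49), acceptable (≥ 0.23),
incorrect (< 0.23), boundaries inclusive exactly as printed. The 5 Å /
10 Å / 1.5 Å / 8.5 Å component constants follow the metric's original
publication. Superposition is the Kabsch algorithm via singular value
decomposition with the determinant correction, so only proper rotations
are returned; collinear inputs are an error. Residue correspondence
between pose and reference is positional — (chain, number, insertion
code) after standardization — with no sequence-alignment fallback, which
is exact for redocking workflows and deliberately refuses mismatched
inputs.

The per-system descriptor subset selects four poses: the best-scoring
pose of each represented quality category, back-filled with additional
incorrect poses (lowest scores first — decoys are most useful at the
bottom of the range) when categories are empty, with lexicographic
tie-breaks for determinism.

## The descriptor suite

All descriptors are computed per residue in the context of the full
standardized file by default (a complex buries its interface, which is
what ΔSASA-based analyses need); an `isolate_chains` argument computes
on an extracted subset instead.

* **SASA** — Shrake–Rupley with a deterministic golden-spiral point set;
  probe 1.4 Å, 960 points per atom by default (area resolution
  `4πR²/960`, well under the 0.5% tolerance of the single-sphere
  closed-form check). Relative SASA divides by the Tien et al.
  theoretical maxima; the reference table is an argument.
* **Residue depth** — mean distance of a residue's heavy atoms to the
  nearest accessible-surface dot, minus the probe radius, so a fully
  exposed atom reports roughly its vdW radius and buried atoms grow from
  there; a single-atom model is assigned depth 0 by convention.
* **Protrusion index** — per atom, occupied volume inside a 10 Å sphere
  is `count × 20.1 Å³`; CX is free/occupied volume, capped at 15 (an
  isolated atom's raw ratio exceeds 200 and carries no information
  beyond "maximally protruding").
* **Half-sphere exposure** — Cα neighbours within 13 Å split by the
  plane normal to the Cα→Cβ vector (real Cβ when present, otherwise a
  pseudo-Cβ built from the backbone frame); up + down equals the
  neighbour count by construction.
* **Dihedrals** — φ/ψ in degrees, IUPAC sign convention, absent at
  termini and across chain breaks (peptide C–N > 2.5 Å).
* **Secondary structure** — 3-state. Hydrogen bonds use the
  Kabsch–Sander electrostatic energy with the amide hydrogen rebuilt
  along the previous residue's C=O direction; a bond forms below
  −0.5 kcal/mol. Runs of i→i+4 turns give H; parallel/antiparallel
  bridge patterns give E (computed across chains, so inter-chain sheets
  are found); H wins over E; everything else, including residues without
  a carbonyl oxygen, is C. Three states rather than eight because the
  downstream use is a categorical feature, not an assignment benchmark;
  no exact agreement with any particular external assignment program is
  claimed.

The CSV emitted per structure has a fixed 16-column header, one row per
residue in chain order, empty fields for absent values.

## What the synthetic fixtures emulate — and what they do not

The generators build idealized poly-glycine backbones from exact
internal coordinates (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ideal
angles, ω = 180°), with alanine/cysteine landmarks where an operation
needs side chains. The Fv fixture places conserved cysteines so the
H92–L88 Cα distance is exact; the complex fixture approaches a helical
antigen end-on and scans the approach distance until the engineered
CDR-contact count is met exactly; crystal-copy and dimer layouts
reproduce the two published multi-copy topologies (two copies with a
marginal antigen–antigen touch → two single-antigen files; a tightly
packed antigen dimer → two files each keeping both chains). Poses are
rigid-body perturbations with the exact transform returned.

These fixtures are geometrically exact but physically idealized: no side
chains beyond stubs, no packing quality, sequences that are glycine
landscapes rather than immunoglobulin folds, and a table-driven
numbering engine instead of a profile-HMM. Passing tests therefore
demonstrate that the *rules* of the pipeline (cutoffs, counting,
renaming, splitting, scoring algebra) are implemented exactly; they do
not validate numbering accuracy on real antibody sequences, classifier
accuracy on real crystal interfaces, or descriptor agreement with any
specific external binary on real folds.

## Numerical choices and degenerate inputs

* All surface quantities are exact functions of the sphere-point count;
  defaults are 960 points (descriptors) and 240 (interface screening,
  where only an 800 Å² threshold is at stake).
* Alternate locations collapse to the highest-occupancy conformer (ties
  by alt-loc letter); only the first model of multi-model files is read.
* PDB output is fixed-column with coordinates at 3 decimals; write∘read
  is the identity on the data model at that precision.
* Contact comparisons are strict `<`; the pairing radius is inclusive
  `<=`; both are arguments.
* Degenerate cases: empty polymer → error; reference without
  inter-partner contacts → "not a complex" error; collinear
  superposition input → error; fewer than 4 poses → error; an
  interface-classifier exception → monomer fallback with a warning.
* Problem sizes throughout the tests and the acceptance script
  (102/97-residue synthetic domains, 40–60-residue antigens, 240–960
  sphere points) keep the full suite around three minutes on one core
  while leaving every boundary check exact; they are package choices,
  not statements about real antibody sizes.

## Known limitations

* The default interface classifier is a two-threshold heuristic; it
  reproduces the two published example topologies but is not a trained
  classifier, and borderline crystal interfaces (600–900 Å²) will be
  sensitive to the BSA threshold.
* Martin numbering itself is delegated; the package ships no HMM and
  cannot number novel sequences without an engine.
* Crystallographic symmetry expansion and biological-assembly generation
  are out of scope: the pipeline standardizes what is in the coordinate
  file.
* Descriptor values are estimator-specific (point counts, radii sets);
  they are deterministic and internally consistent but not bit-equal to
  any external SASA/DSSP implementation.
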