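---
title: "Methods: conservation, motifs, contacts and the 8-state sensor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, motifs, contacts and the 8-state sensor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsmap)
```

# Scope

`spsmap` implements the computational toolbox needed to dissect a
plasma-membrane nutrient sensor of the Ssy1–Ptr3–Ssy5 (SPS) type: an
amino-acid receptor evolved from LeuT-fold transporters, an adaptor with a
WD40 β-propeller, and a latent protease whose activation is controlled by
the antagonism between casein kinase 1 (Yck1/2) phosphorylation and
PP2A^Rts1^ dephosphorylation. The package does not build alignments, run
structure prediction, or predict disorder; it consumes those artifacts
(aligned FASTA/Clustal, PDB/mmCIF, two-column score tracks) and makes the
downstream analyses reproducible and testable.

# Alignment conservation

Coordinates are 1-based and inclusive throughout, and all alignment
results are reported in the numbering of a designated reference row.

Two deliberately different denominators are used and should not be mixed:

* **Column identity fraction** = (count of the most frequent residue) /
  (number of rows). Gaps count as mismatches. A column is *fully
  conserved* only when the fraction is 1, which implies zero gaps. This
  matches how invariant positions are counted when one asks "how many
  residues are identical in all orthologs": a gap anywhere disqualifies
  the position. The published counts this package is designed to
  reproduce (e.g. 35 invariant positions in a transmembrane bundle across
  37 fungal sequences, 25 across a 16-sequence transporter family) are
  invariant-residue counts, so the zero-gap convention is the default and
  the only one exposed.
* **Pairwise identity/similarity** = matches / co-aligned columns (both
  rows non-gap). Restricting to co-aligned columns is the convention
  under which published ranges such as 20–27 % identity and 32–42 %
  similarity for distant transporter homologs are computed; counting gap
  columns would deflate all values for long terminal extensions.

Similarity uses a conventional physico-chemical partition
({A,V,L,I,M}, {F,W,Y}, {K,R,H}, {D,E}, {S,T,N,Q}, {G}, {P}, {C}),
exposed via `similarity_groups()`. The groups a published figure used
(ESPript's defaults) are not documented precisely enough to clone, so the
partition is a configuration knob, and group-level results are treated as
calibration-dependent rather than asserted against published values.

**Conserved boxes** (`detect_conserved_boxes()`) are maximal runs of
columns with identity fraction ≥ `min_identity` (default 0.7), tolerating
at most `max_below_run` (default 2) consecutive sub-threshold columns,
with a minimum span of `min_length` (default 3) reference residues. The
defaults are calibration knobs chosen so that a short invariant triplet
(the smallest box annotated in the sensor's N-terminal domain spans three
residues, L10–P12) is detectable while single conserved columns are not
reported as boxes. Recovering a specific published box set A–F is a
tuning exercise against that paper's alignment and is deliberately not a
test.

Non-standard letters (B, Z, U, O, J) are folded to X with a warning; X
never matches a motif class and is tallied like any residue in profiles.

# Motif scanning

Patterns are ordered element lists; an element is a residue-class set or
a wildcard. `"[ST]xx[ST]"`, `"(S/T)xx(S/T)"` and `"S/T-x-x-S/T"` compile
identically. Two consensi recur in the SPS literature and in the test
suite: the casein-kinase-1 substrate motif `(S/T)xx(S/T)` and the
PP2A-B56/Rts1 docking motif `(L/F/M)xx(I/V/L)xE`.

Design choices:

* **Overlapping hits are counted.** CK1 sites genuinely overlap (a
  priming phosphate at position *i* creates a site at *i+3*); a scanner
  that suppressed overlaps would miss half of a TYGT/TGAS pair.
* **Region semantics**: a hit belongs to a region when its *start* lies
  inside it and the window fits in the sequence. This makes "scan the
  prodomain, residues 1–381" well-defined for motifs that straddle the
  boundary.
* **Ortholog conservation** (`scan_alignment_conservation()`): for each
  reference hit the spanning alignment columns, widened by ±2 reference
  residues (`slack`), are extracted per ortholog row, ungapped and
  re-scanned. The slack absorbs small indel-induced shifts; a motif that
  drifted one residue in an ortholog still counts. The conservation call
  is `ortholog_fraction >= threshold` (default 0.5).
* X in a sequence never matches a class; case is ignored.

Published motif *counts* (15 CK1 motifs in a 381-residue prodomain, 4
docking motifs in a 678-residue adaptor) are convention-sensitive
(overlap counting, scanned boundaries); the package pins the conventions
above and the acceptance tests assert the counts only on the actual
accession sequences.

# Structure contacts

Structure models are flat heavy-atom tables with author numbering (which
for AlphaFold models equals UniProt numbering) and an optional per-residue
confidence (pLDDT) read from the temperature-factor column.

All interaction criteria are **distance-only**. Predicted models carry no
hydrogens, so angular hydrogen-bond terms would be fiction; instead:

* **Salt bridges** (default 4.5 Å): minimum distance between
  charged-group atoms — Lys NZ; Arg NE/NH1/NH2; His ND1/NE2 versus Asp
  OD1/OD2; Glu OE1/OE2. The published distances this convention is meant
  to reproduce are in the 3–4.2 Å range, and the acceptance test records
  whether the charged-group minimum (the standard reading) or an
  all-side-chain-heavy-atom fallback reproduces them.
* **H-bond proxies** (default 3.6 Å): any N/O heavy-atom pair, side chain
  or backbone. The cutoff covers the largest published H-bond in the
  target models (3.1 Å) with margin. In exhaustive scans,
  sequence-adjacent residue pairs are excluded because the peptide bond
  places backbone N/O atoms trivially close; explicitly requested pairs
  are always measured.
* **π–π stacking** (default 5.5 Å): ring-centroid distance between
  F/Y/W/H rings (full indole for Trp, imidazole for His).
* **Clusters**: single-linkage components over side-chain contacts
  (hydrophobic: A/V/L/I/M/F/W/Y/P at 4.5 Å) or Cys SG contacts (4.0 Å —
  wide enough to capture a metal-binding cluster with ~3.5 Å S–S
  spacing). Determinism is guaranteed by processing residues in
  (chain, residue-number) order; `max_internal_gap` is the largest
  nearest-neighbour distance inside a cluster.

**Track segmentation** (`segment_track()`) finds maximal runs on one side
of a threshold after optional centred moving-average smoothing (odd
window; partial windows at the edges). `above` means ≥ and `below` means
≤; both are non-strict so that a track sitting exactly at threshold is
treated consistently by the two directions. Runs break at gaps in residue
numbering. Typical use: disorder tracks at threshold 0.5 to call IDRs,
pLDDT tracks at 70 with `below` to call low-confidence segments.

# Mutation mapping and interfaces

`neighborhood()` reports residues whose minimum side-chain heavy-atom
distance (all-heavy fallback for glycine, which has no side chain) to a
centre residue is within a radius (default 5 Å), annotated with the typed
edges they share with the centre. Published descriptions of mutant sites
use qualitative language ("adjacent", "pointing toward"), so radii are
decisions, and structure-anchored neighbourhood claims are membership
claims, not distance claims. Mutant structures are never modelled — the
report describes the wild-type environment of the mutated site.

`interface_contacts()` reports cross-chain residue pairs with
any-heavy-atom minimum distance within 4.5 Å (a 5.0 Å option exists
because qualitative "within range" language implies looser contacts).
Each pair is typed by the specific classifiers in the order salt bridge →
H-bond → π–π, then `hydrophobic_contact` when both side chains are
hydrophobic, else `generic`.

The packaged mutant catalog (`mutant_catalog()`) records the
receptor/adaptor/protease point mutants discussed in the SPS literature
with phenotype tags (7 receptor gain-of-function mutants, one
hypo-responsive, adaptor gain/loss-of-function pairs, protease
gain-of-function). Two further constitutive positions in the protease
prodomain (L126, V129) are known only as positions, not substitutions, so
they are described here rather than listed in the catalog, whose schema
requires a full wild-type→mutant label.

# The 8-state equilibrium model

The receptor is modelled as an alternating-access transporter that cannot
complete the transport cycle: four conformations (outward open, occluded,
inward-facing occluded, inward open), each with or without bound ligand,
give states A–H. Seven reversible reactions connect them; the
ligand-bound inward-facing-occluded ↔ inward-open step (D ↔ H), which a
true transporter needs, is *structurally absent* — an absent edge, not a
zero rate. With that edge removed, the reaction graph is a spanning tree,
so equilibrium populations are path products of the edge constants
normalized to 1, and no thermodynamic cycle constraint arises. The
inward-facing occluded states D (ligand-bound) and F (ligand-free) are
the signalling states; the observable is `f_D + f_F`.

The signalling fraction is a hyperbola in extracellular ligand
`L`: `S(L) = (aL + b)/(cL + d)` with `a = K1·K2·K3`, `b = K4·K5`,
`c = K1(1 + K2 + K2·K3)` and `d = 1 + K4(1 + K5 + K5·K6 + K5·K6·K7·L_in)`.
Hence basal = `b/d`, plateau = `a/c`, and EC50 = `d/c` exactly.
`dose_response()` finds the EC50 independently by bisection (relative
tolerance 1e-9) and the test suite requires agreement with the closed
form to 1e-6 — a deliberate dual-route check. Intracellular ligand enters
only through `d`, so raising `L_in` provably raises the EC50 and lowers
the basal signal: cytosolic ligand is an uncompetitive inhibitor of
signalling in this topology.

No numeric equilibrium constants have been published for this system;
the defaults (`K2 = 3`, `K3 = 5`, `K4 = 0.002`, `K5 = 10`, `K6 = 5`,
`K7 = 0.05 µM⁻¹`, `L_in = 0`) put the sensor in a low-basal,
ligand-responsive regime in which the mutant-class predictions are
unambiguous, and `K1 = 0.00492 µM⁻¹` is fixed so that the wild-type EC50
`d/c` is ≈ 12 µM — the published potency of the strongest-sensed amino
acid (leucine) for this receptor. All regime-dependent statements are
labelled as such.

```{r}
p <- state_params()
ec50_closed_form(p)           # ~12 uM by construction of K1
solve_equilibrium(p)          # ligand-free: small basal f_F
```

Mutant classes are modelled as multiplicative perturbations:
`"extracellular-gate"` (K2 ×5, K4 ×5) raises the basal signal and lowers
the EC50 — the constitutive + hyper-responsive gain-of-function class;
`"TM1-loop-block"` (K2 ÷100, K4 ÷100) does the opposite — the
hypo-responsive class with strongly reduced basal signal. Under
simultaneous K2/K4 changes the EC50 direction is regime-dependent (K4
raises the numerator `d`, K2 raises the denominator `c`); the defaults
keep all K4 terms ≪ 1 so the K2 effect dominates. This is a property of
the chosen regime, documented rather than hidden.

```{r}
perturb_and_compare(p, preset = "extracellular-gate")
perturb_and_compare(p, preset = "TM1-loop-block")
```

Open modelling questions resolved by decision: states D and F are given
equal signalling efficacy (no published weighting exists; the observable
is their plain sum), and no direct D ↔ F ligand-release step is modelled
because the state scheme draws none. Binding is single-site with activity
equal to concentration. Kinetics are out of scope — the model is an
equilibrium description, which is all the published scheme proposes.

# Synthetic data: what it emulates and what it does not

The generators produce *stated worlds* with machine-readable truth:

* `synth_alignment()`: uniform-background rows; boxes copy the reference
  residue down each column with per-row corruption `1 − identity_level`;
  motif windows are satisfied in an exact, rounded fraction of ortholog
  rows, and non-carrier rows are blocked with a letter outside every
  pattern class across the window ± slack, so planted fractions are exact
  by construction. No indels are generated, so columns equal reference
  positions.
* `synth_structure()` / `synth_complex()`: residues use idealized
  one-rotamer templates on a 40 Å-spaced line (chains offset by 120 Å);
  each planted contact rigid-translates the partner residue along a
  direction in which the contact-defining atoms are extremal, so the
  scoped distance equals the request exactly and no other scoped pair of
  that residue pair is closer. Un-planted residue pairs stay > 8 Å apart.
* `synth_track()`: piecewise-constant levels plus Gaussian noise, clipped
  to the track range.

These fixtures establish *algorithmic correctness* (detectors recover
exactly what was planted; scanners equal brute-force oracles), not
biological realism: there is no backbone continuity, no rotamer
variation, no alignment indels, no correlated conservation. A green test
means the operations implement their definitions, not that the
definitions recover biology; the accession-dependent acceptance tests
carry that burden and require the real inputs.

# Numerical choices and degenerate inputs

* PDB coordinates are written at 0.001 Å precision; round-trip tests
  compare at that tolerance.
* Minimum-distance searches are exact (no spatial pruning); models of
  interest are single proteins, where the O(n²) atom-pair scan is
  negligible.
* An empty sequence or an empty contact plan yields empty results, not
  errors; a missing residue, an empty atom scope (e.g. side-chain scope
  on glycine), a ragged alignment, or an unknown reference row are
  errors.
* Equilibrium weights are positive path products with `w_A = 1`, so the
  normalizing sum is never zero and fractions are exact to floating
  point; the fraction-sum invariant is tested at 1e-12.
* EC50 bisection brackets by decade expansion from [0, 1] and stops at a
  relative width of 1e-9.

# Known limitations

* The Clustal reader accepts the common dialect (header line + name/
  sequence blocks); exotic variants should be converted to aligned FASTA.
* H-bond detection without hydrogens cannot distinguish donors from
  acceptors; an N···N pair at 3.5 Å counts. This matches the resolution
  of the models analysed, not chemistry.
* The mmCIF reader handles the `_atom_site` loop only — sufficient for
  AlphaFold DB and PDB-derived coordinate files, not a general STAR
  parser.
* Accession-anchored results (motif counts, conservation counts, model
  distances) require the UniProt/AlphaFold/supplementary inputs, which
  are not redistributable with the package; the acceptance tests document
  the drop-in location (`inst/extdata/accessions/`) and fail honestly
  without them.
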