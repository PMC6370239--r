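---
title: "Quantifying inherent and induced protein flexibility with apoflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inherent and induced protein flexibility with apoflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

When a ligand binds a protein, how much of the conformational change we
observe is *induced* by binding, and how much is just the *inherent*
wobble that any ensemble of crystal structures of the same protein shows?
Answering this requires three comparison classes within families of
sequence-identical structures: apo–apo pairs (inherent variation of the
unbound state), holo–holo pairs (inherent variation of the bound state),
and apo–holo pairs (inherent plus induced variation). `apoflex`
implements the full analysis chain — curation, unified binding sites,
backbone and side-chain flexibility metrics, solvent accessibility, and
family-level statistics — together with a synthetic-structure generator
that plants exactly known ground truth, so every stage is testable
without downloading a single structure.

## Data model and curation

A **family** is a set of crystal structures sharing 100 % sequence
identity across all chains (exact string equality, both directions). An
optional merge pass joins families whose sequences differ only by
N-/C-terminal extensions; families differing anywhere in the core are
never merged. True family curation in the literature involved manual
judgment of a 95 %-identity clustering; the terminal-extension rule is
this package's deterministic approximation of that intent.

Structures pass through the following filters, in a fixed order that is
part of the contract (holo filtering → unified sites → apo filtering):

* **Holo validity** — resolution ≤ 2.5 Å; exactly one biologically
  relevant ligand (multi-HET ligands count as one molecule); no
  additional non-water molecule in the binding site. The last rule is
  operationalised as: no non-water, non-ligand HET heavy atom within the
  contact cutoff of any ligand heavy atom.
* **Apo validity** — every non-water HET must have molecular weight
  ≤ 100 g/mol or be on the permissible-HET allow-list; no non-water HET
  heavy atom within the contact cutoff of any unified-site residue
  resolvable in that structure. Waters are always permitted.
* **Membership** — after filtering, a family needs at least two apo and
  two holo members or it is dropped entirely.

Every rejection is logged as a decision record with machine-readable
reason codes (`RESOLUTION`, `MULTI_LIGAND`, `SITE_CONTAMINATION`,
`HET_DISALLOWED`, `NO_FAMILY`, `RENUMBER_FAIL`), and reruns are
bit-reproducible.

Within a family, a **reference numbering** is assigned by choosing the
best-resolved member (ties broken by smallest PDB id) and mapping every
member chain onto a reference chain by Needleman–Wunsch global alignment
(match +1, mismatch −1, gap open 10, gap extend 0.5 — Needle-like
defaults; with 100 %-identical sequences the scores matter only for
chain-assignment tie-breaks, which fall back to chain-id order). A
member with any aligned residue-name mismatch, or two chains claiming
overlapping stretches of one reference chain, is discarded as
ambiguous (`RENUMBER_FAIL`) rather than hand-fixed.

Crystallographic realities are handled with two policies. Alternate
locations: keep the copy with the strictly highest occupancy, first
listed on ties. Missing density: backbone RMSD uses the per-pair
intersection of resolved Cα positions; a residue whose χ1-critical atoms
(N, CA, CB, γ) are missing in *any* member — or which is missing
entirely — is removed from the χ1 analysis for all structures in that
family, so every range is computed over the same observation set.

## Unified binding sites

A residue belongs to a structure's binding site iff the minimum distance
between any of its heavy atoms and any ligand heavy atom is ≤ 4.5 Å
(inclusive boundary, hydrogens never considered). The family's **unified
binding site** is the union of these contact sets over all accepted holo
members, expressed in reference numbering. The 4.5 Å default captures
both hydrogen bonding and van der Waals contact distances. The
implementation prefilters candidates with a bounding box but is tested
bit-equivalent to the all-pairs double loop.

## Flexibility metrics

**Backbone.** For every unordered pair of members the package computes
the least-squares-superposed RMSD over shared Cα atoms (Kabsch
algorithm; proper rotation enforced; fewer than three shared Cα flags
the pair and excludes it from maxima rather than contributing a zero).
Each family contributes one value per pairing class — its **maximum**
RMSD — chosen to surface proteins capable of large conformational
change; dataset tables then report averages and medians of those family
maxima. Site-restricted RMSD is also computed; because the frame of that
fit is genuinely underdetermined by the prose it re-implements, the
default superposes on the site Cα subset itself (a local fit isolates
site deformation from global domain motion) and a `site_fit = "global"`
configuration flag provides fit-globally-measure-locally as the
alternative.

**Side chains.** χ1 = torsion(N, CA, CB, γ) with γ = SG (Cys), OG (Ser),
OG1 (Thr), CG1 (Ile, the longer carbon chain), CG otherwise. Valine is
γ-symmetric and contributes both angles as two observation streams
(`primary` = CG1, `valine_alt` = CG2), kept separate by default with a
`merge_val` flag; Gly, Pro and Ala have no χ1. Flexibility of a residue
across a structure set (apo, holo, or apo+holo) is the **minimal
circular range**: the smallest arc containing all observed angles,
computed as 360° minus the largest gap between circularly adjacent
angles. Angles 30°, 45° and 100° give a range of 70°; a single
observation gives 0; the definition is invariant to a global rotation of
all angles. The combined apo+holo range is by construction at least the
larger single-set range; the *excess* over that maximum is the
signature of induced displacement.

**SASA.** Shrake–Rupley quadrature with a 1.4 Å probe and 960 test
points per atom, generated on a deterministic golden spiral (no RNG, so
areas are exactly reproducible and rotation-invariant to quadrature
noise). Radii are the NACCESS-style Chothia set (C 1.87, N 1.65, O 1.40,
S 1.85 Å), kept in a config table. SASA is computed for all protein
residues after removing hydrogens, waters, ligands and every other HET
group, then the unified-site residues are extracted and summed. The
family statistic is ΔSASA = max(holo site SASA) − min(apo site SASA),
so a negative value means the site buries surface upon binding.

## Statistics

Family summaries (one row per family) feed Wilcoxon signed-rank tests on
the paired per-family values: maximum RMSD apo-apo vs holo-holo, apo-holo
vs each single class, and average χ1 range apo vs holo plus combined vs
each single set. Zero differences are dropped before ranking (Wilcoxon's
original treatment; the count is reported). For ≤ 12 retained pairs the
two-sided p-value comes from exact enumeration of all sign assignments
over the midranks — exact even under ties — and above that from the
normal approximation with tie and continuity correction. Correlation
screens report squared Pearson correlations of the flexibility maxima
against mean ligand mass and mean resolution; degenerate screens
(constant input) report missing values, never zero.

Confidence bands use subsample jackknifing: 1000 resamples without
replacement at 90 % of the data size, with the 2.5/97.5 percentiles of
the resampled statistic as the 95 % band. Per-amino-acid flexibility
profiles are cumulative distributions of per-residue χ1 ranges
(apo+holo set, each unique residue counted once); classes are assigned
at the 40° threshold by chaining types whose 95 % intervals overlap into
groups — the most rigid group is `rigid`, the least `very_flexible`,
anything between `semi_flexible`, and a single undivided group is
labelled by its absolute level (≥ 2/3 rigid, ≤ 1/3 very flexible). The
grouping rule is this package's operationalisation; the classification
threshold and bin width (10° occupancy histograms, each unique residue
weighted equally regardless of family size) are configurable.

## The synthetic-data generator

`make_ideal_chain()` builds peptides with ideal bond lengths/angles at
requested φ/ψ (α-helical by default) and side chains reduced to CB plus
the γ atoms that define χ1 — sufficient for every metric in the package
while keeping fixtures tiny. `set_chi1()` rotates distal atoms about
CA–CB to an exact target angle; `perturb_backbone()` displaces residues
rigidly along a sum of low-frequency sinusoids (protein-like collective
deformation, side-chain torsions untouched) rescaled until the achieved
Cα RMSD matches the target within 0.1 %. Ligands are rigid carbon
fragments placed a controlled distance outward from target residues;
decoy HETs can be planted near the site or remote, with metadata
weights.

Coordinates are snapped to the PDB fixed-column 0.001 Å grid **before**
ground truth is measured, so the manifest (unified-site membership,
pairwise RMSDs, per-set χ1 ranges, expected curation decisions) is
reproduced by the pipeline to 10⁻⁶ from the written files. Manifest
site and χ1 truths are measured over the members that survive curation,
since planted decoy carriers never enter the analysed sets.

The default cohort encodes the study conditions the analysis assumes:
2–4 apo and 2–4 holo members per family, chain lengths 28–34, backbone
displacement drawn from the *same* |N(0.5 Å, 0.15 Å)| distribution for
both roles (equal inherent flexibility), within-state χ1 noise of 8°
around a rotamer-well base angle, and an induced +120° shift of the holo
base for 30 % of site residues. Under these conditions the pipeline
reproduces the qualitative statistical pattern of interest: no apo/holo
difference (p > 0.05) but a strongly significant combined-vs-single-set
difference (p < 0.0001). Test and acceptance runs use 10–24 families of
these sizes, which keeps a full run in minutes while leaving the paired
tests well powered.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: crystallographic noise and B-factor
structure, realistic ligand chemistry and shape, correlated side-chain
rotamer libraries, multi-domain motion, alternative space groups or
biounit assembly, and sequence redundancy between families. The
generator validates the *machinery*; dataset-scale biological numbers
require real structures.

## Numerical choices and degenerate inputs

* Angles are stored in [−180°, 180°) (planar trans maps to −180°);
  ranges live in [0°, 360°). Torsions follow the standard biomolecular
  sign convention, cross-checked against an independent projection
  formula and a second implementation.
* Kabsch superposition requires ≥ 3 points and rejects collinear sets
  (rotation not unique) instead of returning an arbitrary frame.
* Distance-rule boundaries are inclusive (d ≤ cutoff counts as
  contact).
* Family maxima over a class with only flagged pairs are missing values,
  never zero; missingness propagates, it is never imputed.
* Reference-structure choice, chain assignment and report row order all
  have deterministic tie-breaks, so reruns are byte-identical.
* All fixture randomness flows from a single integer seed; derived seeds
  stay below 2³¹.

## Limitations

The package analyses χ1 only — motion confined to distal χ angles is
invisible by design, the accepted trade-off for robustness against
nitrogen/oxygen flip ambiguity and poor distal density. NACCESS itself
uses a z-slice integration, so absolute SASA values differ slightly from
this package's Shrake–Rupley quadrature (family-level comparisons are
insensitive to this). Biounit generation from symmetry operators is not
performed: the input file is taken as the assembly, with only the first
MODEL used. mmCIF input, pocket detection without a ligand, and
rotamer-library classification are out of scope.
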