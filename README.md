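# apoflex

Quantifying inherent versus ligand-induced protein flexibility from
families of apo (ligand-free) and holo (ligand-bound) crystal
structures.

## The problem

A single apo/holo comparison cannot tell whether an observed
conformational difference was *caused* by ligand binding or is just the
spread any ensemble of crystal structures of the same protein shows.
Separating the two requires families of sequence-identical structures
with several members of **both** states, and three pairing classes:

* apo–apo pairs — inherent variation of the unbound state,
* holo–holo pairs — inherent variation of the bound state,
* apo–holo pairs — inherent **plus** induced variation.

`apoflex` implements the full analysis for structural bioinformaticians
and docking-method developers who want this decomposition on their own
structure sets:

* **Curation** — 100 %-sequence-identity families with a shared
  reference numbering (Needleman–Wunsch chain mapping), resolution
  cutoff (≤ 2.5 Å), single-ligand rule, HET allow-list / ≤ 100 Da rule,
  and a 4.5 Å binding-site contamination rule, all logged as
  machine-readable decisions.
* **Unified binding sites** — the union of all residues within 4.5 Å of
  any valid ligand across all holo members of a family (hydrogens never
  considered, boundary inclusive).
* **Backbone flexibility** — per-pair Cα RMSD after least-squares
  (Kabsch) superposition; each family summarised by its *maximum* RMSD
  per pairing class:

  `RMSD = sqrt( (1/N) * Σᵢ ||yᵢ − (xᵢ·R + t)||² )`, minimised over all
  proper rotations `R` and translations `t`.

* **Side-chain flexibility** — χ1 = torsion(N, CA, CB, γ) per
  binding-site residue, summarised per structure set (apo, holo,
  apo+holo) as the *minimal circular range*: 360° minus the largest gap
  between circularly adjacent observed angles. Angles {30°, 45°, 100°}
  have range 70°. Valine contributes both γ angles; Ile uses the longer
  chain (CG1); Gly/Pro/Ala have no χ1.
* **SASA** — Shrake–Rupley accessible surface (1.4 Å probe, 960
  deterministic golden-spiral points per atom, Chothia radii) of the
  unified-site residues; per family,
  `ΔSASA = max(holo site SASA) − min(apo site SASA)`.
* **Statistics** — Wilcoxon signed-rank tests on paired per-family
  values (exact sign-assignment enumeration up to n = 12, ties handled
  exactly), 1000 × 90 % subsample-jackknife confidence bands,
  per-amino-acid cumulative flexibility profiles with
  rigid / semi-flexible / very-flexible classes at a 40° threshold, and
  R² screens against ligand mass and resolution.
* **Synthetic data** — `make_ideal_chain()` / `set_chi1()` /
  `perturb_backbone()` / `make_cohort()` generate PDB-format families
  with exactly known ground truth (planted RMSDs, χ1 ranges, site
  membership, curation decoys), so the whole pipeline is testable
  offline.

## Worked example

```r
library(apoflex)

chi1_range(c(30, 45, 100))
#> [1] 70

bundle <- file.path(tempdir(), "demo")
make_cohort(bundle, n_families = 4, seed = 7)   # writes PDBs + metadata
res <- run_pipeline(default_config(bundle, seed = 7))

res$summaries[, c("family_id", "n_apo", "n_holo", "rmsd_max_AA",
                  "rmsd_max_HH", "rmsd_max_AH", "site_size",
                  "delta_sasa")]
#>  family_id n_apo n_holo rmsd_max_AA rmsd_max_HH rmsd_max_AH site_size delta_sasa
#>       F001     2      2       0.671       0.634       0.711         8       8.37
#>       F002     4      3       1.052       0.825       0.989         8      56.16
#>       F003     3      4       0.847       1.038       0.939        10      21.48
#>       F004     3      3       0.530       0.852       0.726        10      22.34

res$dataset[res$dataset$metric %in%
              c("chi1_mean_apo", "chi1_mean_holo", "chi1_mean_apo_holo"), ]
#>              metric average median n
#>       chi1_mean_apo   6.528  6.322 4
#>      chi1_mean_holo   5.716  5.045 4
#>  chi1_mean_apo_holo  19.140 19.476 4

res$tests[, c("comparison", "statistic", "p_value", "n")]
#>             comparison statistic p_value n
#>          rmsd_AA_vs_HH         4   0.875 4
#>          rmsd_AH_vs_AA         8   0.375 4
#>          rmsd_AH_vs_HH         5   1.000 4
#>       chi1_apo_vs_holo         7   0.625 4
#>   chi1_combined_vs_apo        10   0.125 4
#>  chi1_combined_vs_holo        10   0.125 4
```

Reading the output: each family contributes one maximum RMSD per pairing
class (here all under ~1 Å — backbones barely move) and one average χ1
range per structure set. The apo and holo χ1 ranges are similar (≈ 5–7°)
while the combined apo+holo range jumps to ≈ 19°: side chains are pushed
to orientations outside the range either state samples on its own. With
only 4 families the paired tests are underpowered; at the default cohort
size (24 families) the combined-vs-single-set comparisons reach
p < 10⁻⁴ while the apo-vs-holo comparisons stay non-significant, the
signature of induced side-chain flexibility on a rigid backbone.

`run_pipeline()` also writes a report bundle (summaries, pair scores,
χ1 tables, SASA, decisions, profiles, `stats.json`) when
`default_config(..., output_dir = )` is set, and
`inst/scripts/apoflex-cli.R` wraps `generate`/`run` for shell use.

## Layout

```
R/                 structure model, curation, binding sites, geometry,
                   SASA, statistics, synthetic generator, pipeline
tests/testthat/    unit + property tests with independent oracles
scripts/           acceptance.R (see above)
vignettes/         methods vignette: model, assumptions, parameters,
                   numerical choices, limitations
inst/scripts/      command-line wrapper
```
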