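# pepqa — quality assessment of peptide–protein docking models

`pepqa` scores models of peptide–protein complexes against a reference
(crystal) structure the way the CAPRI experiment assesses its peptide
targets, and adds two side-chain-aware measures that the standard
criteria miss. It is aimed at people who build or benchmark peptide
docking protocols and want a self-contained, scriptable assessor.

## The measures and the classification

With the complex partitioned into a **receptor** and a **peptide**
(ligand), the package computes per model:

- **fnat** — fraction of native cross-interface residue contacts
  recovered. A contact is any receptor–peptide residue pair with a
  heavy-atom pair `< 4.0 Å`; interface residues are those with CB
  (CA for Gly) `< 8.0 Å` across the partition; atomic clashes are
  heavy-atom pairs `< 3.0 Å` (reported, never disqualifying).
- **L-RMSD** — RMSD of peptide backbone atoms `{N, CA, C, O}` after
  least-squares (Kabsch) superposition on receptor backbone atoms.
- **I-RMSD** — backbone RMSD over interface residues, fit on those
  same atoms; the interface is always defined on the reference.
- **S-RMSD** — interface *side-chain* RMSD: same superposition frame
  as I-RMSD, evaluated over side-chain heavy atoms, with
  symmetry-equivalent atom names (Phe/Tyr ring, Asp/Glu carboxylates,
  Arg NH, Leu/Val methyls) resolved per residue to the minimum.
- **fnat_hb** — fraction of native cross-interface hydrogen bonds
  (including short-range salt bridges) recovered, using a geometric,
  HBplus-style detector (donor–acceptor `< 3.9 Å`, angles `> 90°`,
  H–acceptor `< 2.5 Å` with ideally placed polar hydrogens; salt
  bridges up to `4.0 Å`).

Models are classified High / Medium / Acceptable / Incorrect from
(fnat, L-RMSD, I-RMSD):

| Class | Criterion |
|---|---|
| High | fnat ≥ 0.8 & (L ≤ 1.0 Å ∨ I ≤ 0.5 Å) |
| Medium | fnat ∈ [0.5, 0.8) & (L ≤ 2.0 ∨ I ≤ 1.0) ∨ fnat ≥ 0.8 & L > 1.0 & I > 0.5 |
| Acceptable | fnat ∈ [0.2, 0.5) & (L ≤ 4.0 ∨ I ≤ 2.0) ∨ fnat ≥ 0.5 & L > 2.0 & I > 1.0 |
| Incorrect | the rest |

A parametric **refined scheme** (`classify_refined()`) loosens the
backbone RMSD thresholds by a fixed amount while awarding a class only
when S-RMSD stays under a per-class cap — so models with borderline
backbones but well-modeled side chains can be promoted, and never
demoted. The default loosening (0.5 Å) and caps (0.5/1.0/2.0 Å) are
this package's placeholders; the calibration is an open question.

The hotspot module consumes per-residue ΔΔG tables from any
computational alanine-scanning predictor (Robetta/FoldX/mCSM-style TSV
exports), flags **hotspots** at ΔΔG ≥ 0.95 (≈ kcal/mol, inclusive),
aggregates per-residue **hit rates** over model ensembles, builds
recovery histograms against a reference hotspot list, and writes hit
counts into PDB B-factors for surface rendering.

Everything is exercisable without downloads: `make_toy_complex()`
builds idealized peptide–receptor complexes from internal coordinates,
`perturb()` generates rigid / side-chain / mixed model ensembles, and
`make_ddg_ensemble()` plants hotspots with controlled noise.

## Worked example

```r
library(pepqa)

ref <- make_toy_complex(seed = 1)            # toy reference complex
models <- c(
  perturb(ref, "rigid", translation = 0.4,  n_models = 2, seed = 2),
  perturb(ref, "mixed", translation = 2.8, chi_noise_deg = 25,
          n_models = 2, seed = 3),
  perturb(ref, "rigid", translation = 10,   n_models = 2, seed = 4)
)
res <- assess_models(ref, models)
res[, c("model_id", "fnat", "fnat_hb", "l_rmsd", "i_rmsd", "s_rmsd",
        "class", "class_refined")]
```

```
   model_id  fnat fnat_hb l_rmsd i_rmsd s_rmsd      class class_refined
1 model_001 1.000   0.875    0.4  0.176   0.18       High          High
2 model_002 1.000   0.938    0.4  0.176   0.18       High          High
3 model_001 0.625   0.375    2.8  1.229   1.56 Acceptable    Acceptable
4 model_002 0.875   0.188    2.8  1.229   1.42     Medium        Medium
5 model_001 0.167   0.000   10.0  4.390   4.49  Incorrect     Incorrect
6 model_002 0.250   0.000   10.0  4.390   4.50  Incorrect     Incorrect
```

Small rigid displacements keep all native contacts (fnat 1, class
High); at ~2.8 Å the models straddle Medium/Acceptable and lose most
hydrogen bonds (fnat_hb drops faster than fnat); at 10 Å everything is
Incorrect. Rank correlations between the measures, with `tidy()` /
`autoplot()` views:

```r
cors <- metric_correlations(res)
round(cors$rho, 2)
#>          fnat fnat_hb l_rmsd i_rmsd s_rmsd
#> fnat     1.00    0.91  -0.96  -0.99  -0.93
#> fnat_hb  0.91    1.00  -0.99  -0.87  -0.87
#> l_rmsd  -0.96   -0.99   1.00   0.91   0.91
#> i_rmsd  -0.99   -0.87   0.91   1.00   0.94
#> s_rmsd  -0.93   -0.87   0.91   0.94   1.00
```

A command-line front end mirrors the R API
(`inst/cli/pepqa.R`: `simulate`, `assess`, `contacts`, `hbonds`,
`classify`, `hitmap`), e.g.

```sh
Rscript inst/cli/pepqa.R simulate --out-dir fx --seed 3 --n-models 10
Rscript inst/cli/pepqa.R assess fx/REF.pdb fx/model_*.pdb --out metrics.tsv
```

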