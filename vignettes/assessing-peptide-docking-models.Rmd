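---
title: "Assessing peptide-protein docking models with pepqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing peptide-protein docking models with pepqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepqa)
```

## The problem

Peptide–protein interactions are typically mediated by a short linear
motif binding a well-defined pocket. When such complexes are modeled by
docking, "how good is this model?" has a sharper edge than in
protein–protein docking: the applications that matter — spotting the
hydrogen bonds that confer specificity, or the hotspot residues whose
mutation abolishes binding — live in the side chains of a handful of
interface residues. `pepqa` implements the standard CAPRI peptide
assessment together with two side-chain-aware measures and an ensemble
hotspot analysis, as a tested library plus a thin CLI, runnable
entirely on synthetic fixtures.

## Measures

The complex is partitioned into receptor chains and peptide chains.
All distances are in Angstrom, all cutoffs on the interface detectors
are *strict* inequalities (a CB pair at exactly 8.0 Å is not interface),
and all metrics use heavy atoms only — CAPRI practice, and most models
carry no hydrogens. An `include_hydrogens` knob exists on the contact
detectors for sensitivity analysis.

* **Interface residues**: CB (CA for glycine) within `< 8.0` of a CB/CA
  across the partition. Non-glycine residues missing CB fall back to CA
  with a warning.
* **Contacts (fnat)**: residue pairs with any heavy-atom pair `< 4.0`,
  counted once per residue pair. `fnat` is the fraction of *reference*
  contacts whose mapped residue pair is also a model contact — the
  denominator is always the native set, so spurious model contacts
  never help.
* **Clashes**: cross-partition heavy-atom pairs `< 3.0`, atom-based
  (every qualifying pair counts). Reported only; the classification
  never disqualifies on clashes. Note that a native hydrogen bond at
  2.9 Å is, by this definition, also a clash — the count is a roughness
  indicator, not an error count.
* **L-RMSD**: the model is superposed on the reference using paired
  receptor backbone atoms {N, CA, C, O} (Kabsch, proper rotations
  only), and the RMSD is evaluated over paired peptide backbone atoms
  under that transform. No refit on the peptide: the measure mixes
  placement and internal-geometry error, by design.
* **I-RMSD**: fit and evaluate on backbone atoms of the
  reference-defined interface. The model's own interface is never used;
  the native structure defines *the* interface.
* **S-RMSD**: evaluated over side-chain heavy atoms of those same
  interface residues, *in the I-RMSD superposition frame*. The
  backbone frame is reused rather than refit on side chains — the two
  readings of "calculated in the same way as I-RMSD but for side
  chains" differ here, and the frame-sharing reading makes S-RMSD a
  clean measure of side-chain placement given the backbone;
  `refit_sidechain = TRUE` gives the other reading for sensitivity
  analysis. Chemically indistinguishable atom namings (Phe/Tyr
  CD1↔CD2 + CE1↔CE2 jointly, Asp OD1↔OD2, Glu OE1↔OE2, Arg NH1↔NH2,
  Leu CD1↔CD2, Val CG1↔CG2) are resolved per residue to the minimum
  summed squared deviation, so a 180° ring flip costs nothing. His is
  never swapped: its two ring nitrogens are distinguishable.
* **fnat_hb**: fraction of native cross-interface hydrogen bonds
  recovered, matched by donor/acceptor atom identity (a `residue`
  matching mode exists for threaded models). `NA` when the reference
  has no cross-interface bonds — a data problem, not a zero.

### Hydrogen-bond detection

Bonds are detected geometrically in the HBplus tradition:
donor–acceptor `< 3.9`, donor–hydrogen–acceptor angle `> 90°` with
hydrogen–acceptor `< 2.5` where a hydrogen is available, and
donor–acceptor–antecedent angle `> 90°`. Explicit hydrogens are used
when present (matched within 1.3 Å of the donor); otherwise polar
hydrogens are placed by ideal geometry for donors whose H position is
determined by heavy atoms (backbone N via the bisector rule, Arg, the
amide NH2 groups of Asn/Gln at ±120° in the sp2 plane, Trp, His).
Rotatable donors (Ser/Thr/Tyr hydroxyls, Lys ammonium) would need a
dihedral search, so they are judged on the heavy-atom criteria alone —
deterministic, slightly permissive. Charged-donor to carboxylate-oxygen
pairs (Lys/Arg/His → Asp/Glu) within `4.0` are flagged and counted as
short-range salt bridges, with only the antecedent-angle check: a salt
bridge is an electrostatic contact, not a directional bond, and the
conventional treatment relaxes the hydrogen criteria for it. All
thresholds are arguments. Exact agreement with any particular HBplus
build is not claimed; what the tests pin down is agreement with an
exhaustive independent implementation of these stated criteria.

## Classification

```{r}
classify_capri(data.frame(fnat = 0.83, l_rmsd = 0.39, i_rmsd = 0.35))
```

Clauses are evaluated best class first; fnat intervals are
lower-inclusive, so 0.8 is High-eligible and 0.5 Medium-eligible; RMSD
thresholds are inclusive. Two consequences worth knowing: a model with
fnat ≥ 0.8 is at worst Medium no matter how large its RMSDs (the
high-fnat Medium clause has no ceiling), and `Incorrect` is literally
"the rest". The `rule` column records which clause fired, for audit.

The refined scheme addresses a gap: backbone-accurate models can carry
badly placed side chains, and side-chain-accurate models can miss the
backbone thresholds narrowly. `classify_refined()` re-evaluates the
clauses with L-/I-RMSD thresholds loosened by `backbone_loosening` but
gates each class on `s_rmsd <= s_rmsd_caps[class]`, and never demotes
below the plain class. The defaults (0.5 Å loosening; caps 0.5, 1.0,
2.0 Å) are placeholders chosen to be conservative — the idea is
proposed as parametric; fixing the numbers would need a larger
benchmark than any toy fixture can provide.

```{r}
scheme <- refined_scheme()
classify_refined(
  data.frame(fnat = 0.85, l_rmsd = 1.2, i_rmsd = 0.6,
             s_rmsd = c(0.4, 2.0)),
  scheme
)[, c("class", "class_refined", "rule_refined")]
```

## Hotspot hit-rate analysis

The alanine-scanning predictors themselves are out of scope; the module
consumes their per-residue ΔΔG tables (TSV with `model_id, chain,
resnum, icode, wt, mut, ddg`; `read_ddg()` remaps other layouts). A
residue is a hotspot for a model iff ΔΔG ≥ 0.95 — inclusive, because
the cutoff itself is already backed off from 1.0 kcal/mol to absorb
predictor noise. Aggregation is per (chain, resnum, icode), not per
wild-type name, so threaded models aggregate correctly. `hit_rates()`
conserves counts (the sum of per-residue hit counts equals the total
number of flags) and is monotone in the cutoff; both properties are
tested. `recovery_histogram()` tabulates models by how many reference
hotspots they flag, with an optional crystal-structure baseline, and
`annotate_structure()` writes counts or rates into B-factors for
blue-to-red surface rendering. A display tier at 1.45 exists in
rendering conventions for "strong" hotspots; it plays no role in any
computation here.

## The synthetic fixture generator

`make_toy_complex()` builds both chains from idealized internal
coordinates (Engh–Huber-style bond lengths and angles, fully extended
backbone, NeRF chain construction) and lays the peptide strand into a
two-strand receptor groove (or against a single strand, `"flat"`) at a
5.0 Å axis separation — close enough that the antiparallel backbones
hydrogen-bond across the interface, β-ladder style. Construction
guarantees ≥ 5 cross-partition contacts and ≥ 1 cross-partition
hydrogen bond, and errors on specs that cannot satisfy them. Sequences
default to a seeded draw from an 18-residue alphabet (no Pro — its
ring constrains the backbone this builder idealizes away; no Cys — no
disulfide handling). χ1 is chosen per residue on a 30° grid to steer
side chains out of the strand plane; remaining χ default to extended
values.

What the generator emulates: realistic atom naming, chain/partition
structure, backbone hydrogen bonding, controllable model-quality
spectra (`perturb()`: rigid peptide motion, Gaussian χ noise, or both),
and hotspot ensembles with known ground truth (`make_ddg_ensemble()`:
hot mean 2.0, cold mean 0.0, noise SD 0.5 ≈ kcal/mol by default —
comfortably separated yet overlapping at realistic noise). What it does
not emulate: sterics (long side chains of facing strands can
interpenetrate — the metrics are geometry bookkeeping and do not care,
but do not feed these structures to a force field), rotamer libraries,
loop structure, bound-state induced fit, or any real binding site.
Passing tests therefore demonstrate the correctness of the *measures*,
not docking realism; the paper-scale correlation structure of real
CAPRI ensembles is not reproducible from toys, and the package makes no
claim to it.

## Numerical choices

* Cross-partition distances are computed from explicit coordinate
  differences, not the `|a|² + |b|² − 2a·b` expansion — the cutoffs are
  strict inequalities and the expansion's cancellation error can flip a
  boundary case.
* Kabsch uses base `svd()`; an improper optimal map is corrected by
  flipping the smallest singular direction, so reflections are never
  returned. Near-collinear atom sets warn and return the
  least-squares fit anyway. The test oracle is Horn's quaternion
  closed form — an independent algorithm, not a re-run.
* Altlocs resolve to highest occupancy, ties by file order; parsing is
  deterministic. MSE is rescued to MET. Waters and other HETATM are
  dropped.
* Residues are paired strictly by (chain, resSeq, iCode) through an
  explicit chain map; no sequence alignment is attempted. CAPRI
  submissions use target numbering, and silent alignment guesses are
  worse than a loud mismatch. Renumbered models are the caller's
  problem, and unpaired residues are reported.
* Residue-name mismatches keep backbone atom pairs and drop side-chain
  pairs: L-/I-RMSD still work on threaded models, S-RMSD honestly
  excludes what it cannot compare. Missing model side-chain atoms are
  skipped, not penalized; the correspondence records them.
* Seeded randomness everywhere (`withr::with_seed`), so ensembles and
  fixtures are byte-reproducible; fixture PDBs carry their spec and
  seed in REMARK 250.

Problem sizes throughout the test suite are deliberately small — toy
complexes of ~225 atoms, ensembles of tens to 200 models — chosen so
the whole suite exercises every code path in well under a minute while
the statistical checks (binomial tail bounds on hit rates) retain
power.

## Known limitations

* PDB only; no mmCIF, no structure repair, no protonation assignment.
* The hydrogen-bond detector is one reasonable parameterization of the
  HBplus criteria; counts on hydrogen-rich or unusual structures may
  differ from other implementations.
* The refined scheme's numbers are placeholders by design.
* Multi-interface assessment (a peptide binding two sites) is out of
  scope; one receptor/peptide partition per run.
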