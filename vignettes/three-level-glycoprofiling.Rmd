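---
title: "Methods: three-level N-glycoprofiling on synthetic LC-MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-level N-glycoprofiling on synthetic LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotriad)
```

## The measurement problem

A glycoprotein with a single sequon can still defeat any one MS
experiment. Released-glycan profiling (PNGase F release, reduction to
alditols, negative-mode PGC-LC-MS) quantifies glycan structures but is
protein- and site-blind, misses PNGase-F-resistant Asn-linked
HexNAc₁(Fucα1,6) stubs entirely, and pools glycans from every protein in
the preparation. Glycopeptide CID/ETD profiling is site-specific and sees
the stubs, but depends on proteolytic peptide context and on the equal-
ionization assumption. Intact-protein ESI-MS sees the whole proteoform —
sequence variant, oxidation and glycan together — but resolves only mass,
and its source conditions can strip labile glycans in-source, creating
artefactual aglycosylated signals. This package implements all three
levels and the reconciliation logic that lets them correct each other,
together with a synthetic-data generator that stands in for raw data that
were never deposited for this experimental design.

## The glycan model

Structures are compositions (Hex, HexNAc, dHex, NeuAc) plus flat linkage
annotations — core fucose, the mannose arm of bimannosyl species
(α1,3/α1,6), and sialyl linkage (α2,3/α2,6) — in three classes:
chitobiose stubs (HexNAc₁₋₂), paucimannose (HexNAc₂Hex₁₋₃, the M-series)
and monoantennary complex (HexNAc₃Hex₃₋₄NeuAc₀₋₁). Full tree topology is
deliberately not modelled: every piece of discriminating evidence the
pipeline consumes — mass, retention class, exoglycosidase response,
PNGase F releasability — is a function of composition plus these
annotations. The default panel is the 11-structure neutrophil granule
glycome (M0F; M1, M1F, M2, M2F, M3F; five monoantennary monosialylated
structures); α1,3-arm isomers of M2/M2F are excluded because they are
absent from human neutrophil material, consistent with the preferential
biosynthetic hydrolysis of the α1,3 mannose. The enzyme rules are:
linkage-unspecific sialidase removes all NeuAc; α2,3-specific sialidase
removes NeuAc only from α2,3-annotated structures; jack bean
α-mannosidase removes terminal α-mannoses exhaustively (β-mannose never;
antenna-substituted arms are not terminal, so bimannosyl complex
structures are refractory and trimannosyl complex structures lose exactly
the free α1,6 arm). Enzyme application is idempotent, which the suite
checks as a property.

Structures sharing a composition (the α2,3/α2,6 sialyl pairs) are
indistinguishable by mass. The glycome stage therefore assigns *isomer
groups* and counts structures per group; the glycopeptide stage reports
the composition under the first panel member's name. Differential
re-assignment across an in-silico exoglycosidase-digested run is the
supported route to split them.

## Mass and isotope arithmetic

All masses derive from one internal table of IUPAC isotope masses and
abundances and standard atomic weights (exported to
`inst/extdata/mass_constants.csv` and by `mass_constants()`), making
peptide + bound glycan = glycopeptide additivity exact by construction.
m/z uses the proton mass (1.007276 Da), not the hydrogen atom — the
standard ESI convention. Reduced alditols add water + 2 H to the residue
sum. Isotopic distributions are computed by binary-exponentiation
convolution of per-element distributions, aggregated on nominal-mass bins
(~1.0034 Da spacing): a QTOF resolves nominal isotopologues of an intact
protein, not fine structure. Peaks are truncated at 99.99% cumulative
abundance and renormalized; the suite verifies the convolution against
brute-force isotopologue enumeration on small molecules. Monoisotopic
mass is the matching currency at the glycan and peptide levels, average
mass at the intact level (an unresolved-envelope deconvoluted apex);
both are always computed, so the +87 Da (C-terminal serine) and +16 Da
(Met oxidation) deltas round identically on either scale.

## The synthetic generator and its defaults

`default_study_model()` encodes the study conditions: a cathepsin G-like
target whose fully occupied Asn71 carries GlcNAcβ 55.2%, Fucα1,6GlcNAcβ
22.7%, M1 10.6%, M1F 7.9%, M2 3.7%, plus six trace species (M2F and the
five sialylated structures) at 0.1% each, the vector renormalized to 1;
two C-terminal truncation variants at 57.8/42.2 (peptide level) and
61.9/38.1 (intact level); complete Met152 oxidation; three native
disulfides (−6 H at the intact level); and two co-purified contaminants
(azurocidin-like, weight 0.6; elastase-like, weight 0.5) whose four sites
are dominated by M2F. The published record does not resolve whether the
peptide-level and intact-level C-terminal ratios differ through
ionization bias or biology, so the model simply carries both level
-specific ground truths. Since the contaminants' M0F and M3F glycoforms
appear in the released glycome but on no confidently assigned site, the
stand-in model attributes them to the contaminant sites explicitly — that
choice is what makes the released glycome contain all 11 panel
structures and makes the contamination diagnosis concrete.

Generator behaviour per level:

* **glycome** — only PNGase-F-releasable site glycans from *all*
  proteins, as alditols, z = 1–2 negative (70/30 split);
* **glycopeptide** — site-covering fully specific chymotryptic peptides ×
  glycoforms, non-glycosylated site peptide when occupancy < 1, and the
  C-terminal variant peptides; z = 1–3 positive (20/50/30); linked
  noise-free CID and ETD fragment spectra per glycopeptide;
* **intact** — the purified target protein only (the intact experiment is
  a C4 separation of the isolated protein, not the mixture): C-terminal
  variants × glycoforms at complete oxidation, z = 15–25 with a fixed
  triangular envelope, per-proteoform isotope clusters.

Chromatography is reduced to single apex features whose area equals the
feature intensity, because EIC areas are the only quantity any stage
consumes; retention times are class-based surrogates (target
glycopeptides centred at 39 min) used for bookkeeping, not inference.
ZIC-HILIC enrichment is carried only as the panel's per-species
retained/non-retained flag (sialylated retained, paucimannose and stubs
not); no retention physics is modelled.

Noise is lognormal on intensities with CV 0.05 per feature, 10 ppm m/z
jitter, and 2% jitter on isotope-cluster abundances. The 5% EIC CV
models instrument-level technical variability of well-behaved EICs; the
published triplicates scatter more (±3.5/±4.9 percentage points on the
two stub shares), which plausibly includes sample-handling variance the
generator does not emulate. Recovery checks therefore compare simulated
means against the printed values using the combined replicate SD (in
quadrature) where a printed SD exists. Positive-mode ionization bias for
sialylated glycopeptides defaults to 0.5 — the direction is documented
(under-representation of sialylated species in positive mode), the
magnitude is not, so the value is an explicit, configurable assumption;
the quantitation stage itself assumes equal ionization efficiency, as the
published workflow did, so the bias is a perturbation the analysis must
tolerate, not a correction it applies.

In-source glycan loss is zero at and below 200 V and rises linearly to
0.4 at 400 V. The shape is the simplest monotone function consistent
with the two anchored observations — no aglycosylated proteoforms at
200 V, a significant artefactual population above 300 V; only the
anchors, not the slope, carry meaning.

Every run is seeded; the same seed reproduces the identical run
byte-for-byte. Replicates use consecutive derived seeds, all kept far
below 2³¹.

### Fixture sequences

The bundled FASTA contains *synthetic stand-in* sequences, not the
natural ones. They satisfy every positional constraint the analysis
depends on: a 255-residue precursor with mature chain 21–244; the single
sequon Asn71 inside the fully specific chymotryptic peptide GSNINVTL
(semi-specific digestion additionally yields GSNINV); C-terminal
²³⁸IRTTMR(S)²⁴⁴ peptides requiring one missed cleavage across Met242;
Met35/Met110/Met152/Met242; active site His64/Asp108/Ser201; six
cysteines; and contaminant chains with sequons at Asn126/Asn171 and
Asn124/Asn173 inside short chymotryptic peptides. Conclusions that
depend on the *actual* residue composition of the natural proteins
(exact intact masses, real retention, real structure) do not transfer
from the stand-ins; everything positional and combinatorial does.

## Analysis stages: parameters and numerical choices

* **Glycome assignment**: deprotonated-ion arithmetic, default tolerance
  0.15 Da — unit-resolution ion-trap data; matching is to the nearest
  composition, near-ties within tolerance are flagged ambiguous rather
  than silently resolved; charge states of one species merge into one
  quantitative entry.
* **Chymotrypsin**: cleaves after F/Y/W/L/M, never before proline;
  histidine cleavage is excluded because the observed peptide repertoire
  requires L/M specificity and H cleavage would fragment the site
  peptide's context. The protein C-terminus is always a valid terminus.
  Semi-specific mode enumerates sub-peptides (minimum length 4) of fully
  specific peptides.
* **Glycopeptide MS1/MS2 tolerances**: 0.3/0.5 Da defaults for ion-trap
  data; both configurable, neither derivable from the published record.
  Spectrum matching scores matched-ion counts with mass-error
  tie-breaks; site localization is claimed only from ETD, when matched
  c/z ions bracket the site with the glycan-consistent shift. ETD ions
  use the classic c (+NH₃) and z (−NH₃ complement) definitions, so each
  complementary singly-protonated pair reconstructs the precursor plus
  two protons exactly — the suite asserts this to 1e-6 Da.
* **Occupancy**: glycosylated / total site-peptide EIC; reported as 1.0
  when no non-glycosylated species is observed. PMSF-inactivated
  preparations contribute no autoproteolytic peptides, so none are
  generated.
* **Deconvolution**: candidate charges 8–30, neutral-mass agreement
  within 1 Da, at least two consecutive charge states per envelope
  (minimum-evidence rule: a single peak is never an envelope). Envelopes
  are accepted greedily by charge-state count then intensity, and an
  envelope whose peaks are already claimed is rejected — this suppresses
  the half-mass harmonics that arise when even-spaced charge states are
  reinterpreted at divided charges. Replacing the vendor
  maximum-entropy algorithm with this defined procedure preserves its
  contract (neutral masses + intensities) while being testable.
* **Proteoform matching**: 50 ppm on average mass — deliberately
  conservative relative to calibrant-level accuracy, since deconvoluted
  apex masses are less accurate than calibrated peak positions; Δ+87.08
  (serine) and Δ+15.999 (oxidation) partner annotations are symmetric
  links on matched masses. The isotope-fit score is total-variation
  similarity (1 − ½Σ|obs − theo|) on aligned nominal bins: 1 for
  identity, 0 for disjoint patterns.
* **Correlation**: R² on raw proportions over an explicit species
  universe (absent = 0), refused below 3 species. The replay compares
  glycopeptide vs intact and glycome vs glycopeptide on the site's
  non-trace glycoforms; contamination diagnosis maps the site profile
  onto the releasable universe and renormalizes before differencing.
* **Semi-quantitative bins**: ≥20% → xxxx, 2–20% → xxx, quantifiable
  <2% → xx, detected-only → x. The 20/2 thresholds are
  reverse-engineered so that the printed site abundances reproduce every
  populated cell of the published site × structure table; they are
  configurable. The trace flag (default: below 0.5% relative) marks
  "detected, non-quantifiable".
* **SASA**: Shrake–Rupley with golden-spiral sample points (default 960;
  convergence to <1% against 3840 is a suite property), Bondi vdW radii,
  5 Å probe. Distances default to minimum side-chain heavy-atom
  separation and always report their convention, because published
  distance figures rarely state theirs. PDB parsing is delegated to
  bio3d with an explicit altLoc policy (highest occupancy wins) and
  waters/heteroatoms excluded.

## Orchestration

The package is a library, not a shell tool: `run_study_replay()` plus
`replay_config()` are the end-to-end interface (simulate all three
levels, run all stages, assemble the reconciliation report, optionally
write CSV/JSON artifacts), and `scripts/acceptance.R` is the one thin
command-line entry point. Default problem sizes — technical triplicates
per level, the full default model — run the complete replay in well
under a minute; they were chosen to mirror the published triplicate
design.

## What passing tests do and do not show

The generator emulates: level-specific species visibility (PNGase F
resistance, contaminant pooling, in-source decay), charge-state
dispersion, lognormal EIC noise, m/z jitter, isotopologue clusters, and
ground-truth provenance for every feature. It does not emulate: profile
peak shapes and integration error, co-elution and interference, dynamic
range limits and dropout of trace species, real ionization physics,
in-run drift, or FDR-relevant search-space complexity (candidates come
from a handful of proteins, so identification is nearly noise-free by
construction). Parameter-recovery results on this synthetic data
therefore validate the *bookkeeping and inference logic* — assignment,
EIC arithmetic, deconvolution, reconciliation — under the stated noise
model; they are not evidence about performance on real acquisitions.
Likewise the published cross-level correlation contrast is reproduced as
an ordering property (near-perfect glycopeptide–intact agreement versus
a visibly degraded glycome–glycopeptide agreement), not as its exact
printed coefficients, which depended on undeposited raw data.

## Known limitations

Adduct chemistry beyond (de)protonation is flagged, never modelled;
deamidation sites are carried as fixed annotations, not localized;
glycan 3D conformers and their heights are out of scope (the structure
module ranks site and residue exposure but does not build glycans);
semi-specific digestion is enumerated, not kinetically modelled; and the
intact stage profiles the purified target protein only.
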