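---
title: "Mass bookkeeping for cross-linked lanthipeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass bookkeeping for cross-linked lanthipeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lantimass)
```

## The problem

Cinnamycin-like lantibiotics (type B lanthipeptides such as kyamicin,
cinnamycin and duramycin) are 19-residue ribosomal peptides whose mature form
carries three thioether bridges, a lysinoalanine cross-link and a
β-hydroxylated aspartate. Confirming that an expression host really makes the
predicted molecule rests almost entirely on high-resolution mass
spectrometry: does an extract contain an ion at the m/z the modified
structure predicts, does the chemically desulfurised material shift by the
expected ladder, and does the fragment series of the reduced peptide walk the
predicted sequence?

`lantimass` implements that chain of reasoning as composable, testable
pieces: elemental-formula algebra, a declarative structure model from which
species formulas are derived, desulfurisation ladders, a rearrangement-aware
y-ion generator, ppm-tolerance screening of peak lists, and a synthetic
peak-list generator that lets the whole workflow be validated without
instrument data.

## The mass model

All arithmetic is integer element counting followed by a single dot product
with a fixed table of monoisotopic masses (`atomic_masses`): C 12 (exact),
H 1.00782503207, N 14.0030740048, O 15.9949146196, S 31.97207100.
Protonated ions use the proton mass `proton_mass` = 1.007276466621 Da rather
than the hydrogen-atom mass — at *z* = 2 the electron mass is visible in the
fourth decimal:

$$ m/z = \frac{M + z\,m_{H^+}}{z} $$

A linear peptide is the sum of its residue compositions plus one water. The
post-translational modifications enter as pure bookkeeping:

* each dehydration (Ser → Dha, Thr → Dhb): − H₂O;
* each β-hydroxylation (Asp): + O;
* thioether cyclisation and lysinoalanine formation: no atom change (they
  are additions across the double bond the dehydration created);
* chemical desulfurisation of *k* thioether bridges (NiCl₂/NaBH₄): − *k* S,
  + 2*k* H; the lysinoalanine is inert to this treatment.

So for the kyamicin configuration (4 dehydrations, 1 hydroxylation) the
mature formula is `linear − 4 H₂O + O`, and the fully reduced species is
`mature − 3 S + 6 H`. Two corollaries are useful as quick sanity checks: the
"deoxy" species (missed hydroxylation) sits exactly m(O)/2 ≈ 7.9975 below
the mature ion at *z* = 2, and consecutive members of the reduction ladder
at *z* = 2 are spaced by (m(S) − 2 m(H))/2 ≈ 14.9782.

```{r}
ky <- kyamicin_structure()
render_formula(mature_formula(ky))
reduction_series(ky)
```

## The structure configurations are data

Core sequences and bridge topologies ship as YAML files
(`inst/extdata/*.yml`) rather than code; a new family member needs a config
file, not a patch. The kyamicin core sequence is not available as machine
readable text and was transcribed from the published structure drawing; the
transcription is validated — as the acceptance suite does — by requiring
that the derived mature formula equal the published C76H108N20O25S3. A wrong
transcription at any position that is not a mass-neutral isomer would break
that equality. The positions of the bridges do not affect intact masses at
all, only the fragment ladder.

## Fragmentation of the reduced peptide

MALDI-TOF LIFT spectra of the desulfurised peptide show the y-ion series
(C-terminal fragments plus water, singly protonated). Two modelling choices
matter and are fixed here explicitly:

1. **Apportioning the desulfurisation.** The whole-molecule shift is
   − S + 2 H per bridge; for per-fragment masses this must be assigned to
   residues. The Cys member reverts to Ala (− S) and the Dhb/Dha-derived
   member to Abu/Ala (+ 2 H), matching the hydride-reduction chemistry.
   The test suite checks that the residue forms re-sum to the exact
   whole-molecule formula.
2. **The lysinoalanine rearrangement.** Fragmentation at the lysinoalanine
   does not simply homolyse: the donor position is read as a glycine
   residue, and the bridge methylene stays on the lysine side-chain
   nitrogen as N=CH₂, i.e. the acceptor residue is lysine + CH₂ − 2H (net
   + C). The hydrogen bookkeeping at the cleaved site is pinned by atom
   conservation: glycine plus the modified lysine carry exactly the atoms
   of the intact Dha + Lys pair, so complementary fragments always sum to
   the precursor composition. Spans containing *both* bridge partners keep
   the intact, mass-neutral cross-link. Should external fragment tables
   ever disagree by a systematic ±1 Da, that would indicate a different
   hydrogen assignment at the N=CH₂ site and should be surfaced, not
   absorbed into a tolerance.

Fragments that would sever a *still-intact* thioether bridge (possible when
`k_reduced < n_bridges`) are generated but flagged `severs_thioether`,
because such ions are not expected to form cleanly; the intended use is the
fully reduced peptide, which is the default.

```{r}
tidy(y_ion_ladder(ky))[c(1, 2, 13, 14, 18), ]
```

## Annotation

`screen_species()` is the in-silico analogue of extracted-ion screening:
each queried (species, charge) ion is annotated with the nearest observed
peak in ppm and called detected inside a tolerance. Choices:

* **Tolerance default 10 ppm** — generous for a lock-mass-corrected TOF
  (observed errors for this family stay below 3.5 ppm) but tight enough
  that decoys essentially never fall inside; override per call.
* **Tie-break** — equidistant peaks resolve to the more intense, then to
  the lower m/z, so reports are deterministic.
* **ppm is quoted against the full-precision calculated m/z.** Published
  tables quote errors against 4-dp calculated values, which injects up to
  ±0.06 ppm of rounding noise (and published 4-dp values are not always
  consistently rounded); recomputed errors can therefore differ from
  printed ones in the second decimal. The exact printed errors are
  recovered by applying `ppm_error()` to the printed value pairs.
* **Retention time** is carried through peak lists but never used for
  matching; co-elution with a standard is an orthogonal, wet-lab argument.

Report surfaces round m/z half-even to 4 decimals and ppm to 2
(`format_mz()`, `format_ppm()`); everything internal is full precision.

## The synthetic-data generator

`simulate_peaklist()` emulates what the screening stage actually consumes:
true peaks at predicted m/z perturbed by Gaussian ppm error (default σ =
2 ppm, the error scale of a calibrated high-resolution instrument),
optional per-species dropout, and log-normal-intensity decoy peaks uniform
over the m/z range. Decoys are rejected inside ±3σ windows around true
ions so ground truth is unambiguous — recovery statistics then have a
clean interpretation. A single integer seed drives everything and the
caller's RNG state is restored afterwards.

What it deliberately does **not** emulate: isotope envelopes, charge-state
envelopes, chromatographic peak shape, intensity-dependent mass error.
Passing recovery tests therefore demonstrates the correctness of the
screening logic under the stated error model, not robustness to every
pathology of real spectra.

`simulate_variant_structures()` permutes the unconstrained residues of a
valid structure (bridge members, lysinoalanine pair and hydroxylation sites
stay fixed), providing fuel for conservation and round-trip property tests.

## Problem sizes and numerical choices

The test suite runs entirely on generated data at desk scale: 19-residue
peptides, peak lists of tens of peaks, 100 independent seeds for the
recovery property, 300 replicates for the ppm-scale Monte-Carlo check.
Formula equality is exact integer equality; mass additivity is asserted to
1e-9 Da; ladder spacing to 1e-12. Parsing accepts only strict Hill-notation
element-count grammar (one upper-case letter plus optional lower-case
letter per symbol); unknown elements, lower-case symbols and empty strings
are errors, and subtraction that would drive any element negative is an
error rather than a clamp.

## Limitations

* Only proton adducts are modelled (no Na⁺/K⁺, no average masses, no
  isotope patterns).
* b-ions and internal fragments are not generated; the characterisation
  workflow this supports reads the y series only.
* Stereochemistry is out of scope; the model is purely compositional.
* `extract_core()` uses a fixed C-terminal length (default 19) rather than
  a protease-motif model, which is correct for this family but not for
  RiPP classes with variable cores.
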