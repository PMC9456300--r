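---
title: "Identifying nusinersen metabolites from negative-mode LC-MS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying nusinersen metabolites from negative-mode LC-MS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nusimet)
```

## The problem

Nusinersen is an 18-mer antisense oligonucleotide with 2′-*O*-methoxyethyl
(MOE) riboses, 5-methylated pyrimidines and an all-phosphorothioate
backbone. Exonucleases remove residues from either end, and hydrolytic
base loss (depurination / depyrimidination) leaves abasic MOE-ribose
units, so the metabolites circulating in serum are short 2–4-mers. There
are no synthetic standards for these species, so identification has to be
built entirely from the mass spectrometry: every proposed identity is a
*mass* match between a deconvoluted neutral species and an enumerated
candidate fragment, confirmed by the internal consistency of the spectrum
itself (charge from isotope spacing, a −1/−2 ion pair, co-elution) rather
than by a reference compound.

This vignette records the model, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## Composition model

Residues are stored in the printed left-to-right order of the drug
sequence. The printed notation labels the left end 3′, although the same
base order is conventionally written 5′→3′ elsewhere for this drug; the
package stores the end labels verbatim as metadata and attaches no
directional chemistry to them, so every composition and mass result is
orientation-independent. Likewise our shortmer labels fix a convention
(left printed end = 3′) and are always reported alongside the explicit
span, so no information depends on reading direction.

The drug is sometimes described as 2′-*O*-methyl, but the metabolite
notation used in the field for this compound (residue tokens `mU`, `mC`,
abasic `MoeR`, the methoxyethyl diagnostic fragment at m/z 76) is
MOE-based, so all riboses carry the MOE substitution; the +C3H6O sugar
delta is held in a single constant.

Building blocks (all verified against independent per-atom summation and
against an external mass calculator during development):

* nucleosides: MOE-mU `C13H20N2O7`, MOE-mC `C13H21N3O6`, MOE-A
  `C13H19N5O5`, MOE-G `C13H19N5O6` (base + MOE-ribose − H2O);
* phosphorothioate bridge: net +P +S +O −H; phosphodiester bridge:
  +P +2O −H;
* terminal thiophosphate: +H +P +2O +S; hydroxyl terminus: nothing;
* abasic site: nucleoside − base + H2O (the hemiacetal abasic sugar);
* neutral free acids are modeled; the sodium salt form of the drug
  substance, and metal adducts generally, are out of scope.

One documented discrepancy: the full-length free-acid 18-mer computes to
7122.3 Da monoisotopic / 7127.2 Da average, while the drug's molecular
mass is usually quoted as 7110 g/mol (a value that presumably refers to a
different form). The package reports what the stated chemistry yields.

## Candidate space

`default_candidate_space()` enumerates every contiguous span of length
2–4 (48 spans of the 18-mer), expands each over all four terminal-group
combinations, and adds all single base-loss variants: 760 candidates.
The choices behind the defaults:

* lengths 2–4, because the observed serum metabolites are 2–4-mers;
* all four terminal combinations, because published metabolite sequence
  strings show thiophosphate marks at either end, both, or neither, and
  the exact terminal chemistry of exonuclease products is not stated;
* at most one base loss, which covers every reported base-loss species
  class while keeping the space in the hundreds.

Candidates are deduplicated by (span, terminals, losses) and never
silently by formula: isobaric candidates are genuinely different
molecules, and ambiguity is a finding, not noise. `formula_groups()`
provides the isobar-grouped view used for reporting. For context,
`count_adjacent_runs()` quantifies how non-unique a short sequence is
within the parent (the mU·mC dinucleotide fits four places in the 18-mer;
G·G only one), counting windows by residue multiset so that a window read
in either direction counts once — consistent with degradation from either
end producing the same composition.

## Spectral model

Negative-mode electrospray removes protons, so a z-charged ion of a
species of neutral mass M appears at (M − z·1.007276)/z, and
deconvolution restores M = z·(m/z) + z·1.007276. The consensus mass of a
species is the *unweighted* mean of its per-ion estimates, which
reproduces published deconvoluted values that lie between the −1 and −2
estimates.

Ion pairing is greedy in order of descending intensity (ties broken by
lower m/z, making the result permutation-invariant): an ion joins a
species only if its mass estimate is within `mass_tol` of every member
and its retention time within `rt_tol` of every member. The defaults,
`mass_tol` 0.2 Da and `rt_tol` 0.1 min, are set so that a genuine −1/−2
pair (identical retention time, sub-0.1 Da mass agreement) always joins,
while the documented hard case — two species about 1 Da apart in mass
eluting 0.23 min apart — always stays separate. A greedy scan is used
instead of a global matching because it is reproducible, linear-time, and
the data are sparse enough that the two never differ in practice.

Isotope envelopes are computed by exact elemental convolution: each
element's single-atom isotope distribution is raised to its atom count by
repeated squaring and the per-element results convolved, aggregating on a
nominal-mass grid (the abundance-weighted mean mass is tracked per
nominal bin). This matches Q-TOF-scale resolution, where fine structure
within one nominal isotopologue is unresolved; the bin count is bounded
by the nominal offset range, so no abundance floor is needed and the
convolution is exact to floating point (the test suite checks it against
brute-force isotopologue enumeration at < 1e-9). Charge is recovered as
round(1/median(spacing)), accepted only when all spacings are within
0.02 of 1/z and z ≤ 4 — otherwise the envelope is declared
indeterminate rather than guessed.

## Matching and status semantics

Species are matched against monoisotopic candidate masses by default with
a deliberately loose 2.5 Da tolerance; both monoisotopic and average
deltas are always reported, because the mass convention of published
"predicted" values for these species is not stated. The tolerance is
configurable down to ppm scale for well-calibrated data. Status is
`identified` (all matches in one formula group), `ambiguous` (≥2 groups,
all listed — isobars are never resolved by retention prediction),
`unidentified` (none), or `unconfirmed` (a single supporting ion, kept
with its candidate list). Widening the tolerance can only grow candidate
sets, never demote a species.

## The synthetic generator

`synth_config()` / `generate_truth()` / `generate_sample()` emulate what
the analysis assumes about serum-extract peak lists:

* planted metabolites drawn uniformly without replacement from the
  candidate space;
* retention times uniform over 8.5–11 min (the observed shortmer elution
  window) with a minimum spacing of 0.12 min, reflecting a separation
  good enough to resolve species 0.23 min apart — and chosen above
  `rt_tol` so that distinct planted species cannot co-elute into one
  another;
* each metabolite emits −1 and −2 isotope envelopes at a shared
  retention time, scaled by a log-uniform abundance over two decades;
* additive Gaussian m/z error (default sd 0.01 Da, mimicking the few
  hundredths-of-a-Da scatter of real peak lists) and multiplicative
  log-normal intensity noise (CV 0.1);
* matrix peaks with random m/z confined to the first 4 min — the
  dead-time region where unremoved matrix elutes — and *no* charge-pair
  structure, so the pipeline must reject them by pairing logic rather
  than an intensity gate.

What it does **not** emulate: ion suppression, instrument drift,
profile-mode peak shape, chimeric/overlapping envelopes, adducts, or any
extraction chemistry. Passing the recall tests therefore shows that the
pipeline logic is correct under its own assumptions, not that those
assumptions hold for any particular instrument.

Test problem sizes: the recall checks plant 20 metabolites (seed 42) for
the headline run and 10 metabolites across three noise levels for the
degradation check; these sizes exercise every species class while keeping
the whole suite fast to run routinely.

## Numerical and degenerate-input choices

* Proton mass 1.007276 Da; isotope masses/abundances from the standard
  IUPAC/CIAAW compilation, shipped as `isotope_table`.
* Report rounding is two decimals, half away from zero, with an ulp-scale
  nudge so decimal halves stored just below .5 in binary still round up.
* Empty peak list → empty assignment table; empty formula → mass 0 and a
  single-peak envelope; a composition longer than its parent → count 0,
  not an error; an EIC window that misses the grid → area 0 with a
  warning.
* All randomness flows through an explicit mandatory seed; identical
  config and inputs give identical outputs, byte for byte.

## Known limitations

The bundled serum reference tables (transcribed verbatim, with notes) are
internally inconsistent in ways that matter for validation:

* two rows print deconvoluted masses that contradict their own printed
  ions (the ion pairs imply 1499.59 and 1395.54); the package's
  deconvolution reproduces the ion-implied values, and these rows are
  flagged in the fixture rather than corrected;
* two rows share one shortmer label at different masses — a probable
  transcription error, preserved with a note;
* several printed species masses — most notably the base-loss species at
  970.35, 1464.62, 1349.60 and 1459.52 Da — are 3–20 Da away from *any*
  fragment composition reachable under the stated backbone chemistry
  (verified against an independent mass calculator). Under the default
  space and 2.5 Da tolerance, 8 of the 16 identified reference species
  receive a candidate; the remainder cannot be reproduced from the
  printed numbers and stated chemistry alone, and the corresponding
  fixture-wide matching check in the test suite documents this as a known
  failure rather than papering over it.

Endonuclease products (internal cuts yielding non-contiguous fragment
pairs), oxidative metabolites, adduct chemistry and retention-time
prediction are out of scope by design.
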