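# nusimet

Identification and tracking of nusinersen metabolites from negative-mode
LC-ESI-MS peak lists.

Nusinersen (Spinraza), the antisense oligonucleotide used to treat spinal
muscular atrophy, is an 18-mer with 2′-*O*-methoxyethyl (MOE) riboses,
5-methyl pyrimidines and a fully phosphorothioate backbone. In serum it is
degraded by 3′- and 5′-exonucleases to short (2–4-mer) truncation products
("shortmers"), with additional depurination / depyrimidination leaving
abasic MOE-ribose units. Because there are no metabolite standards,
identification rests entirely on mass spectrometry: charge states read off
isotope spacing, neutral masses deconvoluted from multiply charged ions,
and identities proposed by matching against an in-silico candidate space —
with every isobaric alternative reported, since short subsequences of the
drug are not unique. `nusimet` implements that workflow as composable,
tested R functions.

## What it computes

**Oligonucleotide mass chemistry.** Residues are MOE nucleosides
(`mU`, `mC`, `A`, `G`); each internal phosphorothioate bridge contributes
net +P +S +O −H, a phosphodiester bridge +P +2O −H, and a terminal
thiophosphate +H +P +2O +S. An abasic site replaces the nucleobase by
hydroxyl (nucleoside − base + H₂O). Monoisotopic, average and nominal
masses are computed from a bundled isotope table.

**Candidate enumeration.** All contiguous truncation products of the
18-mer in a length range, expanded over terminal-group combinations and up
to *k* base losses, labelled in shortmer notation (`5'N-a+3'N-b` = *a*
residues lost at one end, *b* at the other). The default space — lengths
2–4, all four terminal combinations, ≤1 base loss — has 760 candidates.

**Spectral deconvolution.** For a negative-mode ion of charge magnitude
*z*, the neutral mass is *M = z·(m/z) + z·1.007276*. Ions are paired into
species when their per-ion mass estimates agree within 0.2 Da *and* their
retention times within 0.1 min; a −1/−2 pair eluting together is the
signature that two signals come from one compound. Isotope envelopes are
predicted by exact elemental convolution on a nominal-mass grid, and charge
states recovered from the ~1/*z* isotope spacing.

**Identification and reporting.** Species are matched against candidate
masses (default tolerance 2.5 Da, monoisotopic), with status `identified`
(one isobaric formula group), `ambiguous` (several; all listed, never
resolved), `unidentified`, or `unconfirmed` (single supporting ion).

**Quantification.** Trapezoidal EIC peak areas, extraction recoveries as a
percentage of reference (liquid–liquid extract) areas, and before/after
dose-course area matrices per patient.

**Synthetic samples.** A seeded generator plants known fragments as
−1/−2 isotope-enveloped ion pairs with Gaussian chromatographic peaks,
m/z noise and charge-free matrix peaks in the dead-time region, so recall
and merger rates can be scored against ground truth.

## Worked example

```r
library(nusimet)

length(NUSINERSEN$residues)            # 18
count_adjacent_runs(NUSINERSEN, c("mU", "mC"))   # 4 possible mU-mC sites

space <- default_candidate_space()     # 760 candidates, lengths 2-4
peaks <- reference_ions()              # bundled serum reference ions
tab <- run_identification(peaks[, c("mz", "z", "rt", "intensity")],
                          candidates = space)
tab[tab$status %in% c("identified", "ambiguous"),
    c("rt", "mass", "status", "n_candidates", "best_sequence", "best_dm")]
```

```
      rt    mass     status n_candidates best_sequence   best_dm
9   9.63 1205.56  ambiguous            5    *A*MoeR*A*  0.568828
10  9.97 1615.63  ambiguous            4 *A*MoeR*G*mC* -0.435300
14 10.45 1237.47 identified            1    *MoeR*G*G*  0.643658
15 10.45 1499.59 identified            2   mC*mU*mU*mU -2.267960
16 10.60 1395.54 identified            2  MoeR*mC*A*mC  1.777229
17 10.83 1396.52  ambiguous           15  MoeR*mC*A*mC  0.802229
```

Each row is one deconvolved species: `mass` is the consensus neutral mass
from its −1/−2 ion pair (e.g. 1237.47 Da from m/z 617.73 at z = −2 and
1236.46 at z = −1), `n_candidates` the number of in-silico fragments within
the 2.5 Da match tolerance, and `best_dm` the candidate-minus-observed mass
error of the closest one. The two species at 10.45 min co-elute but are
separated by mass; the species at 10.60 and 10.83 min differ by about 1 Da
and are separated by retention time. Note that many reference species
remain `unidentified` here: their printed masses are not consistent with
any fragment of the stated backbone chemistry (see the vignette's
limitations section).

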