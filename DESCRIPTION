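Package: nusimet
Title: Identification and Tracking of Nusinersen Metabolites from Negative-Mode LC-MS Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for identifying exonuclease and base-loss metabolites of
    the antisense oligonucleotide drug nusinersen in negative-mode
    electrospray LC-MS peak lists. Models the elemental composition of
    2'-O-methoxyethyl phosphorothioate oligonucleotides, enumerates the
    truncation / terminal-chemistry / abasic candidate space, predicts
    isotope envelopes by elemental convolution, deconvolutes charge states
    to neutral masses with -1/-2 ion-pair and co-elution confirmation,
    matches species to candidates with explicit isobaric-ambiguity
    reporting, and quantifies extraction recovery and dose-course peak
    areas. A seeded synthetic serum-extract generator with known ground
    truth makes every pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
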