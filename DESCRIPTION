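Package: poisedfrag
Title: Poised Fragment Library Design and One-Step Follow-Up Enumeration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing poised fragment screening libraries and
    elaborating crystallographic fragment hits by parallel chemistry. A
    fragment is poised when it can be made in one step by a robust, widely
    used reaction; such a hit can be deconstructed into purchasable synthons
    and expanded into an analogue library within days. The package ships a
    curated library of 21 reaction engines (8 linking, 13
    heterocycle-forming) with forward and retrosynthetic transforms,
    classifies catalog molecules as poised, applies fragment-likeness,
    reaction-compatibility and synthon-availability filters, selects diverse
    subsets with USRCAT shape-pharmacophore descriptors or circular
    fingerprints, enumerates one-step follow-up libraries around a hit, and
    computes the pIC50/IC50/ligand-efficiency metrics used to rank the
    resulting compounds. A seeded synthetic catalog generator emulates
    vendor catalog space so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, ChemmineOB, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
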