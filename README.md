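# poisedfrag

Design poised fragment screening libraries and elaborate crystallographic
fragment hits by one-step parallel chemistry.

## The problem

Fragment screening by high-concentration crystal soaking finds real but very
weak binders — often too weak for any solution assay. Such hits cannot be
ranked or optimised by conventional SAR until they are elaborated, and
elaboration is only fast if the chemistry is. A **poised fragment** is a
compound that could have been made in one step by a robust, widely used
reaction (an amide coupling, a Suzuki coupling, a thiourea formation, a
standard heterocycle condensation). A poised hit can be deconstructed into
its **synthons** — an amide into the acid chloride and the amine — and an
analogue library assembled within days from commercial analogues of each
synthon, using the same one-step reaction.

`poisedfrag` is for computational and medicinal chemists building such
libraries. It provides:

* a curated, configurable library of **21 poised reactions** (8 linking +
  13 heterocycle-forming), each with a product pattern, a retrosynthetic
  transform producing purchasable synthons, and the matching forward
  transform (`loadReactionLibrary`, `classifyPoised`, `deconstruct`,
  `forwardSynthesize`);
* the **design cascade** vendor catalog → fragment-likeness filters →
  poised classification → reaction-compatibility → synthon-availability →
  diversity selection, with stage accounting (`designLibrary`);
* **USRCAT** shape-pharmacophore descriptors on deterministic conformers,
  circular-fingerprint **Butina clustering** and greedy **max-min**
  selection (`usrcatFromSmiles`, `clusterFingerprints`, `selectDiverse`);
* **follow-up enumeration** around a hit (`proposeAnalogues`,
  `annotateWithAssay`);
* **SAR metrics**: pIC50/IC50 conversion and ligand efficiency
  LE = 1.4 × pIC50 / heavy atoms (`ligandEfficiency`, `pic50ToIc50uM`),
  plus the bundled 22-compound PHIP(2) bromodomain reference panel
  (`referenceCompounds`);
* a seeded **synthetic catalog generator** with ground-truth labels, so the
  whole pipeline is testable without vendor downloads
  (`generateSyntheticCatalog`).

## Worked example

Classify a fragment hit, deconstruct it, and enumerate one-step analogues
from a building-block catalog:

```r
library(poisedfrag)

# N-(2,6-dichlorobenzyl)acetamide: poised via its amide bond
classifyPoised("CC(=O)NCc1c(Cl)cccc1Cl", id = "hit")
#>   fragment_id reaction matched_atoms                    synthons
#> 1         hit    amide       1, 2, 3 CC(=O)Cl, NCc1c(Cl)cccc1Cl

deconstruct("CC(=O)NCc1c(Cl)cccc1Cl", "amide")[[1]]
#> [1] "CC(=O)Cl"         "NCc1c(Cl)cccc1Cl"

syn <- readSynthonCatalog(system.file("extdata", "phip_synthons.csv",
                                      package = "poisedfrag"))
pr <- proposeAnalogues("CC(=O)NCc1c(Cl)cccc1Cl", "amide", syn,
                       similarityThreshold = 0, varyRoles = 2)
head(pr[, c("product_smiles", "similarity_to_original", "passes_filters")], 4)
#>              product_smiles similarity_to_original passes_filters
#> 1 CN(C(=O)C)Cc1c(Cl)cccc1Cl              0.4642857           TRUE
#> 2    COc1cccc(c1CNC(=O)C)OC              0.4137931          FALSE
#> 3         CC(=O)Nc1ccccc1Cl              0.3846154           TRUE
#> 4      Cc1c(NC(=O)C)cccc1Cl              0.3666667           TRUE
```

The second proposal is the 2,6-dimethoxy analogue that turned an
assay-inactive hit into a measurable inhibitor; its assay numbers come from
the bundled panel:

```r
ligandEfficiency(3.72, heavyAtoms("CC(=O)NCc1c(OC)cccc1OC"))
#> [1] 0.35        # kcal/mol per heavy atom
pic50ToIc50uM(3.72)
#> [1] 190.5461    # micromolar
```

`ligandEfficiency` reports the standard medicinal-chemistry convention:
1.4 × pIC50 / (non-hydrogen atom count), rounded to two decimals. A value
above ~0.4 marks an efficient fragment worth elaborating.

Design a library from a (here: synthetic) catalog:

```r
gen <- generateSyntheticCatalog(n = 500, seed = 42)
rec <- fragmentRecords(gen$catalog$smiles, gen$catalog$id)
rep <- designLibrary(rec, gen$synthons,
                     designConfig(k = 50, diversityMetric = "fingerprint"))
rep
#> DesignReport
#>   cascade: ingested=500 -> property_kept=... -> poised=... -> compatible=...
#>            -> available=... -> selected=50
```

A thin command-line front end ships as `inst/scripts/dspl`
(`classify | deconstruct | design | enumerate | stats | le | gen-catalog`):

```sh
Rscript inst/scripts/dspl le --pic50 3.11 --smiles "Cc1ccccc1NC(N)=S"
# 0.40
```

## Package layout

| Area | Entry points |
|---|---|
| Reaction knowledge | `loadReactionLibrary`, `writeReactionLibrary`, `classifyPoised`, `deconstruct`, `forwardSynthesize` |
| Filters | `fragmentRecords`, `designThresholds`, `applyPropertyFilters`, `compatibilityFilter`, `availabilityFilter` |
| Diversity | `usrcatFromSmiles`, `usrcatSimilarity`, `embedConformer`, `clusterFingerprints`, `diversityDistances`, `selectDiverse` |
| Pipeline | `designConfig`, `designLibrary`, `compositionStats` |
| Follow-up | `proposeAnalogues`, `annotateWithAssay` |
| SAR | `ligandEfficiency`, `pic50ToIc50uM`, `referenceCompounds` |
| I/O & generator | `readCatalog`, `writeCatalog`, `readSynthonCatalog`, `generateSyntheticCatalog`, `cliEntry` |

The methods vignette (`vignettes/poised-library-design.Rmd`) documents the
models, parameter choices, numerical conventions and known limitations.
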