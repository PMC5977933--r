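---
title: "Poised fragment libraries: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poised fragment libraries: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poisedfrag)
```

## The poised-fragment model

A *poised* fragment is a screening compound that could have been made in one
step by a robust, widely used synthetic reaction. The practical value is
speed after a hit: identify the poised bond, deconstruct the molecule into
its synthons, buy commercial analogues of each synthon, and re-run the same
one-step chemistry in parallel to obtain an analogue library within days.
This matters most for hits found by high-concentration crystal soaking,
which are typically too weak for solution assays and therefore cannot be
ranked by conventional SAR before elaboration.

`poisedfrag` implements the machinery around that idea:

1. a curated **reaction knowledge base** defining what "poised" means,
2. the **filter cascade** that turns a raw vendor catalog into a poised,
   reaction-compatible, purchasable library,
3. **diversity selection** (USRCAT shape-pharmacophore moments or circular
   fingerprints) for picking the final screening set,
4. **follow-up enumeration** around a hit, and
5. the **ligand-efficiency arithmetic** used to rank elaborated compounds.

## The reaction knowledge base

`loadReactionLibrary()` returns 21 reactions: 8 linking chemistries (amide,
sulfonamide, reductive amination, Suzuki biaryl, Sonogashira, aryl-ether
O-alkylation, SNAr amination on azines, thiourea formation via
thiocarbonyldiimidazole) and 13 heterocycle formations (benzimidazole,
benzoxazole, benzothiazole, Hantzsch thiazole, Knorr pyrazole, Huisgen
1,2,3-triazole, 1,2,4- and 1,3,4-oxadiazole, tetrazole, quinoxaline,
pyrimidine, Paal-Knorr pyrrole, and 5-aminooxazole-4-carbonitrile formation
from an acyl chloride and aminomalononitrile).

There is no single canonical roster for this kind of library: surveys of
the most-used medicinal chemistry reactions and of robust one-step
heterocycle syntheses overlap and differ at the margins. We ship
8 + 13 = 21 as the working roster — the twelve adopted heterocycle
formations were chosen for their prevalence in drug-like space and for
having clean one-step transforms — and made it fully configurable: `writeReactionLibrary()` exports the declarative YAML that
`loadReactionLibrary(path)` reads back, so a user can subset, reorder or
re-parameterise reactions (patterns, role classes, incompatibility rules).
Transform bodies — the graph edits that actually cut and form bonds — are
keyed by reaction name in the package engine; a user file can therefore
configure the shipped chemistries but not define brand-new ones, which would
require a general reaction-SMARTS interpreter out of scope here.

Each reaction couples three things:

* a **product SMARTS** locating the poised substructure (matched by
  OpenBabel, with symmetry-unique atom maps);
* a **retro transform**: deterministic graph edits on the matched atoms that
  cut the poised bond(s) and cap the pieces with the leaving groups a
  chemist would buy — acyl and sulfonyl chlorides, aryl and alkyl bromides,
  boronic acids, phenols. An amide therefore deconstructs to the acid
  chloride plus the amine;
* a **forward transform**: role patterns that each synthon must match, plus
  the graph edits that assemble the product.

Round-trip identity — `forwardSynthesize()` applied to the output of
`deconstruct()` regenerates the input's canonical SMILES — is enforced by
test over all 21 reactions on three curated substrates each. Two numerical
subtleties are worth recording. First, transforms operate on the kekulized
graph, and for some fused heterocycles more than one Kekulé assignment is
legal input; the quinoxaline retro transform re-kekulizes the fused bond
explicitly so either assignment deconstructs to benzene-1,2-diamine rather
than a quinonediimine. Second, condensations of *asymmetric* 1,3-diketones
are regiochemically ambiguous in reality; the forward transform commits to
the first symmetry-unique match, so round-trip identity is guaranteed for
symmetric diketones and for the substrates the generator produces, and a
regioisomer may be returned otherwise — a faithful reflection of the
chemistry, not a bug we attempt to hide.

```{r roundtrip}
sets <- deconstruct("CC(=O)NCc1c(Cl)cccc1Cl", "amide")
sets[[1]]
forwardSynthesize("amide", sets[[1]])
```

Stereochemistry is stripped at ingest (with a warning): the reaction set is
achiral and canonical-SMILES identity is the package-wide equality. All
canonicalization is OpenBabel's canonical SMILES; matched-atom indices in
annotations are 0-based positions in the canonical atom order.

## The filter cascade

`designLibrary()` runs catalog -> property filter -> poised classification
-> compatibility -> availability -> diversity selection, and reports
per-stage counts. Stage order puts the cheap filters first; counts are
non-increasing by construction.

**Property bounds** (`designThresholds()`) default to Rule-of-Three-flavoured
fragment bounds: MW 100-300 Da, cLogP <= 3, HBD <= 3, HBA <= 6, rotatable
bonds <= 3, 7-22 heavy atoms, elements restricted to H/C/N/O/S/halogens.
The original campaign's exact filter settings were not published; these
defaults are standard fragment-library practice, every bound is overridable,
and absolute stage counts from any particular vendor snapshot are therefore
not comparable across implementations. Properties come from OpenBabel
descriptors; note that its logP model runs high for halogenated aromatics,
which is one reason the bounds are configuration, not constants.

**Compatibility** removes fragments that would give mixtures when
re-synthesized: an amide-poised fragment carrying an additional free amine,
for example, corresponds to an asymmetric diamine synthon that would acylate
on both ends. Each reaction carries curated incompatibility SMARTS (free
amines for acylations; free acids/acyl halides and aldehydes for
amine-consuming reactions; stray aryl halides, boronic acids, azides and
terminal alkynes for the couplings) plus an *allowance* for the matches the
reaction's own product necessarily contains — the secondary amine formed by
reductive amination, the 5-amino group of the aminooxazoles. Only matches
beyond the allowance disqualify.

**Availability** requires every synthon of at least one annotation to be
present in a building-block catalog: exact canonical-SMILES identity, or
Tanimoto similarity at a configurable floor in `"similar"` mode.

## Diversity selection

**USRCAT.** Each molecule gets a 60-value descriptor: for five atom subsets
(all atoms, hydrophobic, aromatic, H-bond donors, acceptors) the mean,
standard deviation and cube-rooted (sign-preserving) skewness of the
distance distributions from four reference points — centroid, atom closest
to it, atom farthest from it, atom farthest from that one — always computed
over all atoms. Empty subsets contribute twelve zeros. Similarity is
`1 / (1 + mean |a - b|)`. Subset SMARTS are configurable; the defaults type
carbon not bonded to N/O/F plus S and heavy halogens as hydrophobic, any
aromatic atom as aromatic, N/O with a hydrogen as donor, and neutral N/O
(excluding amide N and pyrrole-type NH) as acceptor.

**Conformers.** USRCAT needs 3D coordinates. The package generates a single
conformer per molecule by classical multidimensional scaling of the bonded
graph's shortest-path distance matrix (1.5 A per heavy-atom bond, 1.1 A per
X-H bond, hydrogens added first), with a tiny seed-keyed symmetric jitter to
break eigenvalue degeneracies. This is a deliberate design choice: the
embedding is bitwise reproducible for a fixed (SMILES, seed), which makes
design runs exactly repeatable, at the cost of geometric realism — rings
flatten and conformational preferences are ignored. The resulting moments
behave as a topology-informed shape descriptor: invariant to rigid motion
(tested to 1e-8), stable across runs, and adequate for *relative* diversity
ranking, but they are not force-field conformer USRCAT values and should
not be compared against ones.

**Selection** is greedy max-min: the first pick maximizes summed distance
to all candidates (ties to the lexicographically smaller id); each later
pick maximizes its minimum distance to the selected set. On random point
sets this beats random picks in minimum pairwise distance in >= 95% of
trials (tested). Butina leader clustering on circular fingerprints is
provided for cluster-level accounting; the original campaign's cluster
count came from a proprietary tool's default fingerprints, so absolute
cluster counts are declared non-reproducible here.

**Fingerprints** throughout are OpenBabel ECFP4 (radius-2 circular) counts,
binarized and folded by OR from 4096 to 2048 bits; similarity is Tanimoto.

## The synthetic catalog generator

Vendor catalogs are a moving target, so `generateSyntheticCatalog()` stands
in for them: it forward-synthesizes products from seeded synthon pools with
a controlled per-reaction composition (default 60% amide, 20% ether, 10%
sulfonamide) and mixes in hydrocarbon decoys (10%) that can match no poised
pattern. Pool templates avoid alkoxy/amino aryl decorations so each product
carries no unintended poised bond of another class, which makes three
guarantees exactly testable: classifier recall on labelled products is
100%, the decoy false-positive rate is 0%, and `compositionStats()`
recovers the target composition within multinomial sampling error. Output
is byte-identical for identical arguments.

What the generator does *not* emulate: real catalogs' redundancy, salt
forms, charged species, exotic elements, property distributions skewed by
medicinal-chemistry fashion, and cross-reactive multi-functional compounds.
Passing the generator-based tests therefore demonstrates the machinery is
correct on its own terms, not that any particular vendor snapshot would
yield particular counts — the published absolute stage counts depend on a
2015 snapshot and are treated as historical observations.

## Follow-up enumeration

`proposeAnalogues()` deconstructs a hit, then swaps one synthon role at a
time for catalog members of the same functional class, ranked by
fingerprint similarity to the original synthon, with a similarity floor
(default 0.3) and per-role cap (default 50). One-at-a-time variation
matches how elaboration rounds are actually run; both-roles-at-once
enumeration is deliberately off. A caveat the defaults cannot hide:
circular-fingerprint Tanimoto between very small synthons is structurally
near zero (ammonia and methylamine share no bits at all), so for small
bespoke catalogs the similarity floor should be lowered — the bundled
PHIP(2) reproduction uses exhaustive enumeration (floor 0) over its
40-entry catalog. Scaffold-merged designs (the lactams of the reference
panel) are reachable only as user-supplied seeds, not generated.

## The reference panel

`referenceCompounds()` bundles the 22-compound PHIP(2) bromodomain panel —
a thiourea series, an N-benzylamide series and a
5-amino-oxazole-4-carbonitrile series — with AlphaScreen pIC50 values,
censoring flags for assay-floor results, and tabulated ligand efficiencies.
Structures are reconstructed from the series scaffolds and substituent
tables; each reconstruction is cross-validated by recomputing LE = 1.4 x
pIC50 / heavy atoms and comparing with the tabulated column. Sixteen of the
seventeen non-censored rows agree to better than 0.005 before rounding; the
one exception (compound 6, tabulated 0.45 vs computed 0.44) most likely
reflects an unrounded pIC50 in the original calculation and is kept as a
documented outlier rather than "corrected". Censored rows reproduce their
tabulated bounds after 2-decimal rounding under <=. The prefactor 1.4
(2.303 RT in kcal/mol near 305 K) is fixed because it reproduces the
tabulated column; 1.37 (298 K) misses several rows by 0.01. Censored pIC50
values are never used as plain numbers in statistics.

```{r panel}
panel <- referenceCompounds()
panel[panel$compound_id %in% c("1", "12", "17"),
      c("compound_id", "smiles", "pic50", "heavy_atoms", "le")]
```

## Problem sizes and degenerate inputs

The test suite and reproduction script run at desk scale by choice: the
generator catalogs used for the classification guarantees hold 2,000
molecules (binomial noise on a 60% class is then ~1 percentage point),
diversity comparisons use 100 trials of 30 points, and round-trip checks
cover 21 x 3 curated substrates. Degenerate inputs are defined behaviour:
an unparsable SMILES is an input error carrying the offending id; a
fragment matching no reaction returns an empty annotation set (not an
error); a catalog emptied mid-cascade yields a report flagged with the
exhausted stage; requesting more compounds than survive the cascade flags
the run and returns the whole pool; an empty synthon catalog removes all
annotations with a warning.

## Known limitations

* Transforms are achiral and single-step; no protecting groups, no
  multi-step routes, no reaction-condition or yield prediction.
* The conformer generator trades geometric realism for determinism (above).
* OpenBabel descriptor conventions (logP, H-bond acceptor counts) differ
  from other toolkits; thresholds are calibrated to be edited, not trusted.
* Absolute counts from any published campaign (library sizes, cluster
  counts, hit rates) depend on vendor snapshots, proprietary clustering and
  wet-lab screening, and are out of scope; the package reports its own
  accounting instead.
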