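# shared fixtures: the bundled PHIP synthon catalog and reference panel

phipSynthons <- function() {
  readSynthonCatalog(system.file("extdata", "phip_synthons.csv",
                                 package = "poisedfrag"))
}

phipPanel <- function() referenceCompounds()

# a tiny deterministic catalog for pipeline tests
tinyCatalog <- function(n = 60, seed = 7) {
  gen <- generateSyntheticCatalog(n = n, seed = seed)
  gen$records <- fragmentRecords(gen$catalog$smiles, gen$catalog$id)
  gen
}
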