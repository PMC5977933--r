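# pIC50 / IC50 / ligand-efficiency arithmetic, and the bundled PHIP(2)
# fragment-elaboration panel used as a reference SAR set.

#' Convert pIC50 to IC50 in micromolar
#'
#' `pIC50 = -log10(IC50 [M])`, so `IC50 [uM] = 10^(6 - pIC50)`.
#'
#' @param pic50 numeric vector of pIC50 values
#' @return IC50 in micromolar
#' @examples
#' pic50ToIc50uM(6)    # 1 uM
#' pic50ToIc50uM(3.72) # ~190 uM
#' @export
pic50ToIc50uM <- function(pic50) {
  stopifnot(is.numeric(pic50), all(is.finite(pic50)))
  10^(6 - pic50)
}

#' Ligand efficiency
#'
#' Binding contribution per non-hydrogen atom:
#' `LE = 1.4 * pIC50 / heavy_atoms` in kcal/mol per heavy atom. The prefactor
#' 1.4 is 2.303*R*T in kcal/mol near 305 K, the convention under which a
#' pIC50 of 3.11 over 11 heavy atoms gives the canonical fragment-hit LE of
#' 0.40.
#'
#' @param pic50 numeric vector of pIC50 values
#' @param heavyAtoms integer vector of non-hydrogen atom counts (recycled)
#' @param digits decimal places for reporting (default 2, the convention of
#'   medicinal-chemistry tables); use `NA` for the unrounded value
#' @return LE values in kcal/mol per heavy atom
#' @examples
#' ligandEfficiency(3.11, 11) # 0.40
#' @export
ligandEfficiency <- function(pic50, heavyAtoms, digits = 2) {
  stopifnot(is.numeric(pic50))
  if (any(heavyAtoms < 1)) stop("heavyAtoms must be >= 1")
  le <- 1.4 * pic50 / heavyAtoms
  if (is.na(digits)) le else round(le, digits)
}

#' The PHIP(2) fragment-elaboration reference panel
#'
#' Twenty-two numbered compounds from a poised-fragment campaign against the
#' PHIP(2) bromodomain: a thiourea series (hit 1 and analogues 5-11), an
#' N-benzylamide series (hit 2, analogues 12-15, and the scaffold-merged
#' lactams 16-17), and a 5-aminooxazole-4-carbonitrile series (hits 3-4,
#' analogues 18-22). Structures are reconstructed from the series scaffolds
#' and substituent tables; AlphaScreen pIC50 values are as reported, with
#' assay-floor results kept as censored upper bounds (`pic50` then holds the
#' bound, `censored` is `TRUE`). `le_printed` is the ligand efficiency as
#' tabulated at the time; `le` is recomputed here via [ligandEfficiency()].
#'
#' @return data.frame with columns `compound_id`, `series`, `smiles`
#'   (canonical), `pic50`, `censored`, `n_replicates`, `heavy_atoms`,
#'   `ic50_uM` (NA for censored rows), `le`, `le_printed`.
#' @examples
#' panel <- referenceCompounds()
#' subset(panel, compound_id == "1")$le # 0.40
#' @export
referenceCompounds <- function() {
  raw <- data.frame(
    compound_id = c("1", "5", "6", "7", "8", "9", "10", "11",
                    "2", "12", "13", "14", "15", "16", "17",
                    "3", "4", "18", "19", "20", "21", "22"),
    series = c(rep("thiourea", 8), rep("benzylamide", 7), rep("oxazole", 7)),
    smiles = c(
      "Cc1ccccc1NC(N)=S",
      "COc1cccc(NC(N)=S)c1C",
      "Cc1cccc(NC(N)=S)c1C",
      "FC(F)(F)c1cccc(NC(N)=S)c1C",
      "Clc1cccc(NC(N)=S)c1C",
      "Cc1cccc(C)c1NC(N)=S",
      "CNC(=S)Nc1ccccc1C",
      "CNC(=S)Nc1ccccc1Cl",
      "CC(=O)NCc1c(Cl)cccc1Cl",
      "CC(=O)NCc1c(OC)cccc1OC",
      "OCC(=O)NCc1c(Cl)cccc1Cl",
      "CC(=O)N(C)Cc1c(Cl)cccc1Cl",
      "OCC(=O)NCc1c(OC)cccc1OC",
      "O=C1CCCN1Cc1c(OC)cccc1OC",
      "O=C1CCCCN1Cc1c(OC)cccc1OC",
      "N#Cc1nc(Cc2ccccc2)oc1N",
      "N#Cc1nc(CC(C)C)oc1N",
      "N#Cc1nc(C2CC2)oc1N",
      "N#Cc1nc(C(C)C)oc1N",
      "N#Cc1nc(Cc2ccc(Cl)cc2)oc1N",
      "N#Cc1nc(C2CCCCC2)oc1N",
      "N#Cc1nc(C2CCCCC2)oc1N2CCCC2"),
    pic50 = c(3.11, 2.97, 3.78, 3.85, 3.59, 3.32, 3.38, 3.89,
              2.30, 3.72, 2.30, 2.30, 2.30, 3.25, 3.51,
              3.23, 3.57, 3.48, 2.30, 3.95, 3.31, 3.71),
    censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    n_replicates = 2L,
    le_printed = c(0.40, 0.32, 0.45, 0.36, 0.42, 0.39, 0.39, 0.45,
                   0.25, 0.35, 0.23, 0.23, 0.20, 0.27, 0.27,
                   0.30, 0.42, 0.44, 0.29, 0.35, 0.33, 0.29)
  )
  raw$smiles <- canonicalSmiles(raw$smiles)
  raw$heavy_atoms <- heavyAtoms(raw$smiles)
  raw$ic50_uM <- ifelse(raw$censored, NA_real_, pic50ToIc50uM(raw$pic50))
  raw$le <- ligandEfficiency(raw$pic50, raw$heavy_atoms)
  raw[c("compound_id", "series", "smiles", "pic50", "censored",
        "n_replicates", "heavy_atoms", "ic50_uM", "le", "le_printed")]
}

#' Export assay results as CSV
#'
#' Writes the standard assay-table layout (`compound_id, smiles, pic50,
#' censored, n, ic50_uM, heavy_atoms, le`).
#'
#' @param assay a data.frame as returned by [referenceCompounds()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeAssayCsv <- function(assay, path) {
  utils::write.csv(assay, path, row.names = FALSE)
  invisible(path)
}
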