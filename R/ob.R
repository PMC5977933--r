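# Glue around OpenBabel (via ChemmineOB). All molecule identity in the package
# is OpenBabel canonical SMILES; all substructure matching is OpenBabel SMARTS.
# A few calls use ChemmineOB's unexported SWIG bindings because the exported
# smartsSearch_OB() only returns match counts and the transform engine needs
# the matched atom indices.

.obCache <- new.env(parent = emptyenv())

.obGet <- function(name) get(name, envir = getNamespace("ChemmineOB"))

# compiled-SMARTS cache keyed by pattern string
.obSmarts <- function(pattern) {
  key <- paste0("sp:", pattern)
  if (!is.null(.obCache[[key]])) return(.obCache[[key]])
  sp <- .obGet("OBSmartsPattern")()
  ok <- .obGet("OBSmartsPattern_Init")(sp, pattern)
  if (!isTRUE(ok)) stop("invalid SMARTS pattern: ", pattern, call. = FALSE)
  .obCache[[key]] <- sp
  sp
}

#' Validate a SMARTS pattern
#'
#' Checks that OpenBabel can compile `pattern`.
#' @param pattern a SMARTS string
#' @return `TRUE` invisibly, or an error describing the bad pattern.
#' @export
validateSmarts <- function(pattern) {
  .obSmarts(pattern)
  invisible(TRUE)
}

.obConvert <- function(from, to, source) {
  ChemmineOB::convertFormat(from, to, source)
}

# one molecule's SDF text -> list of per-pattern unique match maps
# (each map an integer vector of 1-based atom indices in SMARTS atom order)
.obMatchSDF <- function(sdfText, patterns) {
  sps <- lapply(patterns, .obSmarts)
  match1 <- .obGet("OBSmartsPattern_Match")
  umap <- .obGet("OBSmartsPattern_GetUMapList")
  res <- ChemmineOB::forEachMol("SDF", sdfText, function(mol) {
    lapply(sps, function(sp) {
      match1(sp, mol)
      lapply(umap(sp), as.integer)
    })
  })
  out <- res[[1]]
  names(out) <- names(patterns)
  out
}

# count symmetry-unique SMARTS matches in one molecule
.obCountSDF <- function(sdfText, pattern) {
  length(.obMatchSDF(sdfText, list(p = pattern))[[1]])
}

#' Canonicalize SMILES
#'
#' Converts SMILES to the package-wide canonical dialect (OpenBabel canonical
#' SMILES). Stereochemistry is stripped before canonicalization: the reaction
#' chemistry modelled here is achiral and transforms do not track stereocentres
#' (a lossy-ingest warning is emitted when stereo markers are dropped).
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES; `NA` where a SMILES fails to
#'   parse.
#' @examples
#' canonicalSmiles(c("C1=CC=CC=C1", "OCC"))
#' @export
canonicalSmiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  hadStereo <- grepl("[@]|/|\\\\", smiles)
  if (any(hadStereo)) {
    warning(sum(hadStereo), " SMILES carried stereochemistry; stripped at ingest")
    smiles <- gsub("@|/|\\\\", "", smiles)
  }
  vapply(smiles, .canonical1, character(1), USE.NAMES = FALSE)
}

.canonical1 <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) return(NA_character_)
  key <- paste0("can:", smi)
  if (!is.null(.obCache[[key]])) return(.obCache[[key]])
  out <- suppressWarnings(try(.obConvert("SMI", "CAN", smi), silent = TRUE))
  if (inherits(out, "try-error") || !nzchar(out)) return(NA_character_)
  val <- strsplit(sub("\n$", "", out), "[ \t]")[[1]][1]
  if (!nzchar(val)) return(NA_character_)
  .obCache[[key]] <- val
  val
}

# SMILES -> single-molecule SDF text (atom order preserved by OpenBabel)
.smilesToSDF <- function(smi) {
  key <- paste0("sdf:", smi)
  if (!is.null(.obCache[[key]])) return(.obCache[[key]])
  out <- suppressWarnings(try(.obConvert("SMI", "SDF", smi), silent = TRUE))
  if (inherits(out, "try-error") || !grepl("V2000", out))
    stop("SMILES failed to parse: ", smi, call. = FALSE)
  .obCache[[key]] <- out
  out
}

# physchem properties for a vector of SMILES (OpenBabel descriptors)
.obProps <- function(smiles) {
  refs <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  ChemmineOB::prop_OB(refs)
}

#' Circular fingerprints (ECFP4 folded to 2048 bits)
#'
#' Radius-2 circular (extended-connectivity) fingerprints computed by
#' OpenBabel and folded from 4096 bins to 2048 bits by bitwise OR. These are
#' the fingerprints used throughout the package for Tanimoto similarity,
#' Butina clustering and follow-up synthon ranking.
#'
#' @param smiles character vector of SMILES
#' @return logical matrix with one row per molecule and 2048 columns
#' @export
circularFingerprint <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  rows <- lapply(smiles, function(s) {
    ref <- ChemmineOB::forEachMol("SMILES", s, identity)
    fp <- ChemmineOB::fingerprint_OB(ref, "ECFP4")
    fp <- as.numeric(fp) != 0
    fp[seq_len(2048)] | fp[2048 + seq_len(2048)]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(smiles)
  m
}

#' Tanimoto similarity between fingerprint rows
#'
#' @param a,b logical vectors (fingerprints of equal length)
#' @return Tanimoto coefficient in `[0, 1]`; 0 when both are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  i <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) return(0)
  i / u
}
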