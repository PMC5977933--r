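#' @import methods
NULL

#' ReactionDefinition: one poised reaction
#'
#' A poised reaction couples a product substructure pattern (what a poised
#' bond looks like in a catalog molecule) with a retrosynthetic transform
#' (product -> synthons, with the leaving-group conventions of commercial
#' building blocks: acyl chlorides, sulfonyl chlorides, aryl bromides, alkyl
#' bromides, boronic acids) and the matching forward transform
#' (synthons -> product). Reactions are either `linking` (two synthons joined
#' by one bond) or `heterocycle` (a ring assembled from one or two synthons
#' plus, for some chemistries, a fixed reagent such as thiocarbonyldiimidazole
#' or aminomalononitrile).
#'
#' @slot name short unique identifier, e.g. `"amide"`.
#' @slot category `"linking"` or `"heterocycle"`.
#' @slot synthonClasses ordered functional-class labels, one per synthon role.
#' @slot productSmarts SMARTS matching the poised substructure in a product;
#'   its atom order is the contract used by the transform engine.
#' @slot roleSmarts SMARTS one per role, matched against candidate synthons
#'   before forward synthesis.
#' @slot incompat named SMARTS patterns whose presence (beyond `allowance`
#'   matches) disqualifies a fragment for this reaction.
#' @slot allowance named integer: how many matches of each incompatibility
#'   pattern the reaction's own product necessarily contains.
#' @slot provenance free-text citation note.
#' @export
setClass("ReactionDefinition", representation(
  name = "character",
  category = "character",
  synthonClasses = "character",
  productSmarts = "character",
  roleSmarts = "character",
  incompat = "character",
  allowance = "integer",
  provenance = "character"
))

setValidity("ReactionDefinition", function(object) {
  msg <- character(0)
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (!object@category %in% c("linking", "heterocycle"))
    msg <- c(msg, "category must be 'linking' or 'heterocycle'")
  need <- if (identical(object@category, "linking")) 2L else 1L
  if (length(object@synthonClasses) < need)
    msg <- c(msg, sprintf("%s reactions need at least %d synthon classes",
                          object@category, need))
  if (length(object@roleSmarts) != length(object@synthonClasses))
    msg <- c(msg, "one role SMARTS per synthon class required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReactionDefinition", function(object) {
  cat(sprintf("ReactionDefinition '%s' (%s)\n", object@name, object@category))
  cat("  synthon roles: ", paste(object@synthonClasses, collapse = " + "), "\n")
  cat("  product SMARTS:", object@productSmarts, "\n")
  if (length(object@incompat))
    cat("  incompatibilities:", paste(names(object@incompat), collapse = ", "), "\n")
})

#' @describeIn ReactionDefinition-class reaction name accessor
#' @param object a `ReactionDefinition`
#' @export
setGeneric("reactionName", function(object) standardGeneric("reactionName"))
#' @export
setMethod("reactionName", "ReactionDefinition", function(object) object@name)

#' @describeIn ReactionDefinition-class reaction category accessor
#' @export
setGeneric("reactionCategory", function(object) standardGeneric("reactionCategory"))
#' @export
setMethod("reactionCategory", "ReactionDefinition", function(object) object@category)

#' @describeIn ReactionDefinition-class ordered synthon functional classes
#' @export
setGeneric("synthonClasses", function(object) standardGeneric("synthonClasses"))
#' @export
setMethod("synthonClasses", "ReactionDefinition", function(object) object@synthonClasses)

#' DesignConfig: parameters of a library-design run
#'
#' Collects every tunable of the catalog -> filtered -> poised -> compatible
#' -> available -> diversity-selected cascade. Defaults follow
#' Rule-of-Three-flavoured fragment bounds; see [designConfig()].
#'
#' @slot thresholds named list of property bounds.
#' @slot reactions names of enabled reactions (must exist in the library).
#' @slot availabilityMode `"exact"` or `"similar"`.
#' @slot availabilityThreshold Tanimoto similarity floor for `"similar"` mode.
#' @slot k target library size.
#' @slot diversityMetric `"usrcat"` or `"fingerprint"`.
#' @slot conformerSeed,selectionSeed integer seeds recorded in provenance.
#' @export
setClass("DesignConfig", representation(
  thresholds = "list",
  reactions = "character",
  availabilityMode = "character",
  availabilityThreshold = "numeric",
  k = "integer",
  diversityMetric = "character",
  conformerSeed = "integer",
  selectionSeed = "integer"
))

setValidity("DesignConfig", function(object) {
  msg <- character(0)
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (!object@availabilityMode %in% c("exact", "similar"))
    msg <- c(msg, "availabilityMode must be 'exact' or 'similar'")
  if (object@availabilityThreshold < 0 || object@availabilityThreshold > 1)
    msg <- c(msg, "availabilityThreshold must lie in [0, 1]")
  if (!object@diversityMetric %in% c("usrcat", "fingerprint"))
    msg <- c(msg, "diversityMetric must be 'usrcat' or 'fingerprint'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DesignConfig", function(object) {
  cat("DesignConfig\n")
  cat("  k:", object@k, " metric:", object@diversityMetric,
      " availability:", object@availabilityMode,
      sprintf("(>= %.2f)", object@availabilityThreshold), "\n")
  cat("  reactions:", length(object@reactions), "enabled\n")
  th <- object@thresholds
  cat("  properties: MW", th$mw_min, "-", th$mw_max,
      " cLogP <=", th$clogp_max, " HBD <=", th$hbd_max,
      " HBA <=", th$hba_max, " RotB <=", th$rotb_max,
      " heavy", th$heavy_min, "-", th$heavy_max, "\n")
})

#' DesignReport: stage-by-stage accounting of a design run
#'
#' @slot counts named integer vector of per-stage compound counts (ingested,
#'   property_kept, poised, compatible, available, selected); non-increasing
#'   along the cascade.
#' @slot composition data.frame (reaction, n, fraction_pct): share of
#'   compounds carrying at least one poised bond of each reaction, over the
#'   available-poised universe.
#' @slot selected character vector of selected compound ids.
#' @slot annotations data.frame of surviving poised annotations.
#' @slot provenance list: config hash, seeds, stage reached, timestamp.
#' @export
setClass("DesignReport", representation(
  counts = "integer",
  composition = "data.frame",
  selected = "character",
  annotations = "data.frame",
  provenance = "list"
))

setMethod("show", "DesignReport", function(object) {
  cat("DesignReport\n  cascade: ")
  cat(paste(names(object@counts), object@counts, sep = "=", collapse = " -> "), "\n")
  if (nrow(object@composition)) {
    top <- utils::head(object@composition[order(-object@composition$fraction_pct), ], 5)
    cat("  composition (top): ",
        paste(sprintf("%s %.1f%%", top$reaction, top$fraction_pct), collapse = ", "),
        "\n")
  }
  if (!is.null(object@provenance$exhaustedAt))
    cat("  ** exhausted at stage:", object@provenance$exhaustedAt, "**\n")
})
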