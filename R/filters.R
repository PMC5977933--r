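# The filter cascade: physchem fragment-likeness bounds, reaction
# compatibility (no cross-reactive groups beyond the poised bond itself), and
# commercial availability of the implied synthons.

#' Build fragment records with computed properties
#'
#' Canonicalizes SMILES and computes the physchem properties used by the
#' property filters. Unparsable entries are dropped with a warning; the count
#' of skipped entries is attached as `attr(x, "skipped")`.
#'
#' @param smiles character vector of SMILES
#' @param id identifiers (default `F000001`...)
#' @param source free-text origin tag
#' @return data.frame with columns `id`, `smiles` (canonical), `mw`,
#'   `heavy_atoms`, `clogp`, `hbd`, `hba`, `rotatable_bonds`, `rings`,
#'   `source`.
#' @export
fragmentRecords <- function(smiles, id = NULL,
                            source = "") {
  if (is.null(id)) id <- sprintf("F%06d", seq_along(smiles))
  stopifnot(length(id) == length(smiles))
  can <- canonicalSmiles(smiles)
  bad <- is.na(can)
  if (any(bad)) warning(sum(bad), " unparsable SMILES skipped")
  if (all(bad) || length(smiles) == 0) {
    out <- data.frame(id = character(0), smiles = character(0), mw = numeric(0),
                      heavy_atoms = integer(0), clogp = numeric(0),
                      hbd = integer(0), hba = integer(0),
                      rotatable_bonds = integer(0), rings = integer(0),
                      source = character(0))
    attr(out, "skipped") <- sum(bad)
    return(out)
  }
  id <- id[!bad]; can <- can[!bad]
  pr <- .obProps(can)
  rot <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"
  extra <- vapply(can, function(s) {
    m <- .molFromSmiles(s)
    c(sum(m$atoms$elem != "H"), .ringCount(m),
      .obCountSDF(.smilesToSDF(s), rot))
  }, numeric(3), USE.NAMES = FALSE)
  out <- data.frame(id = id, smiles = can, mw = pr$MW,
                    heavy_atoms = as.integer(extra[1, ]),
                    clogp = pr$logP, hbd = as.integer(pr$HBD),
                    hba = as.integer(pr$HBA1),
                    rotatable_bonds = as.integer(extra[3, ]),
                    rings = as.integer(extra[2, ]),
                    source = source)
  attr(out, "skipped") <- sum(bad)
  out
}

#' Default fragment-likeness thresholds
#'
#' Rule-of-Three-flavoured bounds for a poised *fragment* library: molecular
#' weight 100-300 Da, cLogP <= 3, <= 3 H-bond donors, <= 6 acceptors, <= 3
#' rotatable bonds, 7-22 heavy atoms, and no element outside
#' H/C/N/O/S/halogens. All overridable.
#'
#' @param ... named overrides of individual bounds
#' @return named list of thresholds
#' @export
designThresholds <- function(...) {
  th <- list(mw_min = 100, mw_max = 300, clogp_max = 3, hbd_max = 3,
             hba_max = 6, rotb_max = 3, heavy_min = 7, heavy_max = 22,
             elements = c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I"))
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(ov)] <- ov
  th
}

#' FilterReport: outcome of a filter stage
#'
#' @slot kept ids that passed every rule.
#' @slot rejected data.frame (`id`, `rule`, `detail`): first failing rule per
#'   rejected record.
#' @export
setClass("FilterReport", representation(kept = "character",
                                        rejected = "data.frame"))

setValidity("FilterReport", function(object) {
  if (length(intersect(object@kept, object@rejected$id)))
    "kept and rejected ids overlap" else TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d kept, %d rejected\n",
              length(object@kept), nrow(object@rejected)))
  if (nrow(object@rejected)) {
    tb <- sort(table(object@rejected$rule), decreasing = TRUE)
    cat("  rejections by rule:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

#' @describeIn FilterReport-class ids kept by the filter
#' @param object a `FilterReport`
#' @export
setGeneric("keptIds", function(object) standardGeneric("keptIds"))
#' @export
setMethod("keptIds", "FilterReport", function(object) object@kept)

#' @describeIn FilterReport-class rejection table accessor
#' @export
setGeneric("rejections", function(object) standardGeneric("rejections"))
#' @export
setMethod("rejections", "FilterReport", function(object) object@rejected)

#' Export a filter report as CSV
#' @param report a [FilterReport-class]
#' @param path output file
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  df <- rbind(
    data.frame(id = report@kept, status = "kept", rule = "", detail = ""),
    if (nrow(report@rejected))
      data.frame(id = report@rejected$id, status = "rejected",
                 rule = report@rejected$rule, detail = report@rejected$detail)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Apply fragment-likeness property filters
#'
#' A record is kept iff it passes every enabled rule; a rejection names the
#' first failing rule (rules are checked in the order: elements, mw_min,
#' mw_max, clogp_max, hbd_max, hba_max, rotb_max, heavy_min, heavy_max).
#' Setting a bound to `Inf`/`-Inf` (or `elements` to `NULL`) disables it.
#'
#' @param records data.frame from [fragmentRecords()]
#' @param thresholds named list from [designThresholds()]
#' @return a [FilterReport-class]
#' @export
applyPropertyFilters <- function(records, thresholds = designThresholds()) {
  kept <- character(0)
  rej <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    fail <- NULL
    if (!is.null(thresholds$elements)) {
      el <- unique(.molFromSmiles(r$smiles)$atoms$elem)
      off <- setdiff(el, thresholds$elements)
      if (length(off)) fail <- c("elements", paste(off, collapse = ","))
    }
    if (is.null(fail) && r$mw < thresholds$mw_min)
      fail <- c("mw_min", sprintf("MW %.1f < %g", r$mw, thresholds$mw_min))
    if (is.null(fail) && r$mw > thresholds$mw_max)
      fail <- c("mw_max", sprintf("MW %.1f > %g", r$mw, thresholds$mw_max))
    if (is.null(fail) && r$clogp > thresholds$clogp_max)
      fail <- c("clogp_max", sprintf("cLogP %.2f > %g", r$clogp, thresholds$clogp_max))
    if (is.null(fail) && r$hbd > thresholds$hbd_max)
      fail <- c("hbd_max", sprintf("HBD %d > %g", r$hbd, thresholds$hbd_max))
    if (is.null(fail) && r$hba > thresholds$hba_max)
      fail <- c("hba_max", sprintf("HBA %d > %g", r$hba, thresholds$hba_max))
    if (is.null(fail) && r$rotatable_bonds > thresholds$rotb_max)
      fail <- c("rotb_max", sprintf("RotB %d > %g", r$rotatable_bonds,
                                    thresholds$rotb_max))
    if (is.null(fail) && r$heavy_atoms < thresholds$heavy_min)
      fail <- c("heavy_min", sprintf("%d heavy atoms < %g", r$heavy_atoms,
                                     thresholds$heavy_min))
    if (is.null(fail) && r$heavy_atoms > thresholds$heavy_max)
      fail <- c("heavy_max", sprintf("%d heavy atoms > %g", r$heavy_atoms,
                                     thresholds$heavy_max))
    if (is.null(fail)) kept <- c(kept, r$id)
    else rej[[length(rej) + 1L]] <- data.frame(id = r$id, rule = fail[1],
                                               detail = fail[2])
  }
  new("FilterReport", kept = kept,
      rejected = if (length(rej)) do.call(rbind, rej)
                 else data.frame(id = character(0), rule = character(0),
                                 detail = character(0)))
}

#' Reaction-compatibility check for one poised annotation
#'
#' A fragment is compatible with the reaction it is poised for only when it
#' carries no cross-reactive functionality beyond the poised bond itself: an
#' amide-poised fragment with an additional free amine would give a mixture
#' of amides when re-synthesized from an asymmetric diamine synthon, so it is
#' removed. Each reaction carries curated incompatibility patterns plus an
#' allowance for the matches its own product necessarily contains (e.g. the
#' amine formed by reductive amination).
#'
#' @param annotation one row of [classifyPoised()] output
#' @param smiles the fragment's SMILES (must be the annotated fragment)
#' @param library list of [ReactionDefinition-class]
#' @param id fragment id; must equal `annotation$fragment_id` when given
#' @return list with elements `compatible` (logical) and `reason` (empty
#'   string when compatible).
#' @export
compatibilityFilter <- function(annotation, smiles,
                                library = loadReactionLibrary(), id = NULL) {
  if (is.data.frame(annotation)) {
    stopifnot(nrow(annotation) == 1)
    if (!is.null(id) && !identical(id, annotation$fragment_id))
      stop("annotation belongs to fragment '", annotation$fragment_id,
           "', not '", id, "'")
    reaction <- annotation$reaction
  } else reaction <- annotation
  lib <- .libByName(library)
  if (!reaction %in% names(lib)) stop("unknown reaction: ", reaction)
  def <- lib[[reaction]]
  if (!length(def@incompat)) return(list(compatible = TRUE, reason = ""))
  sdf <- .smilesToSDF(canonicalSmiles(smiles))
  for (nm in names(def@incompat)) {
    cnt <- .obCountSDF(sdf, def@incompat[[nm]])
    if (cnt > def@allowance[[nm]]) {
      reason <- if (nm %in% names(.INCOMPAT_REASON)) .INCOMPAT_REASON[[nm]]
                else nm
      return(list(compatible = FALSE, reason = unname(reason)))
    }
  }
  list(compatible = TRUE, reason = "")
}

#' Synthon-availability filter
#'
#' An annotation survives iff every one of its synthons has a match among the
#' available entries of a building-block catalog: exact canonical-SMILES
#' identity, or (mode `"similar"`) circular-fingerprint Tanimoto similarity
#' at or above `threshold`. A fragment is "available-poised" when at least
#' one of its annotations survives.
#'
#' @param annotations data.frame from [classifyPoised()] (possibly several
#'   fragments' worth)
#' @param synthonCatalog data.frame with columns `id`, `smiles`,
#'   `functional_class`, `available`
#' @param mode `"exact"` or `"similar"`
#' @param threshold Tanimoto floor in `[0, 1]` for `"similar"` mode
#' @return the surviving subset of `annotations`.
#' @export
availabilityFilter <- function(annotations, synthonCatalog,
                               mode = c("exact", "similar"), threshold = 0.7) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  cat0 <- synthonCatalog[as.logical(synthonCatalog$available), , drop = FALSE]
  if (nrow(cat0) == 0) {
    warning("synthon catalog has no available entries; all annotations removed")
    return(annotations[0, , drop = FALSE])
  }
  catSmi <- canonicalSmiles(cat0$smiles)
  catFp <- NULL
  if (mode == "similar") catFp <- circularFingerprint(catSmi)
  synOk <- new.env(parent = emptyenv())
  okOne <- function(s) {
    if (!is.null(synOk[[s]])) return(synOk[[s]])
    val <- if (s %in% catSmi) TRUE
           else if (mode == "similar") {
             fp <- circularFingerprint(s)[1, ]
             any(apply(catFp, 1, tanimoto, b = fp) >= threshold)
           } else FALSE
    synOk[[s]] <- val
    val
  }
  keep <- vapply(seq_len(nrow(annotations)), function(i) {
    all(vapply(annotations$synthons[[i]], okOne, logical(1)))
  }, logical(1))
  annotations[keep, , drop = FALSE]
}
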