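# One-step follow-up enumeration around a poised hit: swap each synthon for
# catalog analogues of its functional class and re-run the forward reaction.

#' Propose one-step analogues of a poised hit
#'
#' Deconstructs the hit with the given reaction, then, for each varied role,
#' ranks the catalog synthons of the matching functional class by
#' circular-fingerprint Tanimoto similarity to the hit's own synthon, keeps
#' those at or above `similarityThreshold` (at most `maxPerRole`), holds the
#' other roles fixed, forward-synthesizes, canonicalizes and de-duplicates
#' (the hit itself is excluded). One role is varied at a time. Property
#' filters are applied to each product and recorded in `passes_filters`.
#'
#' @param hitSmiles SMILES of the poised hit
#' @param reactionName reaction the hit is poised for
#' @param synthonCatalog data.frame (`id`, `smiles`, `functional_class`,
#'   `available`)
#' @param similarityThreshold Tanimoto floor for synthon analogy (default
#'   0.3)
#' @param maxPerRole cap on analogues per role (default 50)
#' @param varyRoles integer vector of role indices to vary (default: all)
#' @param thresholds property bounds for the `passes_filters` flag
#' @param library reaction library
#' @return data.frame with columns `product_smiles`, `reaction_name`,
#'   `replaced_role`, `synthon_used`, `synthon_id`,
#'   `similarity_to_original`, `passes_filters`, ordered by (role,
#'   similarity desc, synthon id).
#' @export
proposeAnalogues <- function(hitSmiles, reactionName, synthonCatalog,
                             similarityThreshold = 0.3, maxPerRole = 50L,
                             varyRoles = NULL,
                             thresholds = designThresholds(),
                             library = loadReactionLibrary()) {
  lib <- .libByName(library)
  if (!reactionName %in% names(lib)) stop("unknown reaction: ", reactionName)
  def <- lib[[reactionName]]
  hit <- canonicalSmiles(hitSmiles)
  if (is.na(hit)) stop("unparsable hit SMILES")
  sets <- deconstruct(hit, reactionName, library = lib)
  if (!length(sets))
    stop("hit is not poised for reaction '", reactionName, "'")
  original <- sets[[1]]
  nRoles <- length(def@synthonClasses)
  if (is.null(varyRoles)) varyRoles <- seq_len(nRoles)
  stopifnot(all(varyRoles %in% seq_len(nRoles)))
  cat0 <- synthonCatalog[as.logical(synthonCatalog$available), , drop = FALSE]
  out <- list()
  for (role in varyRoles) {
    cls <- def@synthonClasses[role]
    cand <- cat0[cat0$functional_class == cls, , drop = FALSE]
    if (nrow(cand) == 0) {
      warning("no available catalog synthons of class '", cls, "'")
      next
    }
    cand$smiles <- canonicalSmiles(cand$smiles)
    refFp <- circularFingerprint(original[role])[1, ]
    sims <- vapply(cand$smiles, function(s)
      tanimoto(circularFingerprint(s)[1, ], refFp), numeric(1))
    keep <- sims >= similarityThreshold
    cand <- cand[keep, , drop = FALSE]; sims <- sims[keep]
    ord <- order(-sims, cand$id)
    cand <- cand[ord, , drop = FALSE]; sims <- sims[ord]
    if (nrow(cand) > maxPerRole) {
      cand <- cand[seq_len(maxPerRole), , drop = FALSE]
      sims <- sims[seq_len(maxPerRole)]
    }
    for (i in seq_len(nrow(cand))) {
      syn <- original
      syn[role] <- cand$smiles[i]
      prod <- forwardSynthesize(reactionName, syn, library = lib)
      if (is.na(prod) || prod == hit) next
      out[[length(out) + 1L]] <- data.frame(
        product_smiles = prod, reaction_name = reactionName,
        replaced_role = role, synthon_used = cand$smiles[i],
        synthon_id = cand$id[i], similarity_to_original = sims[i])
    }
  }
  if (!length(out))
    return(data.frame(product_smiles = character(0),
                      reaction_name = character(0),
                      replaced_role = integer(0), synthon_used = character(0),
                      synthon_id = character(0),
                      similarity_to_original = numeric(0),
                      passes_filters = logical(0)))
  df <- do.call(rbind, out)
  df <- df[!duplicated(df$product_smiles), , drop = FALSE]
  rec <- fragmentRecords(df$product_smiles, id = sprintf("P%04d", seq_len(nrow(df))))
  rep <- applyPropertyFilters(rec, thresholds)
  df$passes_filters <- rec$id %in% keptIds(rep)
  rownames(df) <- NULL
  df
}

#' Join follow-up proposals with assay results
#'
#' Left-join on canonical SMILES (preferred) or compound id. Unmatched
#' proposals carry NA assay fields; censored results keep their bound flag
#' and are never coerced to plain numbers.
#'
#' @param proposals data.frame from [proposeAnalogues()]
#' @param assay data.frame with a `smiles` or `compound_id` key plus assay
#'   columns (e.g. [referenceCompounds()])
#' @return `proposals` with assay columns appended.
#' @export
annotateWithAssay <- function(proposals, assay) {
  key <- if ("smiles" %in% names(assay)) "smiles" else "compound_id"
  if (!key %in% names(assay)) stop("assay table needs 'smiles' or 'compound_id'")
  if (anyDuplicated(assay[[key]]))
    stop("duplicate assay keys: ",
         paste(unique(assay[[key]][duplicated(assay[[key]])]), collapse = ", "))
  if (key == "smiles") {
    assay$smiles <- canonicalSmiles(assay$smiles)
    idx <- match(proposals$product_smiles, assay$smiles)
  } else {
    idx <- match(proposals$synthon_id, assay$compound_id)
  }
  cbind(proposals, assay[idx, setdiff(names(assay), "smiles"), drop = FALSE],
        row.names = NULL)
}
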