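# k-of-n consensus pathogenicity classification over categorical
# predictor calls, with HC-LoF and literature-evidence overlays.

#' Normalise one predictor label to a binary damaging call
#'
#' SIFT "deleterious", PolyPhen2 "possibly_damaging" or
#' "probably_damaging", MutationTaster2021 "deleterious", FATHMM-MKL
#' "damaging" and PROVEAN "damaging" all map to \code{"damaging"}; the
#' tools' benign-side labels map to \code{"benign"}; NA stays NA. Both
#' PolyPhen2 damaging grades count as damaging: the consensus tallies are
#' over any damaging-side call, not only the confident grade.
#'
#' @param tool one of \code{"sift"}, \code{"polyphen2"},
#'   \code{"mutationtaster"}, \code{"fathmm_mkl"}, \code{"provean"}.
#' @param label character vector of prediction tokens for that tool.
#' @return character vector over \code{"damaging"}, \code{"benign"}, NA.
#' @examples
#' normalizePrediction("polyphen2", "possibly_damaging")
#' normalizePrediction("sift", c("tolerated", NA))
#' @export
normalizePrediction <- function(tool, label) {
  if (!tool %in% .TOOLS)
    stop("unknown tool: ", tool, " (expected one of ",
         paste(.TOOLS, collapse = ", "), ")", call. = FALSE)
  out <- rep(NA_character_, length(label))
  out[!is.na(label) & label %in% .DAMAGING_LABELS[[tool]]] <- "damaging"
  out[!is.na(label) & label %in%
        setdiff(.TOOL_LEVELS[[tool]], .DAMAGING_LABELS[[tool]])] <- "benign"
  bad <- !is.na(label) & is.na(out)
  if (any(bad))
    stop("unknown ", tool, " label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Count damaging predictor calls per record
#'
#' @param x a \code{VariantTable} or its \code{records} data.frame.
#' @return data.frame with \code{variant_id}, \code{population},
#'   \code{sex}, \code{damaging} (tools calling damaging, 0..5) and
#'   \code{available} (tools with a non-NA call, 0..5). LoF-class variants
#'   typically have \code{available <= 1}: of the five predictors only
#'   MutationTaster2021 scores non-missense variants.
#' @export
damagingCount <- function(x) {
  df <- if (methods::is(x, "VariantTable")) records(x) else x
  calls <- vapply(.TOOLS, function(tool)
    normalizePrediction(tool, df[[tool]]), character(nrow(df)))
  if (nrow(df) == 1L) calls <- matrix(calls, nrow = 1L,
                                      dimnames = list(NULL, .TOOLS))
  data.frame(variant_id = df$variant_id, population = df$population,
             sex = df$sex,
             damaging = as.integer(rowSums(calls == "damaging",
                                           na.rm = TRUE)),
             available = as.integer(rowSums(!is.na(calls))),
             stringsAsFactors = FALSE)
}

.evidenceHit <- function(df, evidenceMode) {
  switch(evidenceMode,
         tools_only = rep(FALSE, nrow(df)),
         tools_or_clinical = df$clinical_case,
         tools_or_functional = df$functional_evidence,
         tools_or_any_evidence = df$clinical_case | df$functional_evidence)
}

#' Classify every record of a variant table under a consensus definition
#'
#' The verdict is \code{"pathogenic"} when the damaging-call count reaches
#' \code{minTools(definition)}, or when the record is a high-confidence
#' LoF variant and the definition admits the LoF rule (applied for every
#' \code{minTools >= 1}), or when the definition's evidence mode matches a
#' set evidence flag. \code{minTools = 0} is the accounting rule: every
#' variant is pathogenic-side. Under the default
#' \code{clinvarMode = "report_only"}, the ClinVar category is carried in
#' the output but never changes a verdict (an in-silico consensus backed
#' by clinical case reports can overrule a ClinVar "benign" assertion);
#' \code{"veto_benign"} suppresses tools-only pathogenic calls for ClinVar
#' "benign" variants.
#'
#' @param x a \code{VariantTable}.
#' @param definition a \code{\link{PathogenicityDefinition}}.
#' @return data.frame with one row per record: \code{variant_id},
#'   \code{population}, \code{sex}, \code{damaging_count},
#'   \code{tools_available}, \code{is_hc_lof}, \code{evidence_hit},
#'   \code{clinvar}, \code{verdict}.
#' @export
setMethod("classifyVariants", "VariantTable",
          function(x, definition, ...) {
  stopifnot(methods::is(definition, "PathogenicityDefinition"))
  df <- records(x)
  counts <- damagingCount(df)
  isHcLof <- !is.na(df$lof_confidence) & df$lof_confidence == "HC" &
    df$consequence %in% .LOF_CONSEQUENCES
  evidenceHit <- .evidenceHit(df, definition@evidenceMode)
  k <- definition@minTools
  toolRoute <- counts$damaging >= k & k >= 1L
  if (definition@clinvarMode == "veto_benign")
    toolRoute <- toolRoute & !(df$clinvar %in% "benign")
  lofRoute <- definition@hcLofIsPathogenic & isHcLof & k >= 1L
  pathogenic <- k == 0L | toolRoute | lofRoute | evidenceHit
  data.frame(variant_id = df$variant_id, population = df$population,
             sex = df$sex,
             damaging_count = counts$damaging,
             tools_available = counts$available,
             is_hc_lof = isHcLof,
             evidence_hit = evidenceHit,
             clinvar = df$clinvar,
             verdict = ifelse(pathogenic, "pathogenic", "benign"),
             stringsAsFactors = FALSE)
})

#' Partition a variant table into pathogenic and benign subsets
#'
#' @param x a \code{VariantTable} (one record per variant for the stratum
#'   of interest).
#' @param definition a \code{\link{PathogenicityDefinition}}.
#' @return list with \code{VariantTable} elements \code{pathogenic} and
#'   \code{benign}; row order within each is the input order, and the two
#'   are a disjoint partition of the input.
#' @export
setMethod("selectPathogenic", "VariantTable",
          function(x, definition, ...) {
  calls <- classifyVariants(x, definition)
  df <- records(x)
  keep <- calls$verdict == "pathogenic"
  list(pathogenic = VariantTable(df[keep, , drop = FALSE]),
       benign = VariantTable(df[!keep, , drop = FALSE]))
})
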