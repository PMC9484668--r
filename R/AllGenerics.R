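#' @name CarrierFreq-generics
#' @title Generics for CarrierFreq classes
#' @description Accessor and analysis generics dispatched on the package's
#'   S4 classes.
#' @param object,x a CarrierFreq object.
#' @param ... passed to methods.
NULL

#' @rdname CarrierFreq-generics
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("validateRecords", function(x, ...)
  standardGeneric("validateRecords"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("classifyVariants", function(x, definition, ...)
  standardGeneric("classifyVariants"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("selectPathogenic", function(x, definition, ...)
  standardGeneric("selectPathogenic"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("estimatePrevalence", function(x, ...)
  standardGeneric("estimatePrevalence"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("thresholdSweep", function(x, ...)
  standardGeneric("thresholdSweep"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("generateCohort", function(x, ...)
  standardGeneric("generateCohort"))

#' @rdname CarrierFreq-generics
#' @export
setGeneric("minTools", function(x) standardGeneric("minTools"))

#' Accessors for VariantTable
#'
#' \code{records} returns the underlying data.frame; \code{variantIds},
#' \code{populations} and \code{sexes} the distinct identifiers and strata;
#' \code{stratumSubset} the rows of one population x sex stratum.
#'
#' @param x a \code{VariantTable}.
#' @name VariantTable-accessors
NULL

#' @rdname VariantTable-accessors
#' @export
setMethod("records", "VariantTable", function(x) x@records)

#' @rdname VariantTable-accessors
#' @export
variantIds <- function(x) unique(records(x)$variant_id)

#' @rdname VariantTable-accessors
#' @export
populations <- function(x) unique(records(x)$population)

#' @rdname VariantTable-accessors
#' @export
sexes <- function(x) unique(records(x)$sex)

#' @rdname VariantTable-accessors
#' @param population,sex stratum selectors.
#' @param drop drop rows with \code{ac == 0} (absent from the stratum).
#' @export
stratumSubset <- function(x, population = "ALL", sex = "ALL", drop = TRUE) {
  df <- records(x)
  df <- df[df$population == population & df$sex == sex, , drop = FALSE]
  if (drop) df <- df[df$ac > 0, , drop = FALSE]
  rownames(df) <- NULL
  VariantTable(df)
}

#' @rdname CarrierFreq-generics
#' @export
setMethod("minTools", "PathogenicityDefinition", function(x) x@minTools)

setMethod("show", "VariantTable", function(object) {
  df <- object@records
  cat("VariantTable with", nrow(df), "records:",
      length(unique(df$variant_id)), "variants x",
      length(unique(paste(df$population, df$sex))), "strata\n")
  if (nrow(df) > 0) {
    cat("  populations:", paste(sort(unique(df$population)), collapse = ", "),
        "\n  sex strata: ", paste(sort(unique(df$sex)), collapse = ", "), "\n")
    cat("  consequences:",
        paste(names(sort(table(df$consequence), decreasing = TRUE)),
              sort(table(df$consequence), decreasing = TRUE),
              collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "PathogenicityDefinition", function(object) {
  cat("PathogenicityDefinition: >=", object@minTools,
      "of 5 predictors damaging", sep = "")
  if (object@hcLofIsPathogenic) cat(", or HC LoF")
  cat("\n  evidence mode:", object@evidenceMode,
      "| ClinVar mode:", object@clinvarMode, "\n")
  invisible(object)
})

setMethod("show", "PrevalenceEstimate", function(object) {
  cat("PrevalenceEstimate [", object@population, "/", object@sex, "] ",
      object@nVariants, " pathogenic variant(s)",
      if (!is.na(object@sampleSize))
        paste0(", N = ", format(object@sampleSize, big.mark = ",")),
      "\n", sep = "")
  if (is.na(object@q)) {
    cat("  no pathogenic variants in stratum: prevalence NA\n")
  } else {
    cat(sprintf("  aggregate q = %.6g\n", object@q))
    cat(sprintf("  P(het)           = %.6g  (%s)\n", object@pHet,
                formatPrevalenceRatio(object@pHet)))
    cat(sprintf("  P(hom incl. CH)  = %.6g  (%s)\n", object@pHomInclCh,
                formatPrevalenceRatio(object@pHomInclCh)))
    cat(sprintf("  P(hom)           = %.6g  (%s)\n", object@pHom,
                formatPrevalenceRatio(object@pHom)))
    cat(sprintf("  P(compound het)  = %.6g  (%s)\n", object@pCh,
                formatPrevalenceRatio(object@pCh)))
    cat("  observed carriers: ", object@observedHetCarriers, " het, ",
        object@observedHomCarriers, " hom\n", sep = "")
  }
  invisible(object)
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: ", nrow(object@populations), " population(s), ",
      object@nVariants, " variants each, seed ", object@seed, "\n", sep = "")
  cat("  spectrum: ", object@singletonFraction, " singleton / ",
      object@commonFraction, " common [",
      paste(object@commonAfRange, collapse = "-"), "]\n", sep = "")
  cat("  truth: ", object@truthPathogenicFraction, " pathogenic, ",
      object@lofFraction, " LoF-class\n", sep = "")
  invisible(object)
})
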