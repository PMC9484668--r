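# Controlled vocabularies for the variant table schema. gnomAD-style
# categorical predictor output is normalised onto these tokens; anything
# else degrades to NA with a warning at read time.

.TOOLS <- c("sift", "polyphen2", "mutationtaster", "fathmm_mkl", "provean")

.TOOL_LEVELS <- list(
  sift           = c("tolerated", "deleterious"),
  polyphen2      = c("benign", "possibly_damaging", "probably_damaging"),
  mutationtaster = c("benign", "deleterious"),
  fathmm_mkl     = c("neutral", "damaging"),
  provean        = c("neutral", "damaging")
)

.DAMAGING_LABELS <- list(
  sift           = "deleterious",
  polyphen2      = c("possibly_damaging", "probably_damaging"),
  mutationtaster = "deleterious",
  fathmm_mkl     = "damaging",
  provean        = "damaging"
)

.CONSEQUENCES <- c("missense", "frameshift", "stop_gained",
                   "splice_acceptor", "inframe_deletion", "other")

# consequence classes eligible for a LOFTEE-style confidence label
.LOF_CONSEQUENCES <- c("frameshift", "stop_gained", "splice_acceptor",
                       "inframe_deletion")

.LOF_LEVELS <- c("HC", "LC")

.CLINVAR_LEVELS <- c("benign", "likely_benign", "uncertain",
                     "likely_pathogenic", "pathogenic", "absent")

.SEX_LEVELS <- c("female", "male", "ALL")

.EVIDENCE_MODES <- c("tools_only", "tools_or_clinical",
                     "tools_or_functional", "tools_or_any_evidence")

.CLINVAR_MODES <- c("report_only", "veto_benign")

.MANDATORY_COLS <- c("variant_id", "chrom", "pos", "ref", "alt",
                     "consequence", "population", "sex", "ac", "an", "nhom",
                     .TOOLS, "lof_confidence", "clinvar")

.OPTIONAL_COLS <- c("clinical_case", "functional_evidence", "references")

#' VariantTable: variants by population/sex strata with allele counts
#'
#' One row per variant x stratum, in the long layout of a gnomAD export:
#' variant identity (\code{variant_id}, \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}), a consequence class, the stratum (\code{population},
#' \code{sex}), allele counts (\code{ac} alternate alleles, \code{an} total
#' alleles called, \code{nhom} homozygous-alternate individuals), categorical
#' in silico predictor calls for the five tools, a LoF-confidence label, a
#' ClinVar category, and literature-evidence flags.
#'
#' Structural schema (column presence and types) is enforced by the class
#' validity; the scientific invariants (\code{ac <= an},
#' \code{nhom <= floor(ac/2)}, stratum-sum consistency, ...) are checked by
#' \code{\link{validateRecords}} which reports violations as data so that a
#' table can be inspected without throwing.
#'
#' @slot records data.frame with the columns listed above.
#' @seealso \code{\link{readVariantTable}}, \code{\link{validateRecords}}
#' @export
setClass("VariantTable", representation(records = "data.frame"))

setValidity("VariantTable", function(object) {
  df <- object@records
  missing <- setdiff(c(.MANDATORY_COLS, .OPTIONAL_COLS), names(df))
  if (length(missing) > 0)
    return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  msgs <- character(0)
  for (col in c("pos", "ac", "an", "nhom"))
    if (!is.numeric(df[[col]]))
      msgs <- c(msgs, paste0("column '", col, "' must be numeric"))
  for (col in c("clinical_case", "functional_evidence"))
    if (!is.logical(df[[col]]))
      msgs <- c(msgs, paste0("column '", col, "' must be logical"))
  bad <- setdiff(stats::na.omit(unique(df$consequence)), .CONSEQUENCES)
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("unknown consequence token(s): ",
                           paste(bad, collapse = ", ")))
  bad <- setdiff(stats::na.omit(unique(df$sex)), .SEX_LEVELS)
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("unknown sex token(s): ",
                           paste(bad, collapse = ", ")))
  if (length(msgs) > 0) msgs else TRUE
})

#' Construct a VariantTable from a data.frame
#'
#' Fills the optional evidence columns with defaults when absent
#' (\code{clinical_case = FALSE}, \code{functional_evidence = FALSE},
#' \code{references = ""}) and coerces count columns to integer-valued
#' numerics. Enum tokens are expected already normalised; use
#' \code{\link{readVariantTable}} for case-folding raw files.
#'
#' @param records data.frame with at least the mandatory columns.
#' @return A \code{VariantTable}.
#' @export
VariantTable <- function(records) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$clinical_case))
    records$clinical_case <- rep(FALSE, nrow(records))
  if (is.null(records$functional_evidence))
    records$functional_evidence <- rep(FALSE, nrow(records))
  if (is.null(records$references))
    records$references <- rep("", nrow(records))
  records$clinical_case <- as.logical(records$clinical_case)
  records$functional_evidence <- as.logical(records$functional_evidence)
  for (col in c("pos", "ac", "an", "nhom"))
    records[[col]] <- as.numeric(records[[col]])
  rownames(records) <- NULL
  methods::new("VariantTable", records = records)
}

#' PathogenicityDefinition: the consensus classification rule
#'
#' A variant is called pathogenic when at least \code{minTools} of the five
#' in silico predictors label it damaging, or (optionally) when it is a
#' high-confidence loss-of-function variant, or (optionally) when literature
#' evidence of the configured kind exists. \code{minTools = 0} is the
#' accounting rule under which every variant counts as pathogenic.
#'
#' @slot minTools integer in 0..5; the k of the k-of-n consensus.
#' @slot hcLofIsPathogenic logical; treat HC LoF variants as pathogenic
#'   whenever \code{minTools >= 1}.
#' @slot evidenceMode one of \code{"tools_only"}, \code{"tools_or_clinical"},
#'   \code{"tools_or_functional"}, \code{"tools_or_any_evidence"}.
#' @slot clinvarMode \code{"report_only"} (ClinVar categories are carried
#'   through but never change a verdict) or \code{"veto_benign"} (a ClinVar
#'   "benign" assertion overrides a tools-only pathogenic call; it never
#'   overrides HC-LoF or literature evidence).
#' @export
setClass("PathogenicityDefinition",
         representation(minTools = "integer",
                        hcLofIsPathogenic = "logical",
                        evidenceMode = "character",
                        clinvarMode = "character"))

setValidity("PathogenicityDefinition", function(object) {
  msgs <- character(0)
  if (length(object@minTools) != 1L || is.na(object@minTools) ||
      object@minTools < 0L || object@minTools > 5L)
    msgs <- c(msgs, "minTools must be a single integer in 0..5")
  if (length(object@hcLofIsPathogenic) != 1L ||
      is.na(object@hcLofIsPathogenic))
    msgs <- c(msgs, "hcLofIsPathogenic must be TRUE or FALSE")
  if (!identical(length(object@evidenceMode), 1L) ||
      !object@evidenceMode %in% .EVIDENCE_MODES)
    msgs <- c(msgs, paste0("evidenceMode must be one of: ",
                           paste(.EVIDENCE_MODES, collapse = ", ")))
  if (!identical(length(object@clinvarMode), 1L) ||
      !object@clinvarMode %in% .CLINVAR_MODES)
    msgs <- c(msgs, paste0("clinvarMode must be one of: ",
                           paste(.CLINVAR_MODES, collapse = ", ")))
  if (length(msgs) > 0) msgs else TRUE
})

#' Create a pathogenicity definition
#'
#' Defaults reproduce the headline rule used for rare recessive gene
#' screens: at least two predictors damaging, or a high-confidence LoF
#' variant; literature evidence and ClinVar are reported but do not change
#' verdicts.
#'
#' @param minTools integer 0..5.
#' @param hcLofIsPathogenic logical.
#' @param evidenceMode see \code{\linkS4class{PathogenicityDefinition}}.
#' @param clinvarMode see \code{\linkS4class{PathogenicityDefinition}}.
#' @return A \code{PathogenicityDefinition}.
#' @examples
#' PathogenicityDefinition(minTools = 2)
#' @export
PathogenicityDefinition <- function(minTools = 2L,
                                    hcLofIsPathogenic = TRUE,
                                    evidenceMode = "tools_only",
                                    clinvarMode = "report_only") {
  methods::new("PathogenicityDefinition",
               minTools = as.integer(minTools),
               hcLofIsPathogenic = as.logical(hcLofIsPathogenic),
               evidenceMode = match.arg(evidenceMode, .EVIDENCE_MODES),
               clinvarMode = match.arg(clinvarMode, .CLINVAR_MODES))
}

#' PrevalenceEstimate: Hardy-Weinberg carrier prevalence for one stratum
#'
#' Aggregate pathogenic allele frequency q = sum of per-variant frequencies
#' q_i = ac_i / an_i, and the four prevalence components under
#' Hardy-Weinberg equilibrium: heterozygous carriers 2pq with p = 1 - q,
#' homozygous-including-compound q^2, strictly homozygous sum(q_i^2), and
#' compound heterozygous q^2 - sum(q_i^2). Observed carrier counts are
#' tallied from the table: heterozygous = sum(ac - 2 nhom), homozygous =
#' sum(nhom). A stratum with zero pathogenic variants yields NA components.
#'
#' @slot population,sex the stratum.
#' @slot definition the \code{PathogenicityDefinition} applied.
#' @slot nVariants number of pathogenic variants in the stratum.
#' @slot sampleSize number of individuals (NA when unknown).
#' @slot q,p aggregate pathogenic allele frequency and its complement.
#' @slot perVariantQ named numeric vector of q_i.
#' @slot pHet,pHomInclCh,pHom,pCh the four prevalence components.
#' @slot observedHetCarriers,observedHomCarriers carrier tallies.
#' @export
setClass("PrevalenceEstimate",
         representation(population = "character",
                        sex = "character",
                        definition = "PathogenicityDefinition",
                        nVariants = "integer",
                        sampleSize = "numeric",
                        q = "numeric",
                        p = "numeric",
                        perVariantQ = "numeric",
                        pHet = "numeric",
                        pHomInclCh = "numeric",
                        pHom = "numeric",
                        pCh = "numeric",
                        observedHetCarriers = "numeric",
                        observedHomCarriers = "numeric"))

setValidity("PrevalenceEstimate", function(object) {
  msgs <- character(0)
  tol <- 1e-9
  if (!is.na(object@q)) {
    if (abs(object@p + object@q - 1) > tol)
      msgs <- c(msgs, "p + q must equal 1")
    if (abs(object@q - sum(object@perVariantQ)) > tol)
      msgs <- c(msgs, "q must equal sum(perVariantQ)")
    if (abs(object@pHet - 2 * object@p * object@q) > tol)
      msgs <- c(msgs, "pHet must equal 2pq")
    if (abs(object@pHomInclCh - object@q^2) > tol)
      msgs <- c(msgs, "pHomInclCh must equal q^2")
    if (abs(object@pHom + object@pCh - object@pHomInclCh) > tol)
      msgs <- c(msgs, "pHom + pCh must equal pHomInclCh")
    if (object@pCh < -tol)
      msgs <- c(msgs, "pCh must be non-negative")
  }
  if (length(msgs) > 0) msgs else TRUE
})

#' CohortConfig: parameters for the synthetic gnomAD-like cohort generator
#'
#' @slot seed integer master seed; all stage streams derive from it.
#' @slot populations data.frame with columns \code{name},
#'   \code{sample_size} (individuals per population).
#' @slot nVariants integer; variants simulated per population.
#' @slot singletonFraction fraction of variants drawn as singletons
#'   (one expected alternate allele in the stratum).
#' @slot commonFraction fraction of variants drawn as common polymorphisms.
#' @slot commonAfRange numeric length-2; allele-frequency range for common
#'   variants. The remaining variants are rare, with frequencies
#'   log-uniform between the singleton frequency and the lower common bound.
#' @slot truthPathogenicFraction fraction of variants that are truly
#'   pathogenic in the ground truth.
#' @slot toolSensitivity,toolSpecificity named numeric vectors (one entry
#'   per predictor) giving P(damaging | pathogenic) and
#'   P(benign | not pathogenic).
#' @slot lofFraction fraction of variants that are LoF-class (receiving a
#'   LoF-confidence label and predictor calls from MutationTaster only).
#' @slot exactCounts logical; when TRUE allele counts are set to
#'   round(2N q_i) instead of binomial draws (for fixture building).
#' @export
setClass("CohortConfig",
         representation(seed = "integer",
                        populations = "data.frame",
                        nVariants = "integer",
                        singletonFraction = "numeric",
                        commonFraction = "numeric",
                        commonAfRange = "numeric",
                        truthPathogenicFraction = "numeric",
                        toolSensitivity = "numeric",
                        toolSpecificity = "numeric",
                        lofFraction = "numeric",
                        exactCounts = "logical"))

setValidity("CohortConfig", function(object) {
  msgs <- character(0)
  fr <- c(singletonFraction = object@singletonFraction,
          commonFraction = object@commonFraction,
          truthPathogenicFraction = object@truthPathogenicFraction,
          lofFraction = object@lofFraction,
          object@toolSensitivity, object@toolSpecificity)
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1))
    msgs <- c(msgs, "all fractions must lie in [0, 1]")
  if (object@singletonFraction + object@commonFraction > 1)
    msgs <- c(msgs, "singletonFraction + commonFraction must be <= 1")
  if (!all(c("name", "sample_size") %in% names(object@populations)))
    msgs <- c(msgs, "populations needs columns 'name' and 'sample_size'")
  else if (any(object@populations$sample_size <= 0))
    msgs <- c(msgs, "sample sizes must be positive")
  if (length(object@commonAfRange) != 2 ||
      any(object@commonAfRange < 0) || any(object@commonAfRange > 1) ||
      object@commonAfRange[1] > object@commonAfRange[2])
    msgs <- c(msgs, "commonAfRange must be an increasing pair in [0, 1]")
  if (!setequal(names(object@toolSensitivity), .TOOLS) ||
      !setequal(names(object@toolSpecificity), .TOOLS))
    msgs <- c(msgs, "tool profiles must name all five predictors")
  if (length(msgs) > 0) msgs else TRUE
})

#' Create a cohort generator configuration
#'
#' The defaults emulate the allele-frequency spectrum of a rare-disease
#' gene in a large reference database: a spectrum dominated by singletons
#' plus an occasional common polymorphism, and predictors with high
#' sensitivity but modest specificity.
#'
#' @param seed integer master seed.
#' @param populations data.frame(name, sample_size).
#' @param nVariants variants per population.
#' @param singletonFraction,commonFraction,commonAfRange see
#'   \code{\linkS4class{CohortConfig}}.
#' @param truthPathogenicFraction fraction of truly pathogenic variants.
#' @param toolSensitivity,toolSpecificity per-tool profiles; scalars are
#'   recycled over the five predictors.
#' @param lofFraction fraction of LoF-class variants.
#' @param exactCounts deterministic allele counts instead of binomial draws.
#' @return A \code{CohortConfig}.
#' @export
CohortConfig <- function(seed = 1L,
                         populations = data.frame(
                           name = c("popA", "popB"),
                           sample_size = c(5000L, 5000L)),
                         nVariants = 50L,
                         singletonFraction = 0.6,
                         commonFraction = 0.05,
                         commonAfRange = c(0.005, 0.1),
                         truthPathogenicFraction = 0.4,
                         toolSensitivity = 0.85,
                         toolSpecificity = 0.80,
                         lofFraction = 0.1,
                         exactCounts = FALSE) {
  recycle <- function(x) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, 5L), .TOOLS)
    x[.TOOLS]
  }
  methods::new("CohortConfig",
               seed = as.integer(seed),
               populations = as.data.frame(populations),
               nVariants = as.integer(nVariants),
               singletonFraction = singletonFraction,
               commonFraction = commonFraction,
               commonAfRange = as.numeric(commonAfRange),
               truthPathogenicFraction = truthPathogenicFraction,
               toolSensitivity = recycle(toolSensitivity),
               toolSpecificity = recycle(toolSpecificity),
               lofFraction = lofFraction,
               exactCounts = as.logical(exactCounts))
}
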