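# Hardy-Weinberg carrier-prevalence arithmetic.
#
# For a set of pathogenic variants of one gene in one stratum, with
# per-variant allele frequencies q_i = ac_i / an_i and aggregate
# q = sum(q_i), p = 1 - q, the single-locus HWE model (a chromosome
# carries at most one variant allele of the gene) gives
#   P(het carrier)            = 2 p q
#   P(hom incl. compound het) = q^2
#   P(strict hom)             = sum(q_i^2)
#   P(compound het)           = q^2 - sum(q_i^2)  (>= 0 by Cauchy-Schwarz)

#' Aggregate pathogenic allele frequency for one stratum
#'
#' @param x a \code{VariantTable} restricted to a single stratum (one row
#'   per variant), or its records data.frame.
#' @return list with \code{q} (the aggregate sum of per-variant
#'   frequencies) and \code{perVariantQ} (named numeric of q_i = ac/an).
#'   A sum above 1 invalidates HWE aggregation and is flagged with a
#'   warning, not an error.
#' @export
aggregateAlleleFrequency <- function(x) {
  df <- if (methods::is(x, "VariantTable")) records(x) else x
  if (nrow(df) == 0)
    return(list(q = 0, perVariantQ = stats::setNames(numeric(0),
                                                     character(0))))
  if (anyDuplicated(df$variant_id))
    stop("each variant must appear once per stratum; duplicated: ",
         paste(unique(df$variant_id[duplicated(df$variant_id)]),
               collapse = ", "), call. = FALSE)
  qi <- stats::setNames(df$ac / df$an, df$variant_id)
  q <- sum(qi)
  if (q > 1)
    warning("aggregate allele frequency exceeds 1; HWE aggregation invalid",
            call. = FALSE)
  list(q = q, perVariantQ = qi)
}

#' Heterozygous-carrier prevalence 2pq
#'
#' Uses p = 1 - q, not the rare-variant approximation p = 1.
#'
#' @param q aggregate pathogenic allele frequency in [0, 1].
#' @return 2 (1 - q) q.
#' @export
hetPrevalence <- function(q) {
  stopifnot(all(q >= 0 & q <= 1, na.rm = TRUE))
  2 * (1 - q) * q
}

#' Prevalence of homozygous including compound-heterozygous genotypes
#'
#' @param q aggregate pathogenic allele frequency in [0, 1].
#' @return q^2.
#' @export
homInclCompoundPrevalence <- function(q) {
  stopifnot(all(q >= 0 & q <= 1, na.rm = TRUE))
  q^2
}

#' Strict-homozygote prevalence
#'
#' @param perVariantQ numeric vector of per-variant allele frequencies.
#' @return sum(q_i^2).
#' @export
homPrevalence <- function(perVariantQ) {
  stopifnot(all(perVariantQ >= 0))
  sum(perVariantQ^2)
}

#' Compound-heterozygote prevalence
#'
#' The remainder q^2 - sum(q_i^2): the probability that the two
#' chromosomes carry two different pathogenic variants. Non-negative for
#' any non-negative q_i, zero when at most one variant has q_i > 0.
#'
#' @param q aggregate frequency; must equal \code{sum(perVariantQ)} to
#'   within \code{tol}.
#' @param perVariantQ per-variant allele frequencies.
#' @param tol absolute consistency tolerance.
#' @return q^2 - sum(q_i^2).
#' @export
compoundHetPrevalence <- function(q, perVariantQ, tol = 1e-9) {
  if (abs(q - sum(perVariantQ)) > tol)
    stop("q does not equal sum(perVariantQ) within tolerance", call. = FALSE)
  max(q^2 - sum(perVariantQ^2), 0)
}

#' Population-size-corrected variant occurrence rate
#'
#' Number of distinct variants observed in a stratum divided by the
#' stratum's sample size: a crude per-individual variant-discovery rate
#' used to compare strata of very different sizes.
#'
#' @param nVariants distinct variants observed.
#' @param sampleSize individuals in the stratum (> 0).
#' @return nVariants / sampleSize.
#' @export
occurrenceRate <- function(nVariants, sampleSize) {
  stopifnot(sampleSize > 0, nVariants >= 0)
  nVariants / sampleSize
}

#' Render a probability as a "1: N" ratio
#'
#' @param probability numeric in (0, 1].
#' @param mode \code{"paper"} rounds the reciprocal to the nearest integer
#'   below 1,000 and to 3 significant figures above (the mixed convention
#'   of published prevalence tables); \code{"integer"} always rounds to
#'   the nearest integer; \code{"sigfigs"} rounds to \code{sigFigs}
#'   significant figures.
#' @param sigFigs significant figures for \code{mode = "sigfigs"}.
#' @return character \code{"1: N"} with thousands separators; \code{"NA"}
#'   for NA or non-positive probabilities.
#' @examples
#' formatPrevalenceRatio(1 / 615.5)               # "1: 616"
#' formatPrevalenceRatio(4.7353e-4, "sigfigs", 2) # "1: 2,100"
#' @export
formatPrevalenceRatio <- function(probability, mode = c("paper", "integer",
                                                        "sigfigs"),
                                  sigFigs = 3L) {
  mode <- match.arg(mode)
  vapply(probability, function(p) {
    if (is.na(p) || p <= 0) return("NA")
    r <- 1 / p
    n <- switch(mode,
                integer = round(r),
                sigfigs = signif(r, sigFigs),
                paper = if (r < 1000) round(r) else signif(r, 3L))
    paste0("1: ", format(n, big.mark = ",", scientific = FALSE))
  }, character(1))
}

#' Estimate carrier prevalence for one stratum under a definition
#'
#' Restricts the table to the requested stratum (rows with \code{ac > 0}),
#' applies the pathogenicity definition, aggregates allele frequencies and
#' composes the four HWE prevalence components. Observed carriers are
#' tallied as heterozygous = sum(ac - 2 nhom) and homozygous = sum(nhom).
#' A stratum with zero pathogenic variants yields NA prevalence
#' components: no estimate, rather than a zero-risk claim.
#'
#' @param x a \code{VariantTable}.
#' @param definition a \code{\link{PathogenicityDefinition}}.
#' @param population,sex the stratum to estimate.
#' @param sampleSize individuals in the stratum; when NULL, inferred as
#'   \code{max(an) / 2} (complete autosomal call rate).
#' @return A \code{\linkS4class{PrevalenceEstimate}}.
#' @examples
#' tab <- readVariantTable(system.file("extdata",
#'   "lep_gnomad_all_synthetic.tsv", package = "CarrierFreq"))
#' estimatePrevalence(tab, PathogenicityDefinition(minTools = 2))
#' @export
setMethod("estimatePrevalence", "VariantTable",
          function(x, definition = PathogenicityDefinition(),
                   population = "ALL", sex = "ALL", sampleSize = NULL, ...) {
  stratum <- stratumSubset(x, population, sex)
  df <- records(stratum)
  if (is.null(sampleSize))
    sampleSize <- if (nrow(df) > 0) max(df$an) / 2 else NA_real_
  sets <- selectPathogenic(stratum, definition)
  pat <- records(sets$pathogenic)
  if (nrow(pat) == 0) {
    return(methods::new("PrevalenceEstimate",
                        population = population, sex = sex,
                        definition = definition, nVariants = 0L,
                        sampleSize = as.numeric(sampleSize),
                        q = NA_real_, p = NA_real_,
                        perVariantQ = numeric(0),
                        pHet = NA_real_, pHomInclCh = NA_real_,
                        pHom = NA_real_, pCh = NA_real_,
                        observedHetCarriers = 0, observedHomCarriers = 0))
  }
  af <- aggregateAlleleFrequency(pat)
  q <- af$q
  methods::new("PrevalenceEstimate",
               population = population, sex = sex,
               definition = definition, nVariants = nrow(pat),
               sampleSize = as.numeric(sampleSize),
               q = q, p = 1 - q, perVariantQ = af$perVariantQ,
               pHet = hetPrevalence(q),
               pHomInclCh = homInclCompoundPrevalence(q),
               pHom = homPrevalence(af$perVariantQ),
               pCh = compoundHetPrevalence(q, af$perVariantQ),
               observedHetCarriers = sum(pat$ac - 2 * pat$nhom),
               observedHomCarriers = sum(pat$nhom))
})

#' Sweep the consensus threshold k
#'
#' Re-estimates prevalence for each value of \code{minTools}, holding the
#' rest of the definition fixed. The pathogenic sets are nested and every
#' prevalence component is non-increasing in k.
#'
#' @param x a \code{VariantTable}.
#' @param kValues integer vector of thresholds (default 0:3).
#' @param template definition whose non-k fields are reused.
#' @param population,sex,sampleSize as in \code{\link{estimatePrevalence}}.
#' @return named list of \code{PrevalenceEstimate}, one per k, in
#'   ascending k order (names \code{"k0"}, \code{"k1"}, ...).
#' @export
setMethod("thresholdSweep", "VariantTable",
          function(x, kValues = 0:3, template = PathogenicityDefinition(),
                   population = "ALL", sex = "ALL", sampleSize = NULL, ...) {
  kValues <- sort(unique(as.integer(kValues)))
  out <- lapply(kValues, function(k) {
    def <- PathogenicityDefinition(
      minTools = k,
      hcLofIsPathogenic = template@hcLofIsPathogenic,
      evidenceMode = template@evidenceMode,
      clinvarMode = template@clinvarMode)
    estimatePrevalence(x, def, population = population, sex = sex,
                       sampleSize = sampleSize)
  })
  stats::setNames(out, paste0("k", kValues))
})

#' Chi-square check of Hardy-Weinberg consistency for one variant
#'
#' Compares observed genotype counts (homozygous = \code{nhom},
#' heterozygous = \code{ac - 2 nhom}, reference = the rest) with their HWE
#' expectations at q = ac/an. A large statistic signals departure from a
#' single randomly-mating population -- e.g. the homozygote excess that
#' arises when structured subpopulations with different allele
#' frequencies are pooled (Wahlund effect).
#'
#' @param ac,an,nhom allele counts for the variant in the stratum.
#' @param sampleSize individuals; defaults to an/2.
#' @return list with \code{expected_hom}, \code{observed_hom},
#'   \code{chi_square} (2 genotype df pooled into 1 free df since q is
#'   estimated from the same data).
#' @export
hweConsistencyCheck <- function(ac, an, nhom, sampleSize = an / 2) {
  stopifnot(an > 0, ac >= 0, ac <= an, nhom >= 0)
  q <- ac / an
  p <- 1 - q
  N <- sampleSize
  expected <- c(hom = N * q^2, het = N * 2 * p * q, ref = N * p^2)
  observed <- c(hom = nhom, het = ac - 2 * nhom,
                ref = N - (ac - 2 * nhom) - nhom)
  keep <- expected > 0
  chi <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  list(expected_hom = unname(expected["hom"]),
       observed_hom = unname(observed["hom"]),
       chi_square = chi)
}
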