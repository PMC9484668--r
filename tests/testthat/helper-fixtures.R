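# Builders for toy variant tables and independent oracles used across
# the suite. Oracles are brute-force enumerations, deliberately written
# without the package's closed-form helpers.

lepFixturePath <- function(name = "lep_gnomad_all_synthetic.tsv")
  system.file("extdata", name, package = "CarrierFreq")

toyRecord <- function(variant_id = "v1", population = "ALL", sex = "ALL",
                      ac = 1, an = 2000, nhom = 0,
                      consequence = "missense", chrom = "7", pos = NULL,
                      sift = NA, polyphen2 = NA, mutationtaster = NA,
                      fathmm_mkl = NA, provean = NA,
                      lof_confidence = NA, clinvar = "absent",
                      clinical_case = FALSE, functional_evidence = FALSE,
                      references = "") {
  if (is.null(pos))
    pos <- 1e6 + strtoi(sub("\\D+", "", paste0(variant_id, "0")),
                        base = 10L)
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, ref = "A",
             alt = "G", consequence = consequence,
             population = population, sex = sex, ac = ac, an = an,
             nhom = nhom, sift = as.character(sift),
             polyphen2 = as.character(polyphen2),
             mutationtaster = as.character(mutationtaster),
             fathmm_mkl = as.character(fathmm_mkl),
             provean = as.character(provean),
             lof_confidence = as.character(lof_confidence),
             clinvar = clinvar, clinical_case = clinical_case,
             functional_evidence = functional_evidence,
             references = references, stringsAsFactors = FALSE)
}

toyTable <- function(...) VariantTable(do.call(rbind, list(...)))

# arguments giving exactly k damaging calls out of the five predictors
damagingProfile <- function(k) {
  stopifnot(k >= 0, k <= 5)
  damaging <- c(sift = "deleterious", polyphen2 = "probably_damaging",
                mutationtaster = "deleterious", fathmm_mkl = "damaging",
                provean = "damaging")
  benign <- c(sift = "tolerated", polyphen2 = "benign",
              mutationtaster = "benign", fathmm_mkl = "neutral",
              provean = "neutral")
  out <- as.list(benign)
  if (k > 0) out[seq_len(k)] <- damaging[seq_len(k)]
  out
}

# exhaustive ordered-allele-pair enumeration of carrier-genotype
# probabilities: allele 0 is reference with prob 1 - sum(qi), allele i
# carries variant i with prob qi
enumPairPrevalence <- function(qi) {
  prob <- c(1 - sum(qi), qi)
  het <- hom <- compound <- 0
  for (a in seq_along(prob)) {
    for (b in seq_along(prob)) {
      pab <- prob[a] * prob[b]
      nVar <- (a > 1) + (b > 1)
      if (nVar == 1) het <- het + pab
      else if (nVar == 2 && a == b) hom <- hom + pab
      else if (nVar == 2) compound <- compound + pab
    }
  }
  list(het = het, hom = hom, compound = compound)
}

# exact P(at least k of 5 independent predictors call damaging) by
# enumeration over the 2^5 call outcomes
enumConsensusRate <- function(k, pDamaging) {
  stopifnot(length(pDamaging) == 5)
  total <- 0
  for (mask in 0:31) {
    bits <- bitwAnd(mask, 2^(0:4)) > 0
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits, pDamaging, 1 - pDamaging))
  }
  total
}
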