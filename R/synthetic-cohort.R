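# Synthetic gnomAD-like cohorts with known ground truth, and
# individual-level genotype simulation under (or deliberately violating)
# the single-locus HWE model.

# run code under a seeded RNG substream, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.TOOL_TOKENS <- list(
  sift           = c(benign = "tolerated", damaging = "deleterious"),
  polyphen2      = c(benign = "benign", damaging = "probably_damaging"),
  mutationtaster = c(benign = "benign", damaging = "deleterious"),
  fathmm_mkl     = c(benign = "neutral", damaging = "damaging"),
  provean        = c(benign = "neutral", damaging = "damaging"))

#' Generate a synthetic variant table with ground truth
#'
#' Simulates a gnomAD-like allele-count table for one gene: a variant
#' spectrum dominated by singletons with occasional common polymorphisms,
#' per-population genotype counts drawn multinomially from HWE proportions
#' (so the generated \code{ac}/\code{nhom} are HWE-consistent within each
#' population), and per-tool categorical predictions drawn conditional on
#' a latent pathogenicity label with the configured sensitivity and
#' specificity. LoF-class variants receive predictions from
#' MutationTaster2021 only, mirroring the scope of the missense
#' predictors, and carry a LoF-confidence label (HC when truly
#' pathogenic). All draws are pure functions of the config seed, with
#' fixed per-stage substreams.
#'
#' @param x a \code{\link{CohortConfig}}.
#' @return list with \code{records} (a \code{VariantTable}, one row per
#'   variant x population) and \code{truth} (data.frame: variant_id,
#'   is_pathogenic, population, true_q).
#' @examples
#' cohort <- generateCohort(CohortConfig(seed = 7, nVariants = 20))
#' cohort$records
#' @export
setMethod("generateCohort", "CohortConfig", function(x, ...) {
  config <- x
  methods::validObject(config)
  nv <- config@nVariants
  pops <- config@populations
  if (nv == 0L) {
    empty <- VariantTable(utils::head(.emptyRecords(), 0))
    return(list(records = empty,
                truth = data.frame(variant_id = character(0),
                                   is_pathogenic = logical(0),
                                   population = character(0),
                                   true_q = numeric(0))))
  }
  refN <- max(pops$sample_size)

  # stage 1: variant identities, truth labels, frequency spectrum
  stage1 <- .withSeed(config@seed, {
    id <- sprintf("snv%04d", seq_len(nv))
    isPathogenic <- stats::runif(nv) < config@truthPathogenicFraction
    isLof <- stats::runif(nv) < config@lofFraction
    category <- sample(c("singleton", "common", "rare"), nv, replace = TRUE,
                       prob = c(config@singletonFraction,
                                config@commonFraction,
                                1 - config@singletonFraction -
                                  config@commonFraction))
    lo <- max(config@commonAfRange[1], 2 / (2 * refN))
    trueQ <- vapply(seq_len(nv), function(i) {
      switch(category[i],
             singleton = 1 / (2 * refN),
             common = stats::runif(1, config@commonAfRange[1],
                                   config@commonAfRange[2]),
             rare = exp(stats::runif(1, log(1 / (2 * refN)), log(lo))))
    }, numeric(1))
    list(id = id, isPathogenic = isPathogenic, isLof = isLof,
         category = category, trueQ = trueQ)
  })

  # stage 2: tool predictions conditional on truth
  preds <- .withSeed(config@seed + 1L, {
    out <- matrix(NA_character_, nrow = nv, ncol = 5L,
                  dimnames = list(NULL, .TOOLS))
    for (tool in .TOOLS) {
      applies <- if (tool == "mutationtaster") rep(TRUE, nv) else
        !stage1$isLof
      pDamaging <- ifelse(stage1$isPathogenic,
                          config@toolSensitivity[[tool]],
                          1 - config@toolSpecificity[[tool]])
      call <- ifelse(stats::runif(nv) < pDamaging, "damaging", "benign")
      out[applies, tool] <- .TOOL_TOKENS[[tool]][call[applies]]
    }
    out
  })

  # stage 3: per-population genotype counts from HWE proportions
  counts <- .withSeed(config@seed + 2L, {
    do.call(rbind, lapply(seq_len(nrow(pops)), function(pi) {
      N <- pops$sample_size[pi]
      q <- pmin(stage1$trueQ, 1)
      if (config@exactCounts) {
        nhom <- round(N * q^2)
        ac <- round(2 * N * q)
        nhom <- pmin(nhom, floor(ac / 2))
      } else {
        geno <- vapply(q, function(qi)
          stats::rmultinom(1, N, c((1 - qi)^2, 2 * qi * (1 - qi),
                                   qi^2))[2:3],
          numeric(2))
        ac <- geno[1, ] + 2 * geno[2, ]
        nhom <- geno[2, ]
      }
      data.frame(population = pops$name[pi], idx = seq_len(nv),
                 ac = ac, an = 2 * N, nhom = nhom,
                 stringsAsFactors = FALSE)
    }))
  })

  consequence <- ifelse(stage1$isLof,
                        rep(c("frameshift", "stop_gained",
                              "splice_acceptor"), length.out = nv),
                        "missense")
  lofConf <- ifelse(stage1$isLof,
                    ifelse(stage1$isPathogenic, "HC", "LC"),
                    NA_character_)
  i <- counts$idx
  df <- data.frame(
    variant_id = stage1$id[i], chrom = "7",
    pos = 127894000 + i, ref = "A", alt = "G",
    consequence = consequence[i],
    population = counts$population, sex = "ALL",
    ac = counts$ac, an = counts$an, nhom = counts$nhom,
    stringsAsFactors = FALSE)
  for (tool in .TOOLS) df[[tool]] <- preds[i, tool]
  df$lof_confidence <- lofConf[i]
  df$clinvar <- "absent"
  df$clinical_case <- FALSE
  df$functional_evidence <- FALSE
  df$references <- ""

  truth <- data.frame(variant_id = stage1$id[i],
                      is_pathogenic = stage1$isPathogenic[i],
                      population = counts$population,
                      true_q = stage1$trueQ[i],
                      stringsAsFactors = FALSE)
  list(records = VariantTable(df), truth = truth)
})

.emptyRecords <- function() {
  df <- data.frame(variant_id = "x", chrom = "7", pos = 1, ref = "A",
                   alt = "G", consequence = "missense", population = "ALL",
                   sex = "ALL", ac = 0, an = 2, nhom = 0,
                   stringsAsFactors = FALSE)
  for (tool in .TOOLS) df[[tool]] <- NA_character_
  df$lof_confidence <- NA_character_
  df$clinvar <- "absent"
  df$clinical_case <- FALSE
  df$functional_evidence <- FALSE
  df$references <- ""
  df
}

#' Simulate individual two-chromosome genotypes at a multi-allelic locus
#'
#' Each chromosome independently carries variant i with probability
#' \code{perVariantQ[i]} and the reference allele otherwise: the
#' single-locus model in which a chromosome carries at most one variant
#' allele of the gene, under which the compound-heterozygote prevalence
#' is exactly q^2 - sum(q_i^2).
#'
#' @param perVariantQ per-variant allele frequencies; sum must be <= 1.
#' @param nIndividuals individuals to simulate.
#' @param seed integer seed.
#' @return integer matrix \code{nIndividuals x 2}; 0 is the reference
#'   allele, i > 0 the i-th variant.
#' @export
simulateGenotypes <- function(perVariantQ, nIndividuals, seed = 1L) {
  q <- as.numeric(perVariantQ)
  stopifnot(all(q >= 0), nIndividuals >= 0)
  if (sum(q) > 1)
    stop("per-variant allele frequencies sum to more than 1", call. = FALSE)
  .withSeed(seed, {
    alleles <- sample.int(length(q) + 1L, 2L * nIndividuals,
                          replace = TRUE, prob = c(1 - sum(q), q)) - 1L
    matrix(alleles, ncol = 2L,
           dimnames = list(NULL, c("chrom1", "chrom2")))
  })
}

#' Empirical carrier fractions from simulated genotypes
#'
#' @param genotypes matrix from \code{\link{simulateGenotypes}}.
#' @return list with \code{het_frac} (exactly one variant chromosome),
#'   \code{hom_frac} (two copies of the same variant) and
#'   \code{compound_frac} (two different variants).
#' @export
empiricalPrevalence <- function(genotypes) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0)
    stop("no genotypes supplied", call. = FALSE)
  a <- genotypes[, 1]
  b <- genotypes[, 2]
  n <- nrow(genotypes)
  list(het_frac = sum(xor(a > 0, b > 0)) / n,
       hom_frac = sum(a > 0 & a == b) / n,
       compound_frac = sum(a > 0 & b > 0 & a != b) / n)
}

#' Simulate a structured (Wahlund) cohort for one variant
#'
#' Genotypes are simulated under HWE *within* each subpopulation at its
#' own allele frequency, then optionally pooled. When subpopulation
#' frequencies differ, the pooled cohort shows a homozygote excess over
#' the HWE expectation at the pooled frequency -- the Wahlund effect --
#' which \code{\link{hweConsistencyCheck}} flags with a large chi-square.
#'
#' @param subpopQ named numeric vector: allele frequency of the variant in
#'   each subpopulation.
#' @param subpopSizes integer vector of individuals per subpopulation.
#' @param seed integer seed.
#' @param pooled also include a pooled \code{population = "ALL"} row.
#' @return A \code{VariantTable} with one row per subpopulation (and the
#'   pooled row), allele counts realised from the simulated genotypes.
#' @export
wahlundCohort <- function(subpopQ, subpopSizes, seed = 1L, pooled = TRUE) {
  stopifnot(length(subpopQ) == length(subpopSizes),
            length(subpopQ) >= 2)
  names <- if (is.null(names(subpopQ)))
    paste0("subpop", seq_along(subpopQ)) else names(subpopQ)
  rows <- lapply(seq_along(subpopQ), function(i) {
    g <- simulateGenotypes(subpopQ[i], subpopSizes[i], seed = seed + i)
    data.frame(population = names[i],
               ac = sum(g > 0), an = 2 * subpopSizes[i],
               nhom = sum(g[, 1] > 0 & g[, 2] > 0),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  if (pooled)
    counts <- rbind(counts,
                    data.frame(population = "ALL", ac = sum(counts$ac),
                               an = sum(counts$an),
                               nhom = sum(counts$nhom)))
  df <- .emptyRecords()[rep(1, nrow(counts)), ]
  df$variant_id <- "wahlund_snv"
  df$population <- counts$population
  df$ac <- counts$ac
  df$an <- counts$an
  df$nhom <- counts$nhom
  rownames(df) <- NULL
  VariantTable(df)
}
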