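# Builds the synthetic LEP worked-example fixtures under inst/extdata/.
#
# The aggregate tallies (75 variants: 68 non-synonymous + 7 LoF; damaging-
# tool-count groups 22 / 21 / 13 / 14 plus 5 HC LoF; carrier totals 2,486
# het + 105 hom overall, 230 / 67 / 32 for the >=1 / >=2 / >=3 pathogenic
# sets; rs17151919 at ac = 2377 with 105 homozygotes) reproduce the
# published gene-level counts. The per-variant allocation of allele counts
# within each group is NOT the real per-variant data (which lives in a
# supplementary spreadsheet not shipped here) -- it is a synthetic
# allocation constrained to the printed group sums, hence the _synthetic
# suffix on the file names.
#
# Run from the package root: Rscript data-raw/make_fixtures.R

AN <- 282912  # 2 x 141,456 individuals

tools <- c("sift", "polyphen2", "mutationtaster", "fathmm_mkl", "provean")
damagingToken <- c(sift = "deleterious", polyphen2 = "probably_damaging",
                   mutationtaster = "deleterious", fathmm_mkl = "damaging",
                   provean = "damaging")
benignToken <- c(sift = "tolerated", polyphen2 = "benign",
                 mutationtaster = "benign", fathmm_mkl = "neutral",
                 provean = "neutral")

# cycle which tools call damaging so the marginals vary across variants
toolPattern <- function(count, offset) {
  idx <- ((offset + seq_len(count) - 1L) %% 5L) + 1L
  out <- benignToken
  out[tools[idx]] <- damagingToken[tools[idx]]
  out
}

rows <- list()
addVariant <- function(id, consequence, ac, nhom, damaging, offset = 0L,
                       lof_confidence = "", clinvar = "",
                       polyphenGrade = NULL) {
  i <- length(rows) + 1L
  if (consequence == "missense") {
    pred <- toolPattern(damaging, offset)
    if (!is.null(polyphenGrade) && pred["polyphen2"] != "benign")
      pred["polyphen2"] <- polyphenGrade
  } else {
    # LoF-class: only MutationTaster2021 scores the variant
    pred <- c(sift = "", polyphen2 = "", mutationtaster = "",
              fathmm_mkl = "", provean = "")
    pred["mutationtaster"] <- if (damaging >= 1) "deleterious" else "benign"
  }
  ref <- if (consequence %in% c("frameshift", "inframe_deletion"))
    "CAT" else "C"
  alt <- if (consequence %in% c("frameshift", "inframe_deletion"))
    "C" else "T"
  rows[[i]] <<- data.frame(
    variant_id = id, chrom = "7", pos = 127894000L + 13L * i,
    ref = ref, alt = alt, consequence = consequence,
    population = "ALL", sex = "ALL", ac = ac, an = AN, nhom = nhom,
    sift = pred["sift"], polyphen2 = pred["polyphen2"],
    mutationtaster = pred["mutationtaster"],
    fathmm_mkl = pred["fathmm_mkl"], provean = pred["provean"],
    lof_confidence = lof_confidence, clinvar = clinvar,
    stringsAsFactors = FALSE)
}

# -- group A: 20 missense with zero damaging calls (incl. the common,
#    benign rs17151919) ----------------------------------------------------
addVariant("rs17151919", "missense", 2377, 105, 0, clinvar = "benign")
acA <- c(20, 15, 10, 8, 6, 4, 4, 3, 3, 2, 2, 2, rep(1, 7))
stopifnot(length(acA) == 19, sum(acA) == 86)
for (j in seq_along(acA))
  addVariant(sprintf("lepv%03d", j), "missense", acA[j], 0, 0,
             clinvar = if (j <= 2) "uncertain" else "")

# -- group B: 2 low-confidence LoF, MutationTaster benign ------------------
addVariant("lepv101", "frameshift", 2, 0, 0, lof_confidence = "LC")
addVariant("lepv102", "frameshift", 1, 0, 0, lof_confidence = "LC")

# -- group C: 5 high-confidence LoF singletons, MutationTaster damaging ----
addVariant("rs1307773933", "frameshift", 1, 0, 1, lof_confidence = "HC")
addVariant("rs747703977", "inframe_deletion", 1, 0, 1,
           lof_confidence = "HC")
addVariant("lepv103", "frameshift", 1, 0, 1, lof_confidence = "HC")
addVariant("lepv104", "frameshift", 1, 0, 1, lof_confidence = "HC")
addVariant("lepv105", "splice_acceptor", 1, 0, 1, lof_confidence = "HC")

# -- group D: 21 missense with exactly one damaging call -------------------
addVariant("rs1800564", "missense", 43, 0, 1, offset = 0L)
acD <- c(29, 20, 15, 10, 8, 7, 6, 5, 4, 3, 2, 2, 2, rep(1, 7))
stopifnot(length(acD) == 20, sum(acD) == 120)
for (j in seq_along(acD))
  addVariant(sprintf("lepv%03d", 110 + j), "missense", acD[j], 0, 1,
             offset = j, clinvar = if (j <= 2) "uncertain" else "")

# -- group E: 13 missense with exactly two damaging calls ------------------
acE <- c(10, 5, 4, 3, 2, 2, 2, 2, 1, 1, 1, 1, 1)
stopifnot(length(acE) == 13, sum(acE) == 35)
for (j in seq_along(acE))
  addVariant(sprintf("lepv%03d", 140 + j), "missense", acE[j], 0, 2,
             offset = j,
             polyphenGrade = if (j %% 2 == 0) "possibly_damaging" else NULL)

# -- group F: 14 missense with three or more damaging calls ----------------
addVariant("rs28954113", "missense", 3, 0, 5, clinvar = "benign")
addVariant("rs724159998", "missense", 1, 0, 3, offset = 1L)
acF <- c(3, 3, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1)
stopifnot(length(acF) == 12, sum(acF) == 23)
for (j in seq_along(acF))
  addVariant(sprintf("lepv%03d", 160 + j), "missense", acF[j], 0,
             3 + (j %% 3), offset = j,
             polyphenGrade = if (j %% 3 == 0) "possibly_damaging" else NULL)

tab <- do.call(rbind, rows)
rownames(tab) <- NULL

# sanity checks against the published gene-level tallies
damagingAll <- c(unname(damagingToken), "possibly_damaging")
count <- mapply(function(...) sum(c(...) %in% damagingAll),
                tab$sift, tab$polyphen2, tab$mutationtaster,
                tab$fathmm_mkl, tab$provean)
isHc <- tab$lof_confidence == "HC"
stopifnot(nrow(tab) == 75,
          sum(tab$consequence == "missense") == 68,
          sum(tab$consequence != "missense") == 7,
          sum(count == 0) == 22,
          sum(count >= 1) == 53,
          sum(count >= 2 | isHc) == 32,
          sum(count >= 3 | isHc) == 19,
          sum(tab$ac) == 2486 + 2 * 105,
          sum(tab$ac[count >= 1]) == 230,
          sum(tab$ac[count >= 2 | isHc]) == 67,
          sum(tab$ac[count >= 3 | isHc]) == 32,
          sum(tab$ac[count == 0]) == 2256 + 2 * 105,
          sum(tab$nhom) == 105,
          sum(tab$clinvar != "") == 6)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "inst/extdata/lep_gnomad_all_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# -- literature-evidence overlay ------------------------------------------
evidence <- data.frame(
  variant_id = c("rs28954113", "rs724159998", "rs1307773933",
                 "rs747703977", "rs1800564", "rs17151919",
                 sprintf("lit_only_%02d", 1:15)),
  clinical_case = c("true", "true", "true", "true", "true", "false",
                    rep("true", 15)),
  functional_evidence = c("true", "false", "true", "true", "false",
                          "true", rep("false", 15)),
  references = c("PMID:9537324; PMID:19657113", "PMID:25678777",
                 "PMID:9202122", "PMID:20223363", "PMID:18347007",
                 "PMID:15504928",
                 sprintf("PMID:%d", 30000000 + 1:15)),
  stringsAsFactors = FALSE)
write.table(evidence, "inst/extdata/lep_evidence_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# -- published per-population summary counts (printed table, used as
#    input for occurrence rates; sample sizes are individuals) -------------
popSummary <- data.frame(
  population = c("ALL", "afr", "asj", "eas", "fin", "nfe", "amr", "oth",
                 "sas"),
  sex = "ALL",
  sample_size = c(141456, 12487, 5185, 9977, 12562, 64603, 17720, 3614,
                  15308),
  n_variants = c(75, 13, 1, 14, 3, 41, 14, 8, 16),
  n_nonsynonymous = c(68, 12, 1, 13, 3, 37, 14, 8, 14),
  n_lof = c(7, 1, 0, 1, 0, 4, 0, 0, 2),
  n_pathogenic_k2 = c(32, 4, 0, 6, 0, 16, 5, 5, 3),
  most_common_variant = c("rs17151919", "rs17151919", "rs17151919",
                          "rs148407750", "rs751272426", "rs17151919",
                          "rs17151919", "rs17151919", "rs17151919"),
  most_common_af_pct = c(0.84, 8.41, 0.26, 0.31, 0.04, 0.04, 0.45, 0.38,
                         0.03),
  stringsAsFactors = FALSE)
write.table(popSummary, "inst/extdata/lep_population_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("fixtures written\n")
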