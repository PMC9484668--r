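test_that("predictor labels normalise to the documented binary calls", {
  expect_equal(normalizePrediction("sift", "deleterious"), "damaging")
  expect_equal(normalizePrediction("sift", "tolerated"), "benign")
  # both PolyPhen2 damaging grades count as damaging
  expect_equal(normalizePrediction("polyphen2",
                                   c("possibly_damaging",
                                     "probably_damaging", "benign")),
               c("damaging", "damaging", "benign"))
  expect_equal(normalizePrediction("mutationtaster", "deleterious"),
               "damaging")
  expect_equal(normalizePrediction("fathmm_mkl", "neutral"), "benign")
  expect_true(is.na(normalizePrediction("provean", NA)))
  expect_error(normalizePrediction("cadd", "damaging"), "unknown tool")
  expect_error(normalizePrediction("sift", "damaging"), "unknown sift")
})

test_that("damagingCount tallies calls and availability", {
  tab <- toyTable(
    do.call(toyRecord, c(list("all5"), damagingProfile(5))),
    do.call(toyRecord, c(list("two"),
                         modifyList(damagingProfile(0),
                                    list(sift = "deleterious",
                                         provean = "damaging")))),
    toyRecord("lofmt", consequence = "frameshift",
              mutationtaster = "deleterious", lof_confidence = "HC"))
  counts <- damagingCount(tab)
  expect_equal(counts$damaging, c(5L, 2L, 1L))
  expect_equal(counts$available, c(5L, 5L, 1L))
})

test_that("consensus verdicts follow the k-of-n rule with overlays", {
  defK2 <- PathogenicityDefinition(minTools = 2)
  # all-five-damaging variant stays pathogenic despite ClinVar benign
  rs28954113like <- toyTable(do.call(toyRecord,
    c(list("v"), damagingProfile(5), list(clinvar = "benign"))))
  expect_equal(classifyVariants(rs28954113like, defK2)$verdict,
               "pathogenic")
  # ...unless ClinVar is given veto power
  veto <- PathogenicityDefinition(minTools = 2, clinvarMode = "veto_benign")
  expect_equal(classifyVariants(rs28954113like, veto)$verdict, "benign")

  # HC LoF with zero tool calls is pathogenic under the LoF rule
  hcLof <- toyTable(toyRecord("fs", consequence = "frameshift",
                              lof_confidence = "HC"))
  expect_equal(classifyVariants(hcLof, defK2)$verdict, "pathogenic")
  noLofRule <- PathogenicityDefinition(minTools = 2,
                                       hcLofIsPathogenic = FALSE)
  expect_equal(classifyVariants(hcLof, noLofRule)$verdict, "benign")
  # LC LoF never triggers the LoF rule
  lcLof <- toyTable(toyRecord("fs2", consequence = "frameshift",
                              lof_confidence = "LC"))
  expect_equal(classifyVariants(lcLof, defK2)$verdict, "benign")

  # benign-by-tools variant flips pathogenic only under the matching
  # evidence mode
  rs17151919like <- toyTable(do.call(toyRecord,
    c(list("v94m"), damagingProfile(0),
      list(functional_evidence = TRUE, references = "PMID:1"))))
  expect_equal(classifyVariants(rs17151919like, defK2)$verdict, "benign")
  funMode <- PathogenicityDefinition(minTools = 2,
                                     evidenceMode = "tools_or_functional")
  expect_equal(classifyVariants(rs17151919like, funMode)$verdict,
               "pathogenic")
  clinMode <- PathogenicityDefinition(minTools = 2,
                                      evidenceMode = "tools_or_clinical")
  expect_equal(classifyVariants(rs17151919like, clinMode)$verdict,
               "benign")

  # minTools = 0 is the accounting rule: everything is pathogenic-side
  defK0 <- PathogenicityDefinition(minTools = 0)
  expect_equal(classifyVariants(rs17151919like, defK0)$verdict,
               "pathogenic")
})

test_that("selectPathogenic partitions, keeps order, and nests over k", {
  recs <- lapply(0:5, function(k)
    do.call(toyRecord, c(list(sprintf("v%d", k)), damagingProfile(k))))
  tab <- do.call(toyTable, c(recs, list(
    toyRecord("v6", consequence = "frameshift", lof_confidence = "LC"))))

  noLof <- PathogenicityDefinition(minTools = 3,
                                   hcLofIsPathogenic = FALSE)
  sets <- selectPathogenic(tab, noLof)
  expect_equal(records(sets$pathogenic)$variant_id,
               c("v3", "v4", "v5"))
  expect_equal(nrow(records(sets$pathogenic)) +
                 nrow(records(sets$benign)), 7)
  expect_length(intersect(records(sets$pathogenic)$variant_id,
                          records(sets$benign)$variant_id), 0)

  ids <- lapply(1:5, function(k)
    records(selectPathogenic(tab,
      PathogenicityDefinition(minTools = k))$pathogenic)$variant_id)
  for (k in 2:5)
    expect_true(all(ids[[k]] %in% ids[[k - 1]]))

  # adding an evidence mode can only enlarge the pathogenic set
  withEv <- VariantTable(within(records(tab), {
    clinical_case[variant_id == "v0"] <- TRUE
    references[variant_id == "v0"] <- "PMID:2"
  }))
  base <- records(selectPathogenic(withEv,
    PathogenicityDefinition(minTools = 3))$pathogenic)$variant_id
  wide <- records(selectPathogenic(withEv,
    PathogenicityDefinition(minTools = 3,
      evidenceMode = "tools_or_any_evidence"))$pathogenic)$variant_id
  expect_true(all(base %in% wide))
  expect_true("v0" %in% wide)
})

test_that("empirical k-of-n sensitivity matches the exact enumeration", {
  config <- CohortConfig(seed = 42, nVariants = 2000,
                         populations = data.frame(name = "pop",
                                                  sample_size = 1000L),
                         truthPathogenicFraction = 0.5, lofFraction = 0,
                         toolSensitivity = 0.85, toolSpecificity = 0.80)
  cohort <- generateCohort(config)
  calls <- classifyVariants(cohort$records,
                            PathogenicityDefinition(minTools = 2))
  truth <- cohort$truth$is_pathogenic[match(calls$variant_id,
                                            cohort$truth$variant_id)]
  sens <- mean(calls$verdict[truth] == "pathogenic")
  fpr <- mean(calls$verdict[!truth] == "pathogenic")
  expectedSens <- enumConsensusRate(2, rep(0.85, 5))
  expectedFpr <- enumConsensusRate(2, rep(0.20, 5))
  n1 <- sum(truth); n0 <- sum(!truth)
  expect_lt(abs(sens - expectedSens),
            3 * sqrt(expectedSens * (1 - expectedSens) / n1))
  expect_lt(abs(fpr - expectedFpr),
            3 * sqrt(expectedFpr * (1 - expectedFpr) / n0))
})
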