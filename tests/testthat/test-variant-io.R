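test_that("reader parses the shipped table and normalises tokens", {
  tab <- readVariantTable(lepFixturePath())
  df <- records(tab)
  expect_equal(nrow(df), 75)
  expect_equal(sum(df$consequence == "missense"), 68)
  expect_equal(sum(df$consequence %in%
                     c("frameshift", "splice_acceptor",
                       "inframe_deletion")), 7)
  lep <- df[df$variant_id == "rs17151919", ]
  expect_equal(lep$ac, 2377)
  expect_equal(lep$an, 282912)
  expect_equal(lep$nhom, 105)
  # AF computes to 0.84% at the printed precision
  expect_equal(round(100 * lep$ac / lep$an, 2), 0.84)
  expect_equal(lep$clinvar, "benign")
  # empty cells became NA, not tokens
  expect_true(all(is.na(df$sift[df$consequence == "frameshift"])))
})

test_that("reader folds case and maps unknown predictor tokens to NA", {
  df <- rbind(toyRecord("v1", sift = "Deleterious",
                        polyphen2 = "Probably_Damaging",
                        mutationtaster = "DELETERIOUS"),
              toyRecord("v2", sift = "weird-token"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  expect_warning(tab <- readVariantTable(path), "unknown token")
  out <- records(tab)
  expect_equal(out$sift[1], "deleterious")
  expect_equal(out$polyphen2[1], "probably_damaging")
  expect_equal(out$mutationtaster[1], "deleterious")
  expect_true(is.na(out$sift[2]))
})

test_that("reader errors name the missing column and the bad row", {
  df <- toyRecord("v1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[, setdiff(names(df), "nhom")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_error(readVariantTable(path), "nhom")

  df2 <- toyRecord("v1", ac = 30, an = 20)
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  expect_error(readVariantTable(path), "ac > an")
})

test_that("empty data section with a valid header reads as empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(toyRecord("v1")[0, ], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  tab <- readVariantTable(path)
  expect_equal(nrow(records(tab)), 0)
})

test_that("write-then-read round-trips exactly, including NA fields", {
  tab <- toyTable(
    toyRecord("v1", ac = 5, nhom = 2,
              sift = "deleterious", provean = "damaging"),
    toyRecord("v2", consequence = "frameshift", lof_confidence = "HC",
              mutationtaster = "deleterious"),
    toyRecord("v3", clinvar = "uncertain", clinical_case = TRUE,
              references = "PMID:1"))
  for (dialect in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeVariantTable(tab, path, dialect = dialect)
    back <- readVariantTable(path, dialect = dialect)
    expect_equal(records(back), records(tab))
    # deterministic serialisation
    path2 <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeVariantTable(back, path2, dialect = dialect)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("validateRecords reports invariant violations as data", {
  clean <- readVariantTable(lepFixturePath())
  expect_equal(nrow(validateRecords(clean)), 0)

  dirty <- toyTable(
    toyRecord("v1", ac = 5, nhom = 3),                 # nhom > floor(ac/2)
    toyRecord("v2", an = 2001),                        # odd an
    toyRecord("v3", lof_confidence = "HC"),            # HC on missense
    toyRecord("v4", clinical_case = TRUE),             # flag, no refs
    toyRecord("v5", population = "afr", ac = 4),
    toyRecord("v5", population = "nfe", ac = 6),
    toyRecord("v5", population = "ALL", ac = 12))      # 4 + 6 != 12
  rep <- validateRecords(dirty)
  expect_setequal(unique(rep$rule),
                  c("nhom_le_half_ac", "an_even", "lof_confidence_scope",
                    "evidence_references", "population_sum"))
  expect_equal(rep$severity[rep$rule == "an_even"], "warning")
  expect_equal(rep$severity[rep$rule == "population_sum"], "error")
  # input untouched
  expect_equal(records(dirty)$ac[1], 5)
})

test_that("duplicate strata are flagged", {
  dup <- toyTable(toyRecord("v1", pos = 10), toyRecord("v1", pos = 10))
  rep <- validateRecords(dup)
  expect_true("stratum_unique" %in% rep$rule)
})

test_that("aggregateStrata derives ALL rows that re-validate", {
  tab <- toyTable(
    toyRecord("v1", population = "afr", sex = "female", ac = 3, an = 100),
    toyRecord("v1", population = "afr", sex = "male", ac = 1, an = 140),
    toyRecord("v1", population = "nfe", sex = "female", ac = 2, an = 200),
    toyRecord("v1", population = "nfe", sex = "male", ac = 4, an = 160))
  agg <- aggregateStrata(tab)
  df <- records(agg)
  allRow <- df[df$population == "ALL" & df$sex == "ALL", ]
  expect_equal(allRow$ac, 10)
  expect_equal(allRow$an, 600)
  rep <- validateRecords(agg)
  expect_equal(sum(rep$severity == "error"), 0)
  # existing ALL rows are not duplicated
  agg2 <- aggregateStrata(agg)
  expect_equal(nrow(records(agg2)), nrow(df))
})

test_that("mergeEvidence flags matches and returns unmatched separately", {
  tab <- readVariantTable(lepFixturePath())
  merged <- mergeEvidence(tab, lepFixturePath("lep_evidence_synthetic.tsv"))
  df <- records(merged$records)
  expect_true(df$clinical_case[df$variant_id == "rs28954113"])
  expect_true(df$functional_evidence[df$variant_id == "rs17151919"])
  expect_false(df$clinical_case[df$variant_id == "rs17151919"])
  # most literature-reported variants are absent from the database table
  expect_equal(nrow(merged$unmatched), 15)
  expect_true(all(grepl("^lit_only", merged$unmatched$variant_id)))

  # empty evidence table leaves records unchanged
  empty <- data.frame(variant_id = character(0),
                      clinical_case = character(0),
                      functional_evidence = character(0),
                      references = character(0))
  expect_equal(records(mergeEvidence(tab, empty)$records), records(tab))

  # duplicate evidence keys are an error
  dup <- data.frame(variant_id = c("a", "a"), clinical_case = "true",
                    functional_evidence = "false", references = "x")
  expect_error(mergeEvidence(tab, dup), "duplicate")
})
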