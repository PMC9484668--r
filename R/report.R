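# Report tables: per-stratum variant summaries, the pathogenicity-
# definition sweep, and per-population prevalence estimates, rendered as
# machine-readable TSV and aligned text.

.estimateRow <- function(est, rounding = "paper", sigFigs = 3L) {
  def <- est@definition
  fmt <- function(p) formatPrevalenceRatio(p, mode = rounding,
                                           sigFigs = sigFigs)
  data.frame(
    definition = paste0(">=", def@minTools, " tools",
                        if (def@hcLofIsPathogenic && def@minTools >= 1)
                          " or HC LoF" else "",
                        if (def@evidenceMode != "tools_only")
                          paste0(" or ", sub("tools_or_", "",
                                             def@evidenceMode)) else ""),
    population = est@population, sex = est@sex,
    sample_size = est@sampleSize,
    n_variants = est@nVariants,
    het_carriers = est@observedHetCarriers,
    hom_carriers = est@observedHomCarriers,
    p_het = est@pHet, p_hom_incl_ch = est@pHomInclCh,
    p_hom = est@pHom, p_ch = est@pCh,
    ratio_het = fmt(est@pHet),
    ratio_hom_incl_ch = fmt(est@pHomInclCh),
    ratio_hom = fmt(est@pHom),
    ratio_ch = fmt(est@pCh),
    stringsAsFactors = FALSE)
}

#' Render prevalence estimates as a report table
#'
#' Fixed column order: definition, stratum, counts, the four prevalence
#' components, and each probability also as a "1: N" ratio. NA estimates
#' (zero pathogenic variants in the stratum) render as "NA", never as a
#' ratio.
#'
#' @param estimates a \code{PrevalenceEstimate} or list of them (e.g. from
#'   \code{\link{thresholdSweep}}).
#' @param rounding ratio rounding mode, see
#'   \code{\link{formatPrevalenceRatio}}.
#' @param sigFigs significant figures for \code{rounding = "sigfigs"}.
#' @return data.frame, one row per estimate.
#' @export
renderTables <- function(estimates, rounding = c("paper", "integer",
                                                 "sigfigs"),
                         sigFigs = 3L) {
  rounding <- match.arg(rounding)
  if (methods::is(estimates, "PrevalenceEstimate"))
    estimates <- list(estimates)
  out <- do.call(rbind, lapply(estimates, .estimateRow,
                               rounding = rounding, sigFigs = sigFigs))
  rownames(out) <- NULL
  out
}

#' Per-stratum variant summary
#'
#' One row per population x sex stratum present in the table: sample size
#' (an/2 of the deepest-covered variant), number of variants observed
#' (\code{ac > 0}), non-synonymous and LoF-class counts, the most common
#' variant with its allele frequency, and the population-size-corrected
#' occurrence rate.
#'
#' @param x a \code{VariantTable}.
#' @return data.frame.
#' @export
summaryTable <- function(x) {
  df <- records(x)
  key <- paste(df$population, df$sex, sep = "|")
  rows <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[sub$ac > 0, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    N <- max(sub$an) / 2
    top <- which.max(sub$ac / sub$an)
    data.frame(population = sub$population[1], sex = sub$sex[1],
               sample_size = N,
               n_variants = nrow(sub),
               n_nonsynonymous = sum(sub$consequence == "missense"),
               n_lof = sum(sub$consequence %in% .LOF_CONSEQUENCES),
               most_common_variant = sub$variant_id[top],
               most_common_af = sub$ac[top] / sub$an[top],
               occurrence_rate = occurrenceRate(nrow(sub), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$population != "ALL", out$population, out$sex), ,
      drop = FALSE]
}

#' Per-population prevalence table
#'
#' Estimates prevalence under one definition for every population x sex
#' stratum present in the table.
#'
#' @param x a \code{VariantTable}.
#' @param definition a \code{\link{PathogenicityDefinition}}.
#' @param rounding,sigFigs ratio formatting, see
#'   \code{\link{formatPrevalenceRatio}}.
#' @return data.frame in \code{\link{renderTables}} layout, one row per
#'   stratum.
#' @export
populationTable <- function(x, definition = PathogenicityDefinition(),
                            rounding = "paper", sigFigs = 3L) {
  df <- records(x)
  strata <- unique(df[, c("population", "sex")])
  strata <- strata[order(strata$population != "ALL", strata$population,
                         strata$sex), , drop = FALSE]
  ests <- lapply(seq_len(nrow(strata)), function(i)
    estimatePrevalence(x, definition, population = strata$population[i],
                       sex = strata$sex[i]))
  renderTables(ests, rounding = rounding, sigFigs = sigFigs)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

.writeText <- function(df, path) {
  txt <- utils::capture.output(print(df, row.names = FALSE))
  writeLines(txt, path)
  path
}

#' Run the full estimation workflow on a variant table file
#'
#' Reads and validates the table (error-severity violations abort with the
#' validation report), then writes three report tables to \code{outDir}:
#' \code{summary} (per-stratum variant counts and occurrence rates),
#' \code{sweep} (the consensus-threshold sweep for the main stratum) and
#' \code{populations} (per-stratum prevalence under the chosen
#' definition). Each is written as TSV and aligned text. Progress goes to
#' \code{message()}; outputs are deterministic functions of the input.
#'
#' @param input path to the variant table.
#' @param outDir output directory (created if absent).
#' @param definition a \code{\link{PathogenicityDefinition}}.
#' @param kValues thresholds for the sweep.
#' @param population,sex main stratum for the sweep.
#' @param rounding,sigFigs ratio formatting.
#' @param dialect input delimiter.
#' @return invisibly, a list with the report data.frames and file paths.
#' @export
cmdEstimate <- function(input, outDir,
                        definition = PathogenicityDefinition(),
                        kValues = 0:3, population = "ALL", sex = "ALL",
                        rounding = "paper", sigFigs = 3L,
                        dialect = "tsv") {
  tab <- readVariantTable(input, dialect = dialect)
  violations <- validateRecords(tab)
  errors <- violations[violations$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0) {
    print(errors)
    stop("input failed validation with ", nrow(errors), " error(s)",
         call. = FALSE)
  }
  if (nrow(violations) > 0)
    message("validation: ", nrow(violations), " warning(s)")
  message("read ", nrow(records(tab)), " records, ",
          length(variantIds(tab)), " variants")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  summary <- summaryTable(tab)
  sweep <- renderTables(thresholdSweep(tab, kValues = kValues,
                                       template = definition,
                                       population = population, sex = sex),
                        rounding = rounding, sigFigs = sigFigs)
  pops <- populationTable(tab, definition, rounding = rounding,
                          sigFigs = sigFigs)
  paths <- c(
    .writeTsv(summary, file.path(outDir, "summary.tsv")),
    .writeText(summary, file.path(outDir, "summary.txt")),
    .writeTsv(sweep, file.path(outDir, "sweep.tsv")),
    .writeText(sweep, file.path(outDir, "sweep.txt")),
    .writeTsv(pops, file.path(outDir, "populations.tsv")),
    .writeText(pops, file.path(outDir, "populations.txt")))
  message("wrote ", length(paths), " report files to ", outDir)
  invisible(list(summary = summary, sweep = sweep, populations = pops,
                 paths = paths))
}

#' Simulate a cohort to disk with a ground-truth sidecar
#'
#' Generates a cohort from the config, writes the variant table and the
#' truth table, and reports per-population recovery: true aggregate
#' pathogenic q versus the estimate obtained by running the classifier and
#' HWE estimator on the simulated table, plus classifier accuracy against
#' the truth labels.
#'
#' @param config a \code{\link{CohortConfig}}.
#' @param outDir output directory.
#' @param definition classification rule used for the recovery summary.
#' @return invisibly, a list with the cohort, truth and recovery summary.
#' @export
cmdSimulate <- function(config, outDir,
                        definition = PathogenicityDefinition()) {
  cohort <- generateCohort(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohortPath <- file.path(outDir, "cohort.tsv")
  writeVariantTable(cohort$records, cohortPath)
  truthPath <- file.path(outDir, "truth.tsv")
  utils::write.table(cohort$truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  recovery <- do.call(rbind, lapply(unique(truth$population), function(p) {
    sub <- truth[truth$population == p, , drop = FALSE]
    est <- estimatePrevalence(cohort$records, definition, population = p,
                              sex = "ALL")
    calls <- classifyVariants(stratumSubset(cohort$records, p, "ALL",
                                            drop = FALSE), definition)
    accuracy <- mean((calls$verdict == "pathogenic") ==
                       sub$is_pathogenic[match(calls$variant_id,
                                               sub$variant_id)])
    data.frame(population = p,
               true_q = sum(sub$true_q[sub$is_pathogenic]),
               estimated_q = est@q,
               n_pathogenic_true = sum(sub$is_pathogenic),
               n_pathogenic_called = est@nVariants,
               classifier_accuracy = accuracy,
               stringsAsFactors = FALSE)
  }))
  .writeTsv(recovery, file.path(outDir, "recovery.tsv"))
  message("cohort written to ", cohortPath)
  invisible(list(records = cohort$records, truth = truth,
                 recovery = recovery,
                 paths = c(cohortPath, truthPath,
                           file.path(outDir, "recovery.tsv"))))
}
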