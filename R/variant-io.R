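# Reading, validating and writing the long-format variant table
# (one row per variant x population x sex stratum, gnomAD-style counts).

.normalizeToken <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ -]+", "_", x)
}

# map raw strings onto a controlled vocabulary; unknown tokens -> NA + warning
.normalizeEnum <- function(x, levels, column, na.token = NA_character_,
                           case.map = identity) {
  raw <- as.character(x)
  tok <- case.map(.normalizeToken(raw))
  tok[is.na(raw) | tok == "" | tok == "na"] <- na.token
  unknown <- !is.na(tok) & !tok %in% c(levels, na.token)
  if (any(unknown)) {
    warning(sprintf("column '%s': %d unknown token(s) (%s) set to NA",
                    column, sum(unknown),
                    paste(unique(tok[unknown]), collapse = ", ")),
            call. = FALSE)
    tok[unknown] <- na.token
  }
  tok
}

.CONSEQUENCE_SYNONYMS <- c(
  missense_variant = "missense", frameshift_variant = "frameshift",
  stop_gained_variant = "stop_gained", splice_acceptor_variant =
    "splice_acceptor", inframe_deletion_variant = "inframe_deletion")

.parseLogical <- function(x, column) {
  tok <- .normalizeToken(x)
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "t", "1", "yes")] <- TRUE
  out[tok %in% c("false", "f", "0", "no", "", "na") | is.na(x)] <- FALSE
  if (anyNA(out))
    stop(sprintf("column '%s': unparseable logical value(s): %s", column,
                 paste(unique(tok[is.na(out)]), collapse = ", ")),
         call. = FALSE)
  out
}

#' Read a variant table from a delimited file
#'
#' Parses the long-format table (TSV by default) with mandatory columns
#' \code{variant_id, chrom, pos, ref, alt, consequence, population, sex, ac,
#' an, nhom, sift, polyphen2, mutationtaster, fathmm_mkl, provean,
#' lof_confidence, clinvar} and optional evidence columns
#' \code{clinical_case, functional_evidence, references}. Enum tokens are
#' normalised case-insensitively (spaces and hyphens fold to underscores);
#' unknown predictor tokens degrade to NA with a warning. An empty ClinVar
#' cell means the variant is absent from ClinVar.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return A \code{\link[=VariantTable-class]{VariantTable}}.
#' @examples
#' tab <- readVariantTable(system.file("extdata",
#'   "lep_gnomad_all_synthetic.tsv", package = "CarrierFreq"))
#' tab
#' @export
readVariantTable <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           na.strings = NULL, check.names = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing) > 0)
    stop("schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  df <- data.frame(variant_id = trimws(raw$variant_id),
                   chrom = trimws(raw$chrom),
                   pos = as.numeric(raw$pos),
                   ref = toupper(trimws(raw$ref)),
                   alt = toupper(trimws(raw$alt)),
                   stringsAsFactors = FALSE)
  csq <- .normalizeToken(raw$consequence)
  hit <- csq %in% names(.CONSEQUENCE_SYNONYMS)
  csq[hit] <- .CONSEQUENCE_SYNONYMS[csq[hit]]
  unknown <- !csq %in% .CONSEQUENCES
  if (any(unknown)) {
    warning(sprintf("column 'consequence': %d unknown token(s) (%s) mapped to 'other'",
                    sum(unknown), paste(unique(csq[unknown]), collapse = ", ")),
            call. = FALSE)
    csq[unknown] <- "other"
  }
  df$consequence <- csq
  df$population <- trimws(raw$population)
  df$sex <- .normalizeEnum(raw$sex, .SEX_LEVELS, "sex",
                           case.map = function(x) {
                             x[x == "all"] <- "ALL"
                             x
                           })
  for (col in c("ac", "an", "nhom")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      stop(sprintf("column '%s': non-numeric value in row(s) %s", col,
                   paste(utils::head(which(is.na(v)), 5), collapse = ", ")),
           call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(df$ac > df$an)
  if (length(bad) > 0)
    stop(sprintf("validation error: ac > an for row(s) %s (variant %s)",
                 paste(utils::head(bad, 5), collapse = ", "),
                 paste(utils::head(df$variant_id[bad], 5), collapse = ", ")),
         call. = FALSE)
  for (tool in .TOOLS)
    df[[tool]] <- .normalizeEnum(raw[[tool]], .TOOL_LEVELS[[tool]], tool)
  df$lof_confidence <- .normalizeEnum(
    raw$lof_confidence, .LOF_LEVELS, "lof_confidence",
    case.map = function(x) {
      x[x %in% c("hc", "high_confidence")] <- "HC"
      x[x %in% c("lc", "low_confidence")] <- "LC"
      x
    })
  cv <- .normalizeEnum(raw$clinvar, .CLINVAR_LEVELS, "clinvar",
                       na.token = "absent",
                       case.map = function(x) {
                         x[x == "uncertain_significance"] <- "uncertain"
                         x
                       })
  df$clinvar <- cv
  df$clinical_case <- if (is.null(raw$clinical_case)) rep(FALSE, n) else
    .parseLogical(raw$clinical_case, "clinical_case")
  df$functional_evidence <- if (is.null(raw$functional_evidence))
    rep(FALSE, n) else .parseLogical(raw$functional_evidence,
                                     "functional_evidence")
  df$references <- if (is.null(raw$references)) rep("", n) else
    ifelse(is.na(raw$references), "", trimws(raw$references))
  VariantTable(df)
}

#' Validate the scientific invariants of a variant table
#'
#' Checks, without throwing, that allele counts are internally consistent
#' (\code{ac <= an}, \code{nhom <= floor(ac/2)}), that strata are unique
#' per variant, that "ALL" rows equal the sum of their per-population (and
#' female+male) constituents, that LoF-confidence labels appear only on
#' LoF-class consequences, and that evidence flags carry references. Odd
#' \code{an} on an autosome and sex-sum mismatches are reported at
#' "warning" severity (coverage differs between sexes in exome data);
#' everything else is an "error".
#'
#' @param x a \code{VariantTable}.
#' @return data.frame with columns \code{rule}, \code{severity},
#'   \code{variant_id}, \code{population}, \code{sex}, \code{message};
#'   zero rows when the table is clean.
#' @export
setMethod("validateRecords", "VariantTable", function(x, ...) {
  df <- records(x)
  out <- list()
  add <- function(rule, severity, rows, message) {
    if (length(rows) == 0) return()
    out[[length(out) + 1]] <<- data.frame(
      rule = rule, severity = severity,
      variant_id = df$variant_id[rows],
      population = df$population[rows], sex = df$sex[rows],
      message = message, stringsAsFactors = FALSE)
  }
  add("ac_le_an", "error", which(df$ac > df$an), "ac exceeds an")
  add("nhom_le_half_ac", "error", which(df$nhom > floor(df$ac / 2)),
      "nhom exceeds floor(ac/2)")
  add("an_even", "warning", which(df$an %% 2 != 0),
      "odd an in autosomal stratum")
  key <- paste(df$chrom, df$pos, df$ref, df$alt, df$population, df$sex,
               sep = "|")
  add("stratum_unique", "error", which(duplicated(key)),
      "duplicate (chrom,pos,ref,alt,stratum)")
  add("lof_confidence_scope", "error",
      which(!is.na(df$lof_confidence) &
              !df$consequence %in% .LOF_CONSEQUENCES),
      "LoF confidence on a non-LoF consequence")
  add("evidence_references", "error",
      which((df$clinical_case | df$functional_evidence) &
              (is.na(df$references) | df$references == "")),
      "evidence flag set without references")

  # ALL rows must equal the sum of their constituents
  sumCheck <- function(allMask, partMask, groupCols, rule, severity, label) {
    allRows <- which(allMask)
    for (i in allRows) {
      sel <- partMask
      for (col in groupCols) sel <- sel & df[[col]] == df[[col]][i]
      if (!any(sel)) next
      for (col in c("ac", "an", "nhom")) {
        if (sum(df[[col]][sel]) != df[[col]][i]) {
          add(rule, severity, i,
              sprintf("%s: ALL %s = %g but constituents sum to %g",
                      label, col, df[[col]][i], sum(df[[col]][sel])))
          break
        }
      }
    }
  }
  sumCheck(df$population == "ALL", df$population != "ALL",
           c("variant_id", "sex"), "population_sum", "error",
           "population sum")
  sumCheck(df$sex == "ALL", df$sex %in% c("female", "male"),
           c("variant_id", "population"), "sex_sum", "warning", "sex sum")

  if (length(out) == 0)
    data.frame(rule = character(0), severity = character(0),
               variant_id = character(0), population = character(0),
               sex = character(0), message = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
})

#' Merge a literature-evidence table into a variant table
#'
#' The evidence table (columns \code{variant_id}, \code{clinical_case},
#' \code{functional_evidence}, \code{references}) is joined by
#' \code{variant_id}; flags are OR-ed onto every stratum row of a matching
#' variant and references appended. Evidence rows for variants absent from
#' the table are returned separately: most literature-reported pathogenic
#' variants of a rare-disease gene never appear in a reference database.
#'
#' @param x a \code{VariantTable}.
#' @param evidence file path or data.frame.
#' @param dialect delimiter when \code{evidence} is a path.
#' @return list with elements \code{records} (updated \code{VariantTable})
#'   and \code{unmatched} (data.frame of evidence rows with no match).
#' @export
mergeEvidence <- function(x, evidence, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (is.character(evidence)) {
    sep <- if (dialect == "tsv") "\t" else ","
    evidence <- utils::read.table(evidence, header = TRUE, sep = sep,
                                  colClasses = "character", quote = "\"",
                                  na.strings = NULL,
                                  stringsAsFactors = FALSE)
  }
  need <- c("variant_id", "clinical_case", "functional_evidence",
            "references")
  missing <- setdiff(need, names(evidence))
  if (length(missing) > 0)
    stop("evidence table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(evidence$variant_id))
    stop("duplicate variant_id in evidence table: ",
         paste(unique(evidence$variant_id[duplicated(evidence$variant_id)]),
               collapse = ", "), call. = FALSE)
  evidence$clinical_case <- .parseLogical(evidence$clinical_case,
                                          "clinical_case")
  evidence$functional_evidence <- .parseLogical(evidence$functional_evidence,
                                                "functional_evidence")
  df <- records(x)
  hit <- evidence$variant_id %in% df$variant_id
  for (i in which(hit)) {
    rows <- df$variant_id == evidence$variant_id[i]
    df$clinical_case[rows] <- df$clinical_case[rows] | evidence$clinical_case[i]
    df$functional_evidence[rows] <-
      df$functional_evidence[rows] | evidence$functional_evidence[i]
    ref <- trimws(evidence$references[i])
    if (!is.na(ref) && ref != "") {
      old <- df$references[rows]
      df$references[rows] <- ifelse(old == "" | is.na(old), ref,
                                    ifelse(old == ref, old,
                                           paste(old, ref, sep = "; ")))
    }
  }
  list(records = VariantTable(df),
       unmatched = evidence[!hit, , drop = FALSE])
}

#' Write a variant table to a delimited file
#'
#' Serialises enums as their lowercase tokens and NA as an empty field so
#' that \code{readVariantTable(writeVariantTable(x))} round-trips exactly.
#'
#' @param x a \code{VariantTable}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- records(x)
  out <- df
  for (col in c("pos", "ac", "an", "nhom"))
    out[[col]] <- format(df[[col]], scientific = FALSE, trim = TRUE)
  for (col in c(.TOOLS, "lof_confidence", "clinvar"))
    out[[col]] <- ifelse(is.na(df[[col]]), "", df[[col]])
  for (col in c("clinical_case", "functional_evidence"))
    out[[col]] <- ifelse(df[[col]], "true", "false")
  out <- out[, c(.MANDATORY_COLS, .OPTIONAL_COLS)]
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Derive missing "ALL" strata by summation
#'
#' For every sex level present, adds a \code{population = "ALL"} row per
#' variant summing \code{ac}, \code{an}, \code{nhom} over the
#' per-population rows; likewise adds \code{sex = "ALL"} rows summing
#' female + male within each population. Existing ALL rows are left
#' untouched. Predictor calls and evidence flags are per-variant, not
#' per-stratum, and are copied from the first constituent row.
#'
#' @param x a \code{VariantTable}.
#' @return A \code{VariantTable} including the derived rows.
#' @export
aggregateStrata <- function(x) {
  df <- records(x)
  sumRows <- function(sub, population, sex) {
    out <- sub[1, , drop = FALSE]
    out$population <- population
    out$sex <- sex
    out$ac <- sum(sub$ac)
    out$an <- sum(sub$an)
    out$nhom <- sum(sub$nhom)
    out
  }
  derive <- function(df, overPopulation) {
    parts <- if (overPopulation)
      df[df$population != "ALL", , drop = FALSE]
    else df[df$sex %in% c("female", "male"), , drop = FALSE]
    if (nrow(parts) == 0) return(df)
    groupCols <- if (overPopulation) c("variant_id", "sex") else
      c("variant_id", "population")
    key <- do.call(paste, c(parts[groupCols], sep = "|"))
    new <- lapply(split(seq_len(nrow(parts)), key), function(idx) {
      sub <- parts[idx, , drop = FALSE]
      population <- if (overPopulation) "ALL" else sub$population[1]
      sex <- if (overPopulation) sub$sex[1] else "ALL"
      exists <- any(df$variant_id == sub$variant_id[1] &
                      df$population == population & df$sex == sex)
      if (exists) NULL else sumRows(sub, population, sex)
    })
    rbind(df, do.call(rbind, new))
  }
  df <- derive(df, overPopulation = FALSE)
  df <- derive(df, overPopulation = TRUE)
  rownames(df) <- NULL
  VariantTable(df)
}
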