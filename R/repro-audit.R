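# Value-level and article-level analytic-reproducibility classification:
# percentage error, the four-way error taxonomy, article outcomes, and the
# tallies over value types and issue loci.

value_type_levels <- c("count_proportion", "confidence_interval",
                       "mean_median", "degrees_of_freedom", "effect_size",
                       "test_statistic", "p_value", "sd_se", "misc")

classification_levels <- c("match", "minor_numerical", "major_numerical",
                           "decision_error", "insufficient_information")

outcome_levels <- c("reproducible", "reproducible_with_assistance",
                    "not_fully_reproducible",
                    "not_fully_reproducible_despite_assistance")

locus_levels <- c("typographical", "analysis_underspecified",
                  "original_analysis_issue", "data_file_issue",
                  "unidentified")

audit_columns <- c("article_id", "value_type", "reported_raw",
                   "obtained_before", "obtained_after", "assistance_requested")

#' Parse a reported value as printed
#'
#' Splits a printed statistic such as `"4.20"`, `"-0.50"` or `"<0.001"`
#' into its numeric value, the number of printed decimal places, and any
#' inequality prefix. The printed precision is retained because re-obtained
#' values are rounded to it before computing percentage error.
#'
#' @param raw character vector of printed values.
#' @return a data frame with columns `value`, `decimals`, `inequality`
#'   (`"<"`, `">"` or `""`).
#' @export
parse_reported <- function(raw) {
  raw <- trimws(raw)
  ineq <- ifelse(startsWith(raw, "<"), "<", ifelse(startsWith(raw, ">"), ">", ""))
  num <- ifelse(ineq == "", raw, substring(raw, 2))
  num <- trimws(num)
  value <- suppressWarnings(as.numeric(num))
  if (any(is.na(value)))
    stop_domain("unparseable reported value: ",
                paste(unique(raw[is.na(value)]), collapse = ", "))
  decimals <- ifelse(grepl("\\.", num),
                     nchar(sub("^-?[0-9]*\\.", "", num)), 0L)
  data.frame(value = value, decimals = as.integer(decimals),
             inequality = ineq, stringsAsFactors = FALSE)
}

#' Percentage error between a reported and a re-obtained value
#'
#' `PE = |obtained - reported| / |reported| * 100`, after first rounding the
#' obtained value to the reported value's printed precision (so values that
#' agree at printed precision have PE exactly 0). The absolute value in the
#' denominator makes PE positive for negative reported values. A reported
#' value of exactly zero is a flagged zero-denominator case: PE is 0 when
#' the obtained value also rounds to zero at printed precision, and `Inf`
#' (classified as a major numerical error) otherwise.
#'
#' @param reported the reported (printed) value.
#' @param obtained the re-obtained value.
#' @param decimals printed decimal places of the reported value; `NULL`
#'   (default) skips the printed-precision rounding.
#' @return non-negative percentage error.
#' @export
percentage_error <- function(reported, obtained, decimals = NULL) {
  if (!is.null(decimals)) obtained <- round(obtained, decimals)
  if (reported == 0) {
    return(if (obtained == 0) 0 else Inf)
  }
  abs(obtained - reported) / abs(reported) * 100
}

.classify_pe <- function(pe) {
  if (pe == 0) "match" else if (pe < 10) "minor_numerical" else "major_numerical"
}

# p <= 0.05 vs p > 0.05 sides; boundary equality on both sides of the
# comparison means no decision error
.p_side_le05 <- function(p) p <= 0.05

.parse_obtained <- function(x) {
  # numeric string, "insufficient", "unattempted"/"" (not available)
  x <- trimws(as.character(x))
  if (x %in% c("insufficient")) return(list(flag = "insufficient", value = NA_real_))
  if (x %in% c("", "unattempted", NA_character_))
    return(list(flag = "unattempted", value = NA_real_))
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop_domain("unparseable obtained value: ", x)
  list(flag = "value", value = v)
}

#' Classify one target value at a given audit stage
#'
#' Applies the four-way error taxonomy to a single reported statistic and
#' its re-obtained counterpart. An insufficient-information flag on the
#' obtained slot dominates. Otherwise the percentage error (at printed
#' precision) defines a match (PE = 0), a minor numerical error
#' (0 < PE < 10) or a major numerical error (PE >= 10). For p-values a
#' decision error -- reported and obtained values on opposite sides of the
#' 0.05 boundary -- takes precedence over a major numerical error, but the
#' PE-based class is retained in `pe_classification` so error tallies can
#' still count p-value numerical errors. Inequality-form reported values
#' (e.g. `"<0.001"`) never contribute numeric PE: they are a match when the
#' obtained value satisfies the inequality, otherwise they are classified
#' by the decision rule (for p-values) or as a major numerical error.
#'
#' @param record a one-row list or data frame with fields `value_type`,
#'   `reported_raw`, `obtained_before`, `obtained_after`,
#'   `assistance_requested`.
#' @param stage `"before_assistance"` or `"after_assistance"`; at the
#'   after stage the before value is used when no assistance was requested.
#' @return a list with `pe`, `classification`, `pe_classification`,
#'   `stage`.
#' @export
classify_value <- function(record, stage = c("before_assistance", "after_assistance")) {
  stage <- match.arg(stage)
  rep_parsed <- parse_reported(record$reported_raw)
  use_after <- stage == "after_assistance" && isTRUE(record$assistance_requested)
  obt <- .parse_obtained(if (use_after) record$obtained_after else record$obtained_before)

  if (obt$flag == "insufficient" ||
      (obt$flag == "unattempted" && use_after))
    return(list(pe = NA_real_, classification = "insufficient_information",
                pe_classification = "insufficient_information", stage = stage))
  if (obt$flag == "unattempted")
    return(list(pe = NA_real_, classification = "insufficient_information",
                pe_classification = "insufficient_information", stage = stage))

  is_p <- record$value_type == "p_value"

  if (rep_parsed$inequality != "") {
    satisfied <- switch(rep_parsed$inequality,
                        "<" = obt$value < rep_parsed$value,
                        ">" = obt$value > rep_parsed$value)
    if (satisfied)
      return(list(pe = NA_real_, classification = "match",
                  pe_classification = "match", stage = stage))
    if (is_p) {
      # the printed bound determines the reported side of 0.05
      rep_le <- if (rep_parsed$inequality == "<") rep_parsed$value <= 0.05 else FALSE
      obt_le <- .p_side_le05(obt$value)
      cls <- if (rep_le != obt_le) "decision_error" else "major_numerical"
      return(list(pe = NA_real_, classification = cls,
                  pe_classification = "major_numerical", stage = stage))
    }
    return(list(pe = NA_real_, classification = "major_numerical",
                pe_classification = "major_numerical", stage = stage))
  }

  pe <- percentage_error(rep_parsed$value, obt$value, rep_parsed$decimals)
  pe_cls <- .classify_pe(pe)
  cls <- pe_cls
  if (is_p && pe > 0 &&
      .p_side_le05(rep_parsed$value) != .p_side_le05(obt$value))
    cls <- "decision_error"
  list(pe = pe, classification = cls, pe_classification = pe_cls, stage = stage)
}

#' Classify every row of an audit table at a given stage
#'
#' @param audit an audit table (data frame with the columns of
#'   [read_audit_table()]).
#' @param stage `"before_assistance"` or `"after_assistance"`.
#' @return a data frame with one row per target value: `article_id`,
#'   `value_type`, `pe`, `classification`, `pe_classification`, `stage`.
#' @export
classify_values <- function(audit, stage = c("before_assistance", "after_assistance")) {
  stage <- match.arg(stage)
  res <- lapply(seq_len(nrow(audit)), function(i)
    classify_value(audit[i, , drop = FALSE], stage))
  data.frame(article_id = audit$article_id,
             value_type = audit$value_type,
             pe = vapply(res, `[[`, numeric(1), "pe"),
             classification = vapply(res, `[[`, character(1), "classification"),
             pe_classification = vapply(res, `[[`, character(1), "pe_classification"),
             stage = stage, stringsAsFactors = FALSE)
}

.blocking <- c("major_numerical", "decision_error", "insufficient_information")

#' Article-level reproducibility outcome
#'
#' Evaluates all target values of one article at the final stage (after
#' author assistance when assistance was requested, otherwise before) and
#' assigns the overall outcome: any remaining insufficient-information,
#' major numerical or decision error makes the article not fully
#' reproducible; only minor errors or exact matches make it reproducible.
#' The with/despite-assistance variants record whether author assistance
#' was needed to reach (or failed to rescue) that state: an article whose
#' target values were already free of blocking errors before assistance is
#' `reproducible` outright.
#'
#' @param records the audit-table rows of a single article.
#' @return a list with `article_id`, `outcome`, `assistance_requested`, and
#'   `counts` (named final-stage classification counts).
#' @export
classify_article <- function(records) {
  if (nrow(records) == 0L) stop_domain("no records for article")
  if (length(unique(records$article_id)) != 1L)
    stop_domain("records must all share one article_id")
  assistance <- any(records$assistance_requested)
  before <- classify_values(records, "before_assistance")
  final <- if (assistance) classify_values(records, "after_assistance") else before
  clean_before <- !any(before$classification %in% .blocking)
  clean_final <- !any(final$classification %in% .blocking)
  outcome <- if (clean_before) "reproducible"
  else if (clean_final) "reproducible_with_assistance"
  else if (assistance) "not_fully_reproducible_despite_assistance"
  else "not_fully_reproducible"
  counts <- table(factor(final$classification, levels = classification_levels))
  list(article_id = records$article_id[1], outcome = outcome,
       assistance_requested = assistance,
       counts = as.integer(counts) |> stats::setNames(classification_levels))
}

#' Article-level outcomes for a whole audit table
#'
#' @param audit an audit table.
#' @return a data frame with one row per article: `article_id`, `outcome`,
#'   `assistance_requested`.
#' @export
classify_articles <- function(audit) {
  ids <- unique(audit$article_id)
  res <- lapply(ids, function(id)
    classify_article(audit[audit$article_id == id, , drop = FALSE]))
  data.frame(article_id = ids,
             outcome = vapply(res, `[[`, character(1), "outcome"),
             assistance_requested = vapply(res, `[[`, logical(1),
                                           "assistance_requested"),
             stringsAsFactors = FALSE)
}

#' Tally value-level classifications by value type
#'
#' Cross-tabulates value assessments over value type and classification,
#' and reports each value type's share of the major numerical errors (the
#' breakdown the audit reports alongside the error counts).
#'
#' @param assessments output of [classify_values()].
#' @return an object of class `value_tally`: list with `counts` (value type
#'   x classification matrix), `n`, and `major_share` (proportion of major
#'   errors per value type).
#' @export
tally_value_errors <- function(assessments) {
  counts <- table(factor(assessments$value_type, levels = value_type_levels),
                  factor(assessments$classification, levels = classification_levels))
  counts <- unclass(counts)
  majors <- counts[, "major_numerical"]
  structure(list(counts = counts,
                 n = nrow(assessments),
                 major_share = if (sum(majors) > 0) majors / sum(majors)
                 else majors * 0),
            class = "value_tally")
}

#' @export
print.value_tally <- function(x, ...) {
  cat(sprintf("%d target values\n", x$n))
  print(x$counts[rowSums(x$counts) > 0, colSums(x$counts) > 0, drop = FALSE])
  invisible(x)
}

#' Tally reproducibility issues by causal locus and resolution
#'
#' @param issues an issue table (columns `article_id`, `locus`,
#'   `resolved_by_authors`).
#' @return an object of class `issue_tally`: list with `counts` (locus x
#'   resolved matrix), `n`, `resolution_rate` per locus.
#' @export
tally_issue_loci <- function(issues) {
  counts <- table(factor(issues$locus, levels = locus_levels),
                  factor(issues$resolved_by_authors, levels = c(FALSE, TRUE)))
  counts <- unclass(counts)
  colnames(counts) <- c("unresolved", "resolved")
  totals <- rowSums(counts)
  rate <- ifelse(totals > 0, counts[, "resolved"] / totals, NA_real_)
  structure(list(counts = counts, n = nrow(issues), resolution_rate = rate),
            class = "issue_tally")
}

#' @export
print.issue_tally <- function(x, ...) {
  cat(sprintf("%d reproducibility issues\n", x$n))
  print(cbind(x$counts, rate = round(x$resolution_rate, 2)))
  invisible(x)
}

# audit / issue table IO -------------------------------------------------------

#' Read an audit table from CSV
#'
#' One row per target value: `article_id`, `value_type` (one of the nine
#' audit value types), `reported_raw` (the value as printed, possibly with
#' an inequality prefix), `obtained_before` and `obtained_after` (a number,
#' `insufficient`, `unattempted`, or empty), and `assistance_requested`
#' (`true`/`false`). `obtained_after` may carry a value only when
#' assistance was requested.
#'
#' @param path CSV path.
#' @return a validated audit data frame.
#' @export
read_audit_table <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(audit_columns, names(raw))
  if (length(missing_cols))
    stop_domain("audit table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  raw$assistance_requested <- c("true" = TRUE, "false" = FALSE)[raw$assistance_requested]
  validate_audit_table(raw)
}

validate_audit_table <- function(audit) {
  if (!all(audit$value_type %in% value_type_levels))
    stop_domain("invalid value_type: ",
                paste(setdiff(unique(audit$value_type), value_type_levels),
                      collapse = ", "))
  if (any(is.na(audit$assistance_requested)))
    stop_domain("assistance_requested must be true/false")
  parse_reported(audit$reported_raw)  # errors on unparseable entries
  has_after <- !(trimws(audit$obtained_after) %in% c("", "unattempted"))
  if (any(has_after & !audit$assistance_requested))
    stop_domain("obtained_after present for a row without assistance_requested")
  audit
}

#' Write an audit table to CSV
#' @param audit an audit data frame.
#' @param path output path.
#' @export
write_audit_table <- function(audit, path) {
  out <- audit[audit_columns]
  out$assistance_requested <- ifelse(out$assistance_requested, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read an issue table from CSV
#'
#' One row per discrete reproducibility issue: `article_id`, `locus` (one
#' of `typographical`, `analysis_underspecified`,
#' `original_analysis_issue`, `data_file_issue`, `unidentified`) and
#' `resolved_by_authors` (`true`/`false`).
#'
#' @param path CSV path.
#' @return a validated issue data frame.
#' @export
read_issue_table <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("article_id", "locus", "resolved_by_authors")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_domain("issue table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  raw$resolved_by_authors <- c("true" = TRUE, "false" = FALSE)[raw$resolved_by_authors]
  if (!all(raw$locus %in% locus_levels))
    stop_domain("invalid locus: ",
                paste(setdiff(unique(raw$locus), locus_levels), collapse = ", "))
  raw
}

#' Write an issue table to CSV
#' @param issues an issue data frame.
#' @param path output path.
#' @export
write_issue_table <- function(issues, path) {
  out <- issues[c("article_id", "locus", "resolved_by_authors")]
  out$resolved_by_authors <- ifelse(out$resolved_by_authors, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
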