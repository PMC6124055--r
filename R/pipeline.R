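# End-to-end orchestration of the policy evaluation (study 1) and the
# reproducibility audit (study 2), and machine-readable report output.

#' Run the open-data-policy evaluation on a coding table
#'
#' Produces the full study-1 result bundle: the reusability cascade with
#' per-period counts, Wilson continuity-corrected CIs for the
#' data-available-statement (DAS) proportions, uncorrected Pearson
#' chi-squared tests for the DAS and reusability 2x2 tables, 50-day binned
#' time series of both outcomes, the segmented logistic ITS fit on DAS
#' inclusion with risk-ratio effect estimates and the three-way trend
#' decomposition, and (optionally) the same ITS block for the in-principle
#' reusability outcome.
#'
#' @param coding a [coding_table] or path to a coding CSV.
#' @param policy_date required when `coding` is a path.
#' @param bin_width width of time bins in days (default 50).
#' @param include_reusability also fit the ITS model on the reusability
#'   outcome (default TRUE).
#' @param level confidence level (default 0.95).
#' @return an object of class `study1_report`.
#' @export
run_study1 <- function(coding, policy_date = NULL, bin_width = 50,
                       include_reusability = TRUE, level = 0.95) {
  table <- if (inherits(coding, "coding_table")) coding
  else read_coding_table(coding, policy_date)
  table <- derive_period_and_reusability(table)
  if (!any(table$post) || all(table$post))
    stop_domain("coding table must contain articles in both the pre- and ",
                "post-policy period")

  cascade <- summarize_cascade(table)
  das_ci <- list(
    pre = wilson_cc_interval(cascade$n_das[cascade$period == "pre"],
                             cascade$n_articles[cascade$period == "pre"], level),
    post = wilson_cc_interval(cascade$n_das[cascade$period == "post"],
                              cascade$n_articles[cascade$period == "post"], level))

  two_by_two <- function(flag) {
    # rows = pre/post, cols = outcome yes/no
    rbind(pre = c(sum(flag & !table$post), sum(!flag & !table$post)),
          post = c(sum(flag & table$post), sum(!flag & table$post)))
  }
  das_flag <- table$statement == "data_available"
  chi2_das <- pearson_chi2_2x2(two_by_two(das_flag))
  chi2_reusable <- pearson_chi2_2x2(two_by_two(table$reusable))

  its_block <- function(outcome) {
    design <- build_design(table, outcome)
    fit <- fit_its_logistic(design)
    list(fit = fit,
         effects = estimate_effects(fit, level),
         decomposition = tryCatch(decompose_trend(fit, level),
                                  error = function(e) {
                                    warning(conditionMessage(e), call. = FALSE)
                                    NULL
                                  }))
  }
  das_its <- its_block("das")
  reusable_its <- if (include_reusability)
    tryCatch(its_block("reusable"), error = function(e) {
      warning("reusability ITS not fitted: ", conditionMessage(e), call. = FALSE)
      NULL
    }) else NULL

  structure(list(n_articles = nrow(table),
                 policy_date = attr(table, "policy_date"),
                 level = level,
                 cascade = cascade,
                 das_ci = das_ci,
                 chi2_das = chi2_das,
                 chi2_reusable = chi2_reusable,
                 binned_das = bin_time_series(table, bin_width, "das"),
                 binned_reusable = bin_time_series(table, bin_width, "reusable"),
                 its_fit = das_its$fit,
                 effects = das_its$effects,
                 decomposition = das_its$decomposition,
                 reusability_its = reusable_its),
            class = "study1_report")
}

#' @export
print.study1_report <- function(x, ...) {
  cat(sprintf("Open-data policy evaluation: %d articles, policy %s\n\n",
              x$n_articles, format(x$policy_date)))
  cat("Data-available statements:\n  pre:  "); print(x$das_ci$pre)
  cat("  post: "); print(x$das_ci$post)
  cat("DAS 2x2: "); print(x$chi2_das)
  cat("Reusability 2x2: "); print(x$chi2_reusable)
  cat("\n"); print(x$its_fit)
  cat("\nEffects (risk-ratio scale):\n")
  print(as.data.frame(lapply(x$effects, function(c)
    if (is.numeric(c)) round(c, 3) else c)))
  if (!is.null(x$decomposition)) {
    cat("\nPost-policy trend decomposition:\n")
    print(x$decomposition)
  }
  invisible(x)
}

#' Run the analytic-reproducibility audit
#'
#' Classifies every target value at both audit stages, derives
#' article-level outcomes, and assembles the study-2 result bundle:
#' value-level tallies by value type, article outcome counts with a Wilson
#' continuity-corrected CI for the initial error rate and Sison-Glaz
#' simultaneous CIs for the three-way outcome split (reproducible without
#' assistance / with assistance / not fully reproducible), and the issue
#' locus tally when an issue table is supplied.
#'
#' @param audit an audit table (data frame) or path to an audit CSV.
#' @param issues an issue table (data frame), path, or NULL.
#' @param level confidence level (default 0.95).
#' @return an object of class `study2_report`.
#' @export
run_study2 <- function(audit, issues = NULL, level = 0.95) {
  if (is.character(audit)) audit <- read_audit_table(audit)
  else audit <- validate_audit_table(audit)
  if (is.character(issues)) issues <- read_issue_table(issues)

  before <- classify_values(audit, "before_assistance")
  final <- classify_values(audit, "after_assistance")
  articles <- classify_articles(audit)

  three_way <- c(
    reproducible = sum(articles$outcome == "reproducible"),
    reproducible_with_assistance =
      sum(articles$outcome == "reproducible_with_assistance"),
    not_fully_reproducible =
      sum(articles$outcome %in% c("not_fully_reproducible",
                                  "not_fully_reproducible_despite_assistance")))
  outcome_ci <- sison_glaz_intervals(three_way, level)

  # articles with any blocking error before assistance
  blocking_before <- tapply(before$classification %in% .blocking,
                            before$article_id, any)
  n_initial_errors <- sum(blocking_before)
  initial_error_ci <- wilson_cc_interval(n_initial_errors, nrow(articles), level)

  final_tally <- tally_value_errors(final)
  n_major <- sum(final_tally$counts[, "major_numerical"])
  major_ci <- wilson_cc_interval(n_major, nrow(audit), level)

  structure(list(n_values = nrow(audit),
                 n_articles = nrow(articles),
                 level = level,
                 value_tally_before = tally_value_errors(before),
                 value_tally = final_tally,
                 article_outcomes = articles,
                 outcome_counts = three_way,
                 outcome_ci = outcome_ci,
                 n_initial_errors = n_initial_errors,
                 initial_error_ci = initial_error_ci,
                 major_error_ci = major_ci,
                 issue_tally = if (!is.null(issues)) tally_issue_loci(issues)),
            class = "study2_report")
}

#' @export
print.study2_report <- function(x, ...) {
  cat(sprintf("Reproducibility audit: %d target values in %d articles\n\n",
              x$n_values, x$n_articles))
  cat(sprintf("Initial errors in %d articles: ", x$n_initial_errors))
  print(x$initial_error_ci)
  cat("Article outcomes (reproducible / with assistance / not fully):\n")
  print(x$outcome_ci)
  cls <- colSums(x$value_tally$counts)
  cat(sprintf("\nFinal value errors: %d major (", cls[["major_numerical"]]))
  cat(sprintf("%d%%, CI [%d, %d]), %d minor, %d decision, %d insufficient\n",
              as_pct(x$major_error_ci$estimate), as_pct(x$major_error_ci$lower),
              as_pct(x$major_error_ci$upper), cls[["minor_numerical"]],
              cls[["decision_error"]], cls[["insufficient_information"]]))
  if (!is.null(x$issue_tally)) {
    cat("\nIssue loci:\n")
    print(x$issue_tally)
  }
  invisible(x)
}

# serialization ---------------------------------------------------------------

.to_plain <- function(x) {
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  if (inherits(x, "data.frame")) return(as.data.frame(unclass(x)))
  if (is.matrix(x)) {
    df <- as.data.frame(x)
    df <- cbind(row = rownames(x), df)
    rownames(df) <- NULL
    return(df)
  }
  if (is.list(x)) return(lapply(unclass(x), .to_plain))
  x
}

#' Write a study report to disk
#'
#' `"json"` writes a single lossless JSON document (numbers at full
#' precision; display rounding is a presentation concern only).
#' `"csv_bundle"` writes a directory with one CSV per tabular component
#' plus a JSON file for scalar fields.
#'
#' @param report a `study1_report` or `study2_report`.
#' @param path output file (json) or directory (csv_bundle).
#' @param format `"json"` or `"csv_bundle"`.
#' @export
write_report <- function(report, path, format = c("json", "csv_bundle")) {
  format <- match.arg(format)
  plain <- .to_plain(report)
  if (format == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    return(invisible(NULL))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  is_table <- vapply(plain, is.data.frame, logical(1))
  for (nm in names(plain)[is_table])
    utils::write.csv(plain[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(plain[!is_table], file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(NULL)
}
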