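# Article coding table: domain types, CSV schema, validation, and the
# descriptive study-1 summaries (reusability cascade, time binning).

statement_levels <- c("data_available", "data_not_available", "no_statement")
route_levels     <- c("personal_website", "third_party_repository",
                      "journal_supplementary", "other", "none")
accessible_levels <- c("yes", "no", "some_files", "not_applicable")
complete_levels   <- c("all", "some", "unclear", "not_applicable")
understandable_levels <- c("yes", "partly", "no", "not_applicable")
licence_levels   <- c("cc_by", "cc_0", "other", "none")

coding_columns <- c("article_id", "submission_date", "statement",
                    "access_route", "accessible", "complete",
                    "understandable", "has_scripts", "licence")

#' Construct a validated article coding table
#'
#' A coding table holds one row per article with its submission date, the
#' category of its data-availability statement, the access route, the
#' accessibility / completeness / understandability codes, a script flag and
#' a licence code, plus the policy implementation date as an attribute.
#'
#' Invariants enforced: unique article ids; `access_route != "none"` exactly
#' when `statement == "data_available"`; the accessibility, completeness and
#' understandability codes are `"not_applicable"` exactly when the article
#' has no data-available statement.
#'
#' @param records a data frame with columns `article_id`, `submission_date`
#'   (Date), `statement`, `access_route`, `accessible`, `complete`,
#'   `understandable`, `has_scripts` (logical), `licence`.
#' @param policy_date the policy implementation date (Date or ISO string).
#' @return the validated table, classed `coding_table`.
#' @export
coding_table <- function(records, policy_date) {
  policy_date <- tryCatch(as.Date(policy_date), error = function(e) NA)
  if (is.na(policy_date)) stop_domain("policy_date is not a valid date")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(coding_columns, names(records))
  if (length(missing_cols))
    stop_domain("coding table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  records <- records[coding_columns]
  records$submission_date <- as.Date(records$submission_date)
  validate_coding_table(records)
  structure(records, policy_date = policy_date,
            class = c("coding_table", "data.frame"))
}

validate_coding_table <- function(records) {
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop_domain("row ", idx[1], ": ", what)
  }
  if (anyDuplicated(records$article_id))
    stop_domain("article_id values must be unique")
  bad_row(is.na(records$submission_date), "unparseable submission_date")
  check_enum <- function(col, levels) {
    bad_row(!(records[[col]] %in% levels),
            sprintf("invalid %s (must be one of %s)", col,
                    paste(levels, collapse = ", ")))
  }
  check_enum("statement", statement_levels)
  check_enum("access_route", route_levels)
  check_enum("accessible", accessible_levels)
  check_enum("complete", complete_levels)
  check_enum("understandable", understandable_levels)
  check_enum("licence", licence_levels)
  bad_row(is.na(records$has_scripts), "has_scripts must be true/false")
  das <- records$statement == "data_available"
  bad_row(das != (records$access_route != "none"),
          "access_route must be 'none' exactly when there is no data-available statement")
  for (col in c("accessible", "complete", "understandable")) {
    bad_row((!das) != (records[[col]] == "not_applicable"),
            sprintf("%s must be 'not_applicable' exactly when there is no data-available statement", col))
  }
  invisible(records)
}

#' Read an article coding table from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with lower-snake-case headers,
#' ISO-8601 dates, `true`/`false` booleans, and the empty string standing
#' for `not_applicable` in the reusability code columns.
#'
#' @param path path to the CSV file.
#' @param policy_date the policy implementation date.
#' @return a [coding_table].
#' @export
read_coding_table <- function(path, policy_date) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(coding_columns, names(raw))
  if (length(missing_cols))
    stop_domain("coding table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  for (col in c("accessible", "complete", "understandable"))
    raw[[col]][raw[[col]] == ""] <- "not_applicable"
  raw$has_scripts <- c("true" = TRUE, "false" = FALSE)[raw$has_scripts]
  suppressWarnings(raw$submission_date <- as.Date(raw$submission_date,
                                                  format = "%Y-%m-%d"))
  coding_table(raw, policy_date)
}

#' Write an article coding table to CSV
#'
#' Inverse of [read_coding_table()]: `read_coding_table(write_coding_table(t))`
#' reproduces `t` exactly, with ISO dates preserved byte-for-byte.
#'
#' @param table a [coding_table].
#' @param path output path.
#' @export
write_coding_table <- function(table, path) {
  out <- as.data.frame(table)[coding_columns]
  out$submission_date <- format(out$submission_date, "%Y-%m-%d")
  for (col in c("accessible", "complete", "understandable"))
    out[[col]][out[[col]] == "not_applicable"] <- ""
  out$has_scripts <- ifelse(out$has_scripts, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Derive policy period, day offsets and in-principle reusability
#'
#' Adds three derived columns to a coding table: `post` (the policy applies
#' to articles submitted on or after the policy date), `days_from_policy`
#' (signed integer days, negative pre-policy), and `reusable` (the
#' in-principle reusability composite: accessible data files that are
#' complete and understandable).
#'
#' @param table a [coding_table].
#' @return the table with columns `post`, `days_from_policy`, `reusable`.
#' @export
derive_period_and_reusability <- function(table) {
  policy_date <- attr(table, "policy_date")
  if (is.null(policy_date)) stop_domain("policy_date not set on table")
  table$days_from_policy <-
    as.integer(table$submission_date - policy_date)
  table$post <- table$days_from_policy >= 0L
  table$reusable <- table$statement == "data_available" &
    table$accessible == "yes" &
    table$complete == "all" &
    table$understandable == "yes"
  table
}

has_derived_columns <- function(table) {
  all(c("post", "days_from_policy", "reusable") %in% names(table))
}

#' Summarize the in-principle reusability cascade by policy period
#'
#' Counts, per period, the articles at each stage of the reusability
#' cascade: all articles, articles with a data-available statement (DAS),
#' articles whose data files were accessible, articles whose data were in
#' addition complete and understandable, and the in-principle reusable
#' composite. Counts are monotone non-increasing along the cascade.
#'
#' @param table a [coding_table] (derived columns are added if absent).
#' @return a `cascade_summary`: a data frame with one row per period and
#'   count plus proportion columns.
#' @export
summarize_cascade <- function(table) {
  if (!has_derived_columns(table)) table <- derive_period_and_reusability(table)
  one_period <- function(sub, period) {
    das <- sub$statement == "data_available"
    acc <- das & sub$accessible == "yes"
    cu  <- das & sub$complete == "all" & sub$understandable == "yes"
    data.frame(
      period = period,
      n_articles = nrow(sub),
      n_das = sum(das),
      n_accessible = sum(acc),
      n_complete_and_understandable = sum(cu),
      n_reusable = sum(acc & cu),
      prop_das = if (nrow(sub)) sum(das) / nrow(sub) else NA_real_,
      prop_reusable_of_das = if (sum(das)) sum(acc & cu) / sum(das) else NA_real_,
      prop_reusable = if (nrow(sub)) sum(acc & cu) / nrow(sub) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- rbind(one_period(table[!table$post, , drop = FALSE], "pre"),
               one_period(table[table$post, , drop = FALSE], "post"))
  class(out) <- c("cascade_summary", "data.frame")
  out
}

#' Bin a binary article outcome into fixed-width time bins
#'
#' Bins are half-open `[left, right)` intervals of `bin_width` days anchored
#' at the policy date (day 0), extending symmetrically; an article submitted
#' exactly on the policy date falls in the first post-policy bin. Only
#' non-empty bins are returned.
#'
#' @param table a [coding_table] (derived columns are added if absent).
#' @param bin_width bin width in days (default 50).
#' @param outcome `"das"` or `"reusable"`.
#' @return a data frame with columns `midpoint` (days from policy at the bin
#'   centre), `n` (articles in the bin), `proportion` (mean outcome).
#' @export
bin_time_series <- function(table, bin_width = 50, outcome = c("das", "reusable")) {
  outcome <- match.arg(outcome)
  if (bin_width <= 0) stop_domain("bin_width must be positive")
  if (!has_derived_columns(table)) table <- derive_period_and_reusability(table)
  if (nrow(table) == 0L)
    return(data.frame(midpoint = numeric(0), n = integer(0),
                      proportion = numeric(0)))
  y <- if (outcome == "das") table$statement == "data_available" else table$reusable
  idx <- floor(table$days_from_policy / bin_width)
  agg <- vapply(sort(unique(idx)), function(i) {
    in_bin <- idx == i
    c(i, sum(in_bin), mean(y[in_bin]))
  }, numeric(3))
  data.frame(midpoint = (agg[1, ] + 0.5) * bin_width,
             n = as.integer(agg[2, ]),
             proportion = agg[3, ])
}
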