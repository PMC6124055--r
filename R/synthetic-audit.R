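# Seeded audit fixtures with ground-truth error labels, and a deterministic
# fixture reproducing the audit's marginal counts exactly.

#' Parameters for a synthetic audit fixture
#'
#' @param n_articles number of audited articles.
#' @param values_per_article target values per article.
#' @param injection_rates named fractions of values receiving each injected
#'   error class (`minor`, `major`, `decision`, `insufficient`); the
#'   remainder are exact matches. Must sum to at most 1.
#' @param assistance_resolution_rate probability that author assistance
#'   resolves a given blocking error to an exact match.
#' @param value_type_mix named sampling probabilities over the nine audit
#'   value types.
#' @param seed integer root seed.
#' @return an `audit_fixture_params` list.
#' @export
audit_fixture_params <- function(n_articles = 35,
                                 values_per_article = 38,
                                 injection_rates = c(minor = 0.11,
                                                     major = 0.05,
                                                     decision = 0,
                                                     insufficient = 0.002),
                                 assistance_resolution_rate = 0.5,
                                 value_type_mix = c(count_proportion = 0.10,
                                                    confidence_interval = 0.05,
                                                    mean_median = 0.20,
                                                    degrees_of_freedom = 0.10,
                                                    effect_size = 0.10,
                                                    test_statistic = 0.15,
                                                    p_value = 0.15,
                                                    sd_se = 0.10,
                                                    misc = 0.05),
                                 seed = 1) {
  stopifnot(n_articles >= 1, values_per_article >= 1,
            all(injection_rates >= 0), sum(injection_rates) <= 1,
            all(c("minor", "major", "decision", "insufficient") %in%
                  names(injection_rates)),
            assistance_resolution_rate >= 0, assistance_resolution_rate <= 1,
            all(value_type_levels %in% names(value_type_mix)))
  structure(list(n_articles = as.integer(n_articles),
                 values_per_article = as.integer(values_per_article),
                 injection_rates = injection_rates,
                 assistance_resolution_rate = assistance_resolution_rate,
                 value_type_mix = value_type_mix[value_type_levels],
                 seed = as.integer(seed)),
            class = "audit_fixture_params")
}

# reported/obtained pairs realising each label unambiguously after
# printed-precision rounding (reported values carry two decimals; p-values
# stay on one side of the 0.05 boundary unless a decision error is wanted)
.realise_label <- function(label, type, reported) {
  if (label == "decision")
    return(list(reported = "0.04", obtained = "0.06"))
  rep_str <- sprintf("%.2f", reported)
  obtained <- switch(label,
                     match = rep_str,
                     minor = sprintf("%.4f", reported * 1.03),
                     major = sprintf("%.4f", reported * 1.25),
                     insufficient = "insufficient")
  list(reported = rep_str, obtained = obtained)
}

.blocking_labels <- c("major", "decision", "insufficient")

#' Generate a seeded audit fixture with known error labels
#'
#' Every target value receives a true classification label drawn from the
#' injection rates; reported/obtained pairs are constructed to realise that
#' label exactly (minor: obtained = reported x 1.03; major: x 1.25;
#' decision: a p-value moved across 0.05; insufficient: flagged). Articles
#' containing any blocking error request author assistance, which resolves
#' each blocking error to an exact match with the configured probability.
#' An issue table with one issue per blocking error accompanies the audit
#' table. Ground-truth labels for both stages and rule-derived article
#' outcomes are returned for classifier-recovery checks.
#'
#' @param params an [audit_fixture_params].
#' @return a list with `audit` (audit table), `issues` (issue table) and
#'   `ground_truth` (list of `values` and `articles` data frames).
#' @export
generate_audit_fixture <- function(params = audit_fixture_params()) {
  stopifnot(inherits(params, "audit_fixture_params"))
  n_art <- params$n_articles
  vpa <- params$values_per_article
  rates <- params$injection_rates
  labels_all <- c("match", "minor", "major", "decision", "insufficient")
  probs <- c(1 - sum(rates), rates[c("minor", "major", "decision", "insufficient")])

  set.seed(sub_seed(params$seed, "injections"))
  art_id <- rep(sprintf("syn%03d", seq_len(n_art)), each = vpa)
  label_before <- sample(labels_all, n_art * vpa, replace = TRUE, prob = probs)
  type <- sample(value_type_levels, n_art * vpa, replace = TRUE,
                 prob = params$value_type_mix)
  type[label_before == "decision"] <- "p_value"
  # p-value minors need reported >= 0.20 so the x1.03 perturbation survives
  # rounding to two printed decimals with 0 < PE < 10
  p_min <- ifelse(label_before == "minor", 0.20, 0.10)
  base <- ifelse(type == "p_value",
                 round(stats::runif(n_art * vpa, p_min, 0.60), 2),
                 round(stats::runif(n_art * vpa, 5, 80), 2))

  pairs <- Map(.realise_label, label_before, type, base)
  reported <- vapply(pairs, `[[`, character(1), "reported")
  obtained_before <- vapply(pairs, `[[`, character(1), "obtained")

  set.seed(sub_seed(params$seed, "assistance"))
  blocking <- label_before %in% .blocking_labels
  assist_art <- unique(art_id[blocking])
  assistance <- art_id %in% assist_art
  resolved <- blocking & assistance &
    stats::runif(n_art * vpa) < params$assistance_resolution_rate
  label_after <- ifelse(resolved, "match", label_before)
  obtained_after <- ifelse(!assistance, "unattempted",
                           ifelse(resolved, reported, obtained_before))

  audit <- data.frame(article_id = art_id,
                      value_type = type,
                      reported_raw = reported,
                      obtained_before = obtained_before,
                      obtained_after = ifelse(assistance, obtained_after,
                                              "unattempted"),
                      assistance_requested = assistance,
                      stringsAsFactors = FALSE)

  # one discrete issue per blocking error, with a sampled causal locus
  set.seed(sub_seed(params$seed, "issues"))
  iss_idx <- which(blocking)
  issues <- data.frame(
    article_id = art_id[iss_idx],
    locus = sample(locus_levels, length(iss_idx), replace = TRUE,
                   prob = c(0.09, 0.53, 0.05, 0.18, 0.15)),
    resolved_by_authors = resolved[iss_idx],
    stringsAsFactors = FALSE)

  # rule-derived ground-truth article outcomes (independent of the classifier)
  per_art <- split(seq_len(n_art * vpa), art_id)
  outcomes <- vapply(sprintf("syn%03d", seq_len(n_art)), function(id) {
    idx <- per_art[[id]]
    clean_before <- !any(label_before[idx] %in% .blocking_labels)
    clean_after <- !any(label_after[idx] %in% .blocking_labels)
    if (clean_before) "reproducible"
    else if (clean_after) "reproducible_with_assistance"
    else "not_fully_reproducible_despite_assistance"
  }, character(1))

  list(audit = audit,
       issues = issues,
       ground_truth = list(
         values = data.frame(article_id = art_id,
                             label_before = label_before,
                             label_after = label_after,
                             stringsAsFactors = FALSE),
         articles = data.frame(article_id = names(outcomes),
                               outcome = unname(outcomes),
                               stringsAsFactors = FALSE)))
}

#' Deterministic audit fixture reproducing the audit's margins
#'
#' Constructs an audit and issue table for 35 articles and 1324 target
#' values whose final-stage margins are exact: 64 major numerical errors
#' (with the published value-type breakdown: 17 sd/se, 17 p-values, 10 test
#' statistics, 8 effect sizes, 4 means/medians, 4 degrees of freedom, 1
#' count, 1 confidence interval, 2 miscellaneous), 146 minor numerical
#' errors, 2 insufficient-information errors and no decision errors, with
#' article outcomes 11 reproducible / 11 reproducible with assistance / 13
#' not fully reproducible despite assistance, and 57 discrete issues (30
#' under-specified analyses, 10 data-file issues, 5 typographical, 3
#' original-analysis issues, 9 unidentified) of which 33 were resolved.
#'
#' @return a list with `audit`, `issues` and `ground_truth` as in
#'   [generate_audit_fixture()].
#' @export
audit_fixture_paper_margins <- function() {
  major_types <- c(rep("sd_se", 17), rep("p_value", 17),
                   rep("test_statistic", 10), rep("effect_size", 8),
                   rep("mean_median", 4), rep("degrees_of_freedom", 4),
                   "count_proportion", "confidence_interval", rep("misc", 2))
  majors_per_x <- c(rep(5L, 12), 4L)
  # 29 articles carry 38 values and 6 carry 37, totalling 1324
  vpa <- c(rep(38L, 5), rep(37L, 6), rep(38L, 24))
  minors_per_article <- c(rep(5L, 6), rep(4L, 29))  # 146 in total

  rows <- list()
  gt_vals <- list()
  add_row <- function(id, type, rep_raw, before, after, assist, lb, la) {
    rows[[length(rows) + 1]] <<- data.frame(
      article_id = id, value_type = type, reported_raw = rep_raw,
      obtained_before = before, obtained_after = after,
      assistance_requested = assist, stringsAsFactors = FALSE)
    gt_vals[[length(gt_vals) + 1]] <<- data.frame(
      article_id = id, label_before = lb, label_after = la,
      stringsAsFactors = FALSE)
  }

  ids <- c(sprintf("rep%02d", 1:11), sprintf("ast%02d", 1:11),
           sprintf("nfr%02d", 1:13))
  group <- c(rep("r", 11), rep("w", 11), rep("x", 13))
  major_cursor <- 0L
  for (k in seq_along(ids)) {
    id <- ids[k]; g <- group[k]
    assist <- g != "r"
    total <- vpa[k]
    used <- 0L
    if (g == "x") {
      nm <- majors_per_x[k - 22L]
      for (j in seq_len(nm)) {
        major_cursor <- major_cursor + 1L
        ty <- major_types[major_cursor]
        if (ty == "p_value")
          add_row(id, ty, "0.30", "0.45", "0.45", TRUE, "major", "major")
        else
          add_row(id, ty, "10.00", "12.50", "12.50", TRUE, "major", "major")
        used <- used + 1L
      }
      if (k - 22L <= 2L) {   # the two remaining insufficient-information errors
        add_row(id, "mean_median", "5.00", "insufficient", "insufficient",
                TRUE, "insufficient", "insufficient")
        used <- used + 1L
      }
    }
    if (g == "w") {
      for (j in 1:2) {   # majors before assistance, resolved to match after
        add_row(id, "test_statistic", "10.00", "12.50", "10.00",
                TRUE, "major", "match")
        used <- used + 1L
      }
    }
    after_val <- function(x) if (assist) x else "unattempted"
    for (j in seq_len(minors_per_article[k])) {
      add_row(id, "mean_median", "20.00", "20.60", after_val("20.60"),
              assist, "minor", "minor")
      used <- used + 1L
    }
    for (j in seq_len(total - used)) {
      add_row(id, "count_proportion", "12.34", "12.34", after_val("12.34"),
              assist, "match", "match")
    }
  }
  audit <- do.call(rbind, rows)
  gt_values <- do.call(rbind, gt_vals)

  # 57 discrete issues across the 24 assisted articles, 33 resolved
  assisted <- ids[group != "r"]
  loci <- c(rep("analysis_underspecified", 30), rep("data_file_issue", 10),
            rep("typographical", 5), rep("original_analysis_issue", 3),
            rep("unidentified", 9))
  resolved <- c(rep(TRUE, 24), rep(FALSE, 6),   # analysis_underspecified
                rep(TRUE, 8), rep(FALSE, 2),    # data_file_issue
                rep(FALSE, 5),                  # typographical
                TRUE, rep(FALSE, 2),            # original_analysis_issue
                rep(FALSE, 9))                  # unidentified
  issues <- data.frame(article_id = rep(assisted, length.out = 57),
                       locus = loci,
                       resolved_by_authors = resolved,
                       stringsAsFactors = FALSE)

  gt_articles <- data.frame(
    article_id = ids,
    outcome = c(rep("reproducible", 11),
                rep("reproducible_with_assistance", 11),
                rep("not_fully_reproducible_despite_assistance", 13)),
    stringsAsFactors = FALSE)

  list(audit = audit, issues = issues,
       ground_truth = list(values = gt_values, articles = gt_articles))
}
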