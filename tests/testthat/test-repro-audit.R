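test_that("percentage error follows the printed-precision formula", {
  expect_equal(percentage_error(2.0, 2.3), 15.0)
  expect_equal(percentage_error(5.00, 5.001, decimals = 2), 0)
  # absolute value in the denominator for negative reported values
  expect_equal(percentage_error(-0.50, -0.45), 10.0)
  expect_equal(percentage_error(3, 3), 0)
  # flagged zero-denominator cases
  expect_equal(percentage_error(0, 0.0004, decimals = 2), 0)
  expect_equal(percentage_error(0, 0.4, decimals = 2), Inf)

  # scale invariance (pre-rounding): PE(k r, k o) == PE(r, o) for k > 0
  set.seed(31)
  for (i in 1:200) {
    r <- runif(1, -50, 50); o <- runif(1, -50, 50); k <- runif(1, 0.01, 100)
    if (r == 0) next
    expect_equal(percentage_error(k * r, k * o), percentage_error(r, o),
                 tolerance = 1e-9)
  }
})

test_that("reported-value parsing preserves printed precision and inequalities", {
  p <- parse_reported(c("4.20", "-0.50", "<0.001", ">0.9", "12"))
  expect_equal(p$value, c(4.20, -0.50, 0.001, 0.9, 12))
  expect_equal(p$decimals, c(2L, 2L, 3L, 1L, 0L))
  expect_equal(p$inequality, c("", "", "<", ">", ""))
  expect_error(parse_reported("n/a"), "unparseable")
})

test_that("value classification applies the four-way taxonomy", {
  cls <- function(row, stage = "before_assistance")
    classify_value(row, stage)$classification

  expect_equal(cls(audit_row("mean_median", "4.20", "4.21")), "minor_numerical")
  expect_equal(cls(audit_row("test_statistic", "12.0", "13.5")), "major_numerical")
  # the boundary PE = 10 is a major error
  expect_equal(cls(audit_row("mean_median", "2.0", "2.2")), "major_numerical")
  expect_equal(cls(audit_row("mean_median", "2.00", "2.00")), "match")
  expect_equal(cls(audit_row("mean_median", "5.00", "insufficient")),
               "insufficient_information")

  # p-values: decision errors take precedence over numerical errors
  expect_equal(cls(audit_row("p_value", "0.04", "0.06")), "decision_error")
  expect_equal(cls(audit_row("p_value", "0.30", "0.45")), "major_numerical")
  # p = 0.05 sides: <= 0.05 vs > 0.05; boundary stays on the null side
  expect_equal(cls(audit_row("p_value", "0.050", "0.047")), "minor_numerical")
  expect_equal(cls(audit_row("p_value", "0.05", "0.06")), "decision_error")
  # a printed-precision match never becomes a decision error
  expect_equal(cls(audit_row("p_value", "0.05", "0.0504")), "match")

  # inequality-form p-values: match when satisfied, decision rule otherwise
  expect_equal(cls(audit_row("p_value", "<0.001", "0.0004")), "match")
  expect_equal(cls(audit_row("p_value", "<0.001", "0.2")), "decision_error")
  expect_equal(cls(audit_row("p_value", "<0.001", "0.01")), "major_numerical")
  r <- classify_value(audit_row("p_value", "<0.001", "0.01"), "before_assistance")
  expect_true(is.na(r$pe))  # inequality forms contribute no numeric PE

  # after-assistance stage reads the post-assistance value
  row <- audit_row("mean_median", "10.00", "12.50", "10.00", assistance = TRUE)
  expect_equal(cls(row), "major_numerical")
  expect_equal(cls(row, "after_assistance"), "match")
})

test_that("article classification implements the outcome rule", {
  match_row <- function(id, assist = FALSE)
    within(audit_row("mean_median", "2.00", "2.00",
                     if (assist) "2.00" else "unattempted", assist),
           article_id <- id)
  minor_row <- function(id, assist = FALSE)
    within(audit_row("mean_median", "20.00", "20.60",
                     if (assist) "20.60" else "unattempted", assist),
           article_id <- id)
  resolved_major <- function(id)
    within(audit_row("sd_se", "10.00", "12.50", "10.00", TRUE),
           article_id <- id)
  open_major <- function(id, assist = TRUE)
    within(audit_row("sd_se", "10.00", "12.50",
                     if (assist) "12.50" else "unattempted", assist),
           article_id <- id)

  expect_equal(classify_article(rbind(match_row("a"), match_row("a")))$outcome,
               "reproducible")
  # only minor errors still count as reproducible
  expect_equal(classify_article(rbind(match_row("a"), minor_row("a")))$outcome,
               "reproducible")
  expect_equal(classify_article(rbind(resolved_major("b"), match_row("b", TRUE)))$outcome,
               "reproducible_with_assistance")
  expect_equal(classify_article(rbind(open_major("c"), resolved_major("c")))$outcome,
               "not_fully_reproducible_despite_assistance")
  expect_equal(classify_article(open_major("d", assist = FALSE))$outcome,
               "not_fully_reproducible")
  expect_error(classify_article(match_row("e")[0, ]), "no records")

  # monotonicity: adding a major-error record never improves the outcome
  rank <- c(reproducible = 1, reproducible_with_assistance = 2,
            not_fully_reproducible = 3,
            not_fully_reproducible_despite_assistance = 3)
  bases <- list(rbind(match_row("m")),
                rbind(resolved_major("m"), match_row("m", TRUE)),
                rbind(open_major("m"), minor_row("m", TRUE)))
  for (base in bases) {
    before <- classify_article(base)$outcome
    after <- classify_article(rbind(base, open_major("m")))$outcome
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("value and issue tallies conserve their margins", {
  fx <- generate_audit_fixture(audit_fixture_params(n_articles = 12, seed = 4))
  final <- classify_values(fx$audit, "after_assistance")
  tal <- tally_value_errors(final)
  expect_equal(sum(tal$counts), nrow(fx$audit))
  expect_equal(tal$n, nrow(fx$audit))
  # recount oracle per margin
  for (cl in colnames(tal$counts))
    expect_equal(sum(tal$counts[, cl]), sum(final$classification == cl))
  for (ty in rownames(tal$counts))
    expect_equal(unname(rowSums(tal$counts)[ty]), sum(final$value_type == ty))
  if (sum(tal$counts[, "major_numerical"]) > 0)
    expect_equal(sum(tal$major_share), 1)
  # empty input -> all-zero table
  expect_equal(sum(tally_value_errors(final[0, ])$counts), 0)

  it <- tally_issue_loci(fx$issues)
  expect_equal(sum(it$counts), nrow(fx$issues))
  all_resolved <- fx$issues
  all_resolved$resolved_by_authors <- TRUE
  it2 <- tally_issue_loci(all_resolved)
  expect_true(all(it2$resolution_rate[rowSums(it2$counts) > 0] == 1))
})

test_that("classifier recovers injected labels perfectly on seeded fixtures", {
  for (seed in c(2, 19)) {
    fx <- generate_audit_fixture(audit_fixture_params(n_articles = 20,
                                                      values_per_article = 25,
                                                      seed = seed))
    before <- classify_values(fx$audit, "before_assistance")
    final <- classify_values(fx$audit, "after_assistance")
    expect_identical(before$classification,
                     unname(label_to_class[fx$ground_truth$values$label_before]))
    expect_identical(final$classification,
                     unname(label_to_class[fx$ground_truth$values$label_after]))
    arts <- classify_articles(fx$audit)
    gt <- fx$ground_truth$articles
    expect_identical(arts$outcome, gt$outcome[match(arts$article_id,
                                                    gt$article_id)])
  }
  # no injections -> everything reproducible
  fx0 <- generate_audit_fixture(audit_fixture_params(
    n_articles = 8, injection_rates = c(minor = 0, major = 0, decision = 0,
                                        insufficient = 0), seed = 3))
  expect_true(all(classify_articles(fx0$audit)$outcome == "reproducible"))
})

test_that("audit tables roundtrip through CSV with validation", {
  fx <- generate_audit_fixture(audit_fixture_params(n_articles = 6, seed = 10))
  ap <- withr::local_tempfile(fileext = ".csv")
  ip <- withr::local_tempfile(fileext = ".csv")
  write_audit_table(fx$audit, ap)
  write_issue_table(fx$issues, ip)
  expect_equal(read_audit_table(ap), fx$audit)
  expect_equal(read_issue_table(ip), fx$issues)

  clean <- generate_audit_fixture(audit_fixture_params(
    n_articles = 3, injection_rates = c(minor = 0, major = 0, decision = 0,
                                        insufficient = 0), seed = 10))
  bad <- clean$audit                      # no article requested assistance
  bad$obtained_after[1] <- "1.23"
  expect_error(validate_audit_table(bad), "assistance")
})
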