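# shared fixtures and independent oracles used across test files

# a minimal valid coding table built in code
make_small_table <- function(policy_date = as.Date("2015-03-01")) {
  records <- data.frame(
    article_id = c("a1", "a2", "a3", "a4"),
    submission_date = policy_date + c(-10, -10, 5, 5),
    statement = c("no_statement", "data_available", "data_available",
                  "data_available"),
    access_route = c("none", "third_party_repository", "journal_supplementary",
                     "journal_supplementary"),
    accessible = c("not_applicable", "yes", "yes", "no"),
    complete = c("not_applicable", "all", "some", "unclear"),
    understandable = c("not_applicable", "yes", "partly", "no"),
    has_scripts = c(FALSE, TRUE, FALSE, FALSE),
    licence = c("none", "cc_by", "none", "none"),
    stringsAsFactors = FALSE)
  coding_table(records, policy_date)
}

# independent maximum-likelihood oracle: BFGS on the Bernoulli log-likelihood
# with analytic gradient, independent of the IRLS path in the package
brute_force_logistic <- function(design) {
  X <- cbind(1, design$time, design$post, design$interaction)
  y <- design$outcome
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    eta <- drop(X %*% b)
    -drop(t(X) %*% (y - plogis(eta)))
  }
  opt <- optim(rep(0, 4), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  opt$par
}

# fixed 12-row design used for the small-instance fit comparison
fixed_12row_design <- function() {
  data.frame(
    outcome = c(0, 0, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1),
    time = c(-5, -4, -3, -2, -1, -0.5, 0, 1, 2, 3, 4, 5),
    post = c(rep(0, 6), rep(1, 6)),
    interaction = c(rep(0, 6), 0, 1, 2, 3, 4, 5))
}

# record columns of a coding table with container attributes stripped,
# for roundtrip comparisons
plain_records <- function(tab) {
  cols <- c("article_id", "submission_date", "statement", "access_route",
            "accessible", "complete", "understandable", "has_scripts",
            "licence")
  d <- as.data.frame(tab)[cols]
  attributes(d) <- list(names = names(d), class = "data.frame",
                        row.names = seq_len(nrow(d)))
  d
}

# map generator labels to classifier categories
label_to_class <- c(match = "match",
                    minor = "minor_numerical",
                    major = "major_numerical",
                    decision = "decision_error",
                    insufficient = "insufficient_information")

# one audit row as a list, for classify_value unit tests
audit_row <- function(value_type, reported_raw, before, after = "unattempted",
                      assistance = FALSE) {
  data.frame(article_id = "t1", value_type = value_type,
             reported_raw = reported_raw, obtained_before = before,
             obtained_after = after, assistance_requested = assistance,
             stringsAsFactors = FALSE)
}
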