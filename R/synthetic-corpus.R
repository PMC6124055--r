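# Seeded synthetic article corpora with the segmented-logistic outcome
# trajectory and the conditional reusability cascade, plus a deterministic
# corpus reproducing the study's marginal counts.

#' Parameters for a synthetic article corpus
#'
#' The defaults emulate the evaluated corpus: 591 articles with submission
#' dates spanning 1915 days before to 523 days after a policy implemented
#' on 2015-03-01, a data-available-statement (DAS) outcome following the
#' segmented logistic trajectory with coefficients implying a pre-policy
#' trend RR of 1.04 per 50 days, a level-change RR of 1.53 and a slope
#' ratio of 1.14 from a baseline probability of 0.35 at the policy date,
#' and a conditional reusability cascade calibrated so that roughly 45% of
#' DAS articles are in-principle reusable.
#'
#' @param n_articles number of articles.
#' @param date_range integer days relative to the policy date,
#'   `c(min_day, max_day)` with `min_day < 0 < max_day`.
#' @param beta segmented-logistic coefficients `(b0, b1, b2, b3)`.
#' @param cascade_probs named probabilities `accessible` (given DAS),
#'   `complete` (given accessible) and `understandable` (given complete).
#' @param policy_date policy implementation date.
#' @param seed integer root seed feeding the named sub-streams.
#' @return a `corpus_params` list.
#' @export
corpus_params <- function(n_articles = 591,
                          date_range = c(-1915, 523),
                          beta = beta_for_rr_targets(),
                          cascade_probs = c(accessible = 0.97,
                                            complete = 0.70,
                                            understandable = 0.66),
                          policy_date = as.Date("2015-03-01"),
                          seed = 1) {
  stopifnot(n_articles >= 1, length(date_range) == 2,
            date_range[1] < 0, date_range[2] > 0,
            length(beta) == 4,
            all(cascade_probs >= 0), all(cascade_probs <= 1),
            all(c("accessible", "complete", "understandable") %in%
                  names(cascade_probs)))
  structure(list(n_articles = as.integer(n_articles),
                 date_range = as.integer(date_range),
                 beta = unname(beta),
                 cascade_probs = cascade_probs,
                 policy_date = as.Date(policy_date),
                 seed = as.integer(seed)),
            class = "corpus_params")
}

#' Generate a synthetic article corpus
#'
#' Submission dates are uniform over the date range; the DAS indicator is
#' Bernoulli with probability `expit(b0 + b1*t + b2*post + b3*t*post)`
#' (`t` in 50-day units); accessibility, completeness and understandability
#' are drawn conditionally down the cascade; access routes, script flags
#' and licences follow fixed mixtures typical of journal-hosted data. Each
#' named sub-stream draws from its own seed derived from the root seed, so
#' the same seed always yields a byte-identical table.
#'
#' @param params a [corpus_params].
#' @return a [coding_table]; the generating parameters are attached as
#'   attribute `ground_truth`.
#' @export
generate_corpus <- function(params = corpus_params()) {
  stopifnot(inherits(params, "corpus_params"))
  n <- params$n_articles
  b <- params$beta
  cp <- params$cascade_probs

  set.seed(sub_seed(params$seed, "dates"))
  days <- sample(seq.int(params$date_range[1], params$date_range[2]), n,
                 replace = TRUE)

  t50 <- days / 50
  post <- as.integer(days >= 0)
  p_das <- stats::plogis(b[1] + b[2] * t50 + b[3] * post + b[4] * t50 * post)
  set.seed(sub_seed(params$seed, "outcome"))
  das <- stats::rbinom(n, 1, p_das) == 1

  accessible <- complete <- understandable <- rep("not_applicable", n)
  set.seed(sub_seed(params$seed, "cascade"))
  for (i in which(das)) {
    acc_ok <- stats::runif(1) < cp[["accessible"]]
    accessible[i] <- if (acc_ok) "yes" else sample(c("no", "some_files"), 1)
    if (acc_ok) {
      comp_ok <- stats::runif(1) < cp[["complete"]]
      complete[i] <- if (comp_ok) "all" else sample(c("some", "unclear"), 1)
      if (comp_ok) {
        und_ok <- stats::runif(1) < cp[["understandable"]]
        understandable[i] <- if (und_ok) "yes" else sample(c("partly", "no"), 1)
      } else {
        understandable[i] <- sample(c("partly", "no"), 1)
      }
    } else {
      complete[i] <- "unclear"
      understandable[i] <- "no"
    }
  }

  set.seed(sub_seed(params$seed, "extras"))
  route <- rep("none", n)
  route[das] <- sample(c("journal_supplementary", "third_party_repository",
                         "personal_website", "other"),
                       sum(das), replace = TRUE,
                       prob = c(0.865, 0.115, 0.010, 0.010))
  has_scripts <- rep(FALSE, n)
  has_scripts[das] <- stats::runif(sum(das)) < 0.075
  licence <- rep("none", n)
  licence[das] <- sample(c("cc_by", "cc_0", "other", "none"),
                         sum(das), replace = TRUE,
                         prob = c(0.40, 0.05, 0.05, 0.50))

  records <- data.frame(
    article_id = sprintf("art%04d", seq_len(n)),
    submission_date = params$policy_date + days,
    statement = ifelse(das, "data_available", "no_statement"),
    access_route = route,
    accessible = accessible,
    complete = complete,
    understandable = understandable,
    has_scripts = has_scripts,
    licence = licence,
    stringsAsFactors = FALSE)
  out <- coding_table(records, params$policy_date)
  attr(out, "ground_truth") <- params
  out
}

#' Deterministic corpus reproducing the study's marginal counts
#'
#' Builds a coding table whose per-period cascade margins equal the
#' evaluated corpus exactly: 417 pre-policy articles of which 104 have a
#' data-available statement and 23 are in-principle reusable, and 174
#' post-policy articles of which 136 have a statement and 85 are reusable
#' (with 2 inaccessible datasets per period). Submission dates are evenly
#' spaced within each period and statement-bearing articles are evenly
#' interleaved, so the table also supports a well-conditioned ITS fit.
#'
#' @param policy_date policy implementation date.
#' @return a [coding_table].
#' @export
corpus_from_margins <- function(policy_date = as.Date("2015-03-01")) {
  build_period <- function(n, n_das, n_reusable, n_inaccessible, days, prefix) {
    das_idx <- unique(round(seq(1, n, length.out = n_das)))
    stopifnot(length(das_idx) == n_das)
    statement <- rep("no_statement", n)
    statement[das_idx] <- "data_available"
    accessible <- complete <- understandable <- rep("not_applicable", n)
    # first the reusable block, then complete-but-opaque fillers, then the
    # inaccessible tail
    reus <- das_idx[seq_len(n_reusable)]
    inacc <- das_idx[seq.int(n_das - n_inaccessible + 1, n_das)]
    rest <- setdiff(das_idx, c(reus, inacc))
    accessible[reus] <- "yes"; complete[reus] <- "all"; understandable[reus] <- "yes"
    accessible[rest] <- "yes"; complete[rest] <- "some"; understandable[rest] <- "partly"
    accessible[inacc] <- "no"; complete[inacc] <- "unclear"; understandable[inacc] <- "no"
    data.frame(
      article_id = sprintf("%s%04d", prefix, seq_len(n)),
      submission_date = policy_date + days,
      statement = statement,
      access_route = ifelse(statement == "data_available",
                            "journal_supplementary", "none"),
      accessible = accessible,
      complete = complete,
      understandable = understandable,
      has_scripts = FALSE,
      licence = ifelse(statement == "data_available", "cc_by", "none"),
      stringsAsFactors = FALSE)
  }
  pre <- build_period(417, 104, 23, 2, round(seq(-1915, -1, length.out = 417)), "pre")
  post <- build_period(174, 136, 85, 2, round(seq(0, 523, length.out = 174)), "post")
  coding_table(rbind(pre, post), policy_date)
}
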