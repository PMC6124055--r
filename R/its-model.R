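# Segmented logistic interrupted time-series model: design construction and
# maximum-likelihood fitting.

#' Build the ITS design matrix from a coding table
#'
#' Converts article-level data into the design of the segmented logistic
#' model `logit(p) = b0 + b1*time + b2*post + b3*time*post`, where `time` is
#' days since policy implementation in units of 50 days (negative
#' pre-policy) and `post` indicates submission on or after the policy date.
#' An article submitted exactly on the policy date has `time = 0, post = 1`.
#'
#' @param table a [coding_table] (derived columns are added if absent).
#' @param outcome `"das"` (data-available statement) or `"reusable"`
#'   (in-principle reusability).
#' @param time_unit days per unit of the time covariate (default 50).
#' @return a data frame with columns `outcome` (0/1), `time`, `post`,
#'   `interaction`.
#' @export
build_design <- function(table, outcome = c("das", "reusable"), time_unit = 50) {
  outcome <- match.arg(outcome)
  if (!has_derived_columns(table)) table <- derive_period_and_reusability(table)
  y <- if (outcome == "das") table$statement == "data_available" else table$reusable
  time <- table$days_from_policy / time_unit
  post <- as.integer(table$post)
  data.frame(outcome = as.integer(y), time = time, post = post,
             interaction = time * post)
}

#' Fit the segmented logistic ITS model
#'
#' Maximizes the Bernoulli log-likelihood of
#' `logit(p) = b0 + b1*time + b2*post + b3*time*post` by iteratively
#' reweighted least squares, with the coefficient covariance matrix taken as
#' the inverse observed information at the optimum.
#'
#' The fit requires at least one observation of each outcome class in each
#' period; quasi-complete separation (fitted probabilities collapsing to 0
#' or 1) is reported as an explicit error.
#'
#' @param rows a design data frame from [build_design()] (columns `outcome`,
#'   `time`, `post`, `interaction`).
#' @param epsilon IRLS convergence tolerance (default 1e-10).
#' @param maxit maximum IRLS iterations (default 100).
#' @return an object of class `its_fit`: list with `beta` (named length-4
#'   vector), `vcov` (4x4), `log_likelihood`, `n`, `converged`,
#'   `iterations`.
#' @export
fit_its_logistic <- function(rows, epsilon = 1e-10, maxit = 100) {
  required <- c("outcome", "time", "post", "interaction")
  if (!all(required %in% names(rows)))
    stop_domain("design must have columns ", paste(required, collapse = ", "))
  if (any(rows$interaction != rows$time * rows$post))
    stop_domain("interaction column must equal time * post")
  for (p in 0:1) {
    y <- rows$outcome[rows$post == p]
    if (length(unique(y)) < 2L)
      stop_domain("separation: the ", if (p) "post" else "pre",
                  "-policy period does not contain both outcome classes")
  }
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ time + post + interaction, family = stats::binomial(),
               data = rows,
               control = stats::glm.control(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (sep_warned && any(abs(beta) > 15))
    stop_domain("separation: fitted probabilities numerically 0 or 1")
  if (!fit$converged)
    stop_domain("IRLS did not converge in ", maxit,
                " iterations (deviance ", format(fit$deviance), ")")
  names(beta) <- c("b0", "b1_time", "b2_post", "b3_interaction")
  V <- summary(fit)$cov.unscaled
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(beta = beta,
                 vcov = V,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = nrow(rows),
                 converged = fit$converged,
                 iterations = fit$iter),
            class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Segmented logistic ITS fit (n = %d, logLik = %.3f, %s)\n",
              x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  se <- sqrt(diag(x$vcov))
  tab <- cbind(estimate = x$beta, se = se, `exp(est)` = exp(x$beta))
  print(round(tab, 4))
  invisible(x)
}
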