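# Effect estimates on the risk-ratio scale, the additive three-way trend
# decomposition, and model predictions, all with delta-method inference.

#' Zhang-Yu conversion of an odds ratio to a risk ratio
#'
#' `RR = OR / ((1 - P0) + P0 * OR)`, where `P0` is the outcome probability
#' in the reference (anchor) condition. When `OR` and `P0` come from a
#' logistic model, the result is exactly the ratio of the two model
#' probabilities.
#'
#' @param odds_ratio positive odds ratio.
#' @param p0 anchor probability in `[0, 1)`.
#' @return the risk ratio.
#' @export
zhang_yu_rr <- function(odds_ratio, p0) {
  if (any(odds_ratio <= 0)) stop_domain("odds_ratio must be positive")
  if (any(p0 < 0) || any(p0 >= 1)) stop_domain("p0 must be in [0, 1)")
  odds_ratio / ((1 - p0) + p0 * odds_ratio)
}

#' Square-root approximation of a risk ratio from an odds ratio
#'
#' VanderWeele's approximate one-to-one transformation `RR ~ sqrt(OR)`,
#' suitable for common outcomes where the rare-outcome approximation fails.
#'
#' @param odds_ratio positive odds ratio.
#' @return the approximate risk ratio.
#' @export
vanderweele_sqrt_rr <- function(odds_ratio) {
  if (any(odds_ratio <= 0)) stop_domain("odds_ratio must be positive")
  sqrt(odds_ratio)
}

# log risk ratio as a function of beta, for OR = exp(a'beta) anchored at
# P0 = expit(b'beta), and its analytic gradient
.log_rr <- function(beta, a, b) {
  or <- exp(sum(a * beta))
  p0 <- stats::plogis(sum(b * beta))
  sum(a * beta) - log((1 - p0) + p0 * or)
}

.log_rr_grad <- function(beta, a, b) {
  or <- exp(sum(a * beta))
  p0 <- stats::plogis(sum(b * beta))
  D <- (1 - p0) + p0 * or
  a - (p0 * (1 - p0) * (or - 1) * b + p0 * or * a) / D
}

# contrast definitions: a = OR contrast, b = anchor linear combination,
# w = Wald contrast for the p-value
.effect_defs <- function() {
  list(
    level_change = list(a = c(0, 0, 1, 0), b = c(1, 0, 0, 0), w = c(0, 0, 1, 0)),
    pre_trend    = list(a = c(0, 1, 0, 0), b = c(1, 0, 0, 0), w = c(0, 1, 0, 0)),
    post_trend   = list(a = c(0, 1, 0, 1), b = c(1, 0, 1, 0), w = c(0, 1, 0, 1))
  )
}

#' Policy and trend effects on the risk-ratio scale
#'
#' Transforms a fitted segmented logistic ITS model into four effect
#' estimates: the level change at policy implementation (`exp(b2)` anchored
#' at the pre-policy probability at the policy date), the pre-policy secular
#' trend per time unit (`exp(b1)`, same anchor), the post-policy trend
#' (`exp(b1 + b3)` anchored at the post-policy probability at the policy
#' date), and the slope ratio (post-trend RR divided by pre-trend RR).
#' Odds ratios are mapped to risk ratios by the Zhang-Yu conversion at the
#' stated anchors; confidence intervals are delta-method intervals on the
#' log-RR scale; p-values are two-sided Wald tests of the corresponding
#' coefficient (`b2`, `b1`, `b1 + b3`, and `b3` respectively).
#'
#' @param fit an [its_fit][fit_its_logistic].
#' @param level confidence level (default 0.95).
#' @param anchors optional named list overriding the anchor linear
#'   combinations (length-4 vectors `b` such that `P0 = expit(b'beta)`) for
#'   `level_change`, `pre_trend` and `post_trend`.
#' @return a data frame classed `effect_estimates` with one row per effect:
#'   `label`, `odds_ratio`, `anchor_probability`, `risk_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `sided`.
#' @export
estimate_effects <- function(fit, level = 0.95, anchors = NULL) {
  if (!inherits(fit, "its_fit")) stop_domain("fit must be an its_fit")
  if (!fit$converged) stop_domain("fit did not converge")
  beta <- unname(fit$beta)
  V <- fit$vcov
  z <- stats::qnorm(1 - (1 - level) / 2)
  defs <- .effect_defs()
  if (!is.null(anchors)) {
    for (nm in names(anchors)) defs[[nm]]$b <- anchors[[nm]]
  }

  one <- function(a, b, w) {
    lrr <- .log_rr(beta, a, b)
    g <- .log_rr_grad(beta, a, b)
    se <- sqrt(drop(t(g) %*% V %*% g))
    zw <- sum(w * beta) / sqrt(drop(t(w) %*% V %*% w))
    list(or = exp(sum(a * beta)), p0 = stats::plogis(sum(b * beta)),
         rr = exp(lrr), lo = exp(lrr - z * se), hi = exp(lrr + z * se),
         p = 2 * stats::pnorm(-abs(zw)))
  }
  res <- lapply(defs, function(d) one(d$a, d$b, d$w))

  # slope ratio: ratio of the converted trend RRs; Wald p-value on b3
  d_pre <- defs$pre_trend; d_post <- defs$post_trend
  lrr_sr <- .log_rr(beta, d_post$a, d_post$b) - .log_rr(beta, d_pre$a, d_pre$b)
  g_sr <- .log_rr_grad(beta, d_post$a, d_post$b) -
    .log_rr_grad(beta, d_pre$a, d_pre$b)
  se_sr <- sqrt(drop(t(g_sr) %*% V %*% g_sr))
  w3 <- c(0, 0, 0, 1)
  z_sr <- sum(w3 * beta) / sqrt(drop(t(w3) %*% V %*% w3))
  res$slope_ratio <- list(or = exp(beta[4]), p0 = NA_real_,
                          rr = exp(lrr_sr),
                          lo = exp(lrr_sr - z * se_sr),
                          hi = exp(lrr_sr + z * se_sr),
                          p = 2 * stats::pnorm(-abs(z_sr)))

  out <- data.frame(
    label = names(res),
    odds_ratio = vapply(res, `[[`, numeric(1), "or"),
    anchor_probability = vapply(res, `[[`, numeric(1), "p0"),
    risk_ratio = vapply(res, `[[`, numeric(1), "rr"),
    ci_lower = vapply(res, `[[`, numeric(1), "lo"),
    ci_upper = vapply(res, `[[`, numeric(1), "hi"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    sided = "two",
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

# decomposition share functions and analytic jacobian -------------------------

# shares of the joint one-unit post-policy risk ratio attributable to the
# baseline trend, the policy level change, and their interaction (additive
# excess-relative-risk attribution), with RRs from the sqrt(OR) map
.decomp_shares <- function(beta) {
  rt <- exp(beta[2] / 2)
  rp <- exp(beta[3] / 2)
  rj <- exp((beta[2] + beta[3] + beta[4]) / 2)
  d <- rj - 1
  c(baseline = (rt - 1) / d,
    policy = (rp - 1) / d,
    interaction = (rj - rt - rp + 1) / d)
}

.decomp_jacobian <- function(beta) {
  rt <- exp(beta[2] / 2)
  rp <- exp(beta[3] / 2)
  rj <- exp((beta[2] + beta[3] + beta[4]) / 2)
  d <- rj - 1
  drt <- rt / 2 * c(0, 1, 0, 0)
  drp <- rp / 2 * c(0, 0, 1, 0)
  drj <- rj / 2 * c(0, 1, 1, 1)
  jb <- drt / d - (rt - 1) * drj / d^2
  jp <- drp / d - (rp - 1) * drj / d^2
  rbind(baseline = jb, policy = jp, interaction = -jb - jp)
}

#' Three-way decomposition of the post-policy trend
#'
#' Attributes the joint risk ratio of one post-policy time unit -- i.e. the
#' combined exposure to one unit of elapsed time and to the policy -- to
#' three additive components on the excess-relative-risk scale: the baseline
#' secular trend alone, the policy alone, and their interaction (the
#' acceleration of the secular trend due to the policy; the relative excess
#' risk due to interaction, RERI). Odds ratios are mapped to risk ratios by
#' the square-root transformation; the three shares sum to 1 by
#' construction. Standard errors are delta-method through the full chain
#' from the coefficients to the shares; p-values are one-sided tests that
#' each share is zero; confidence intervals are on the natural scale.
#'
#' @param fit an [its_fit][fit_its_logistic].
#' @param level confidence level (default 0.95).
#' @return an object of class `trend_decomposition`: list with `rr_time`,
#'   `rr_policy`, `rr_joint` and a data frame `shares` (`component`,
#'   `share`, `se`, `ci_lower`, `ci_upper`, `p_one_sided`).
#' @export
decompose_trend <- function(fit, level = 0.95) {
  if (!inherits(fit, "its_fit")) stop_domain("fit must be an its_fit")
  if (!fit$converged) stop_domain("fit did not converge")
  beta <- unname(fit$beta)
  rr_joint <- exp((beta[2] + beta[3] + beta[4]) / 2)
  if (rr_joint <= 1)
    stop_domain("decomposition undefined: joint post-policy risk ratio <= 1")
  s <- .decomp_shares(beta)
  J <- .decomp_jacobian(beta)
  S <- J %*% fit$vcov %*% t(J)
  se <- sqrt(diag(S))
  z <- stats::qnorm(1 - (1 - level) / 2)
  shares <- data.frame(
    component = names(s),
    share = unname(s),
    se = unname(se),
    ci_lower = unname(s - z * se),
    ci_upper = unname(s + z * se),
    p_one_sided = unname(stats::pnorm(s / se, lower.tail = FALSE)),
    stringsAsFactors = FALSE)
  structure(list(rr_time = exp(beta[2] / 2),
                 rr_policy = exp(beta[3] / 2),
                 rr_joint = rr_joint,
                 level = level,
                 shares = shares),
            class = "trend_decomposition")
}

#' @export
print.trend_decomposition <- function(x, ...) {
  cat(sprintf("Joint one-unit post-policy RR %.3f = time %.3f * policy %.3f * interaction\n",
              x$rr_joint, x$rr_time, x$rr_policy))
  s <- x$shares
  # the two non-negative shares are truncated to [0,1] for display only
  disp_lo <- s$ci_lower; disp_hi <- s$ci_upper
  keep <- s$component %in% c("baseline", "policy")
  disp_lo[keep] <- pmax(0, disp_lo[keep]); disp_hi[keep] <- pmin(1, disp_hi[keep])
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %3d%% (CI [%d, %d], one-sided p %s)\n",
                s$component[i], as_pct(s$share[i]), as_pct(disp_lo[i]),
                as_pct(disp_hi[i]),
                if (s$p_one_sided[i] < 0.001) "< 0.001"
                else sprintf("= %.3f", s$p_one_sided[i])))
  }
  invisible(x)
}

#' Predicted outcome probability from an ITS fit
#'
#' Evaluates the model probability `expit(b0 + b1*time + b2*post +
#' b3*time*post)` with a delta-method confidence interval computed on the
#' logit scale and transformed, so bounds always lie within `[0, 1]`.
#'
#' @param fit an [its_fit][fit_its_logistic].
#' @param time time in model units (50-day units since policy by default).
#' @param post 0/1 period indicator (recycled against `time`).
#' @param level confidence level (default 0.95).
#' @return a data frame with columns `time`, `post`, `probability`,
#'   `ci_lower`, `ci_upper`.
#' @export
predict_probability <- function(fit, time, post, level = 0.95) {
  if (!inherits(fit, "its_fit")) stop_domain("fit must be an its_fit")
  if (!fit$converged) stop_domain("fit did not converge")
  k <- max(length(time), length(post))
  time <- rep_len(time, k); post <- rep_len(post, k)
  X <- cbind(1, time, post, time * post)
  lp <- drop(X %*% fit$beta)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = time, post = post,
             probability = stats::plogis(lp),
             ci_lower = stats::plogis(lp - z * se),
             ci_upper = stats::plogis(lp + z * se))
}

#' Coefficients reproducing target risk-ratio effects
#'
#' Inverts the Zhang-Yu conversion to find segmented-logistic coefficients
#' `(b0, b1, b2, b3)` whose implied pre-policy trend RR, level-change RR and
#' slope ratio (under the anchor conventions of [estimate_effects()]) equal
#' the supplied targets, given the baseline outcome probability at the
#' policy date.
#'
#' @param rr_trend pre-policy secular trend risk ratio per time unit.
#' @param rr_level level-change risk ratio at policy implementation.
#' @param rr_slope_ratio ratio of post- to pre-policy trend risk ratios.
#' @param baseline_prob model outcome probability immediately pre-policy.
#' @return a named length-4 coefficient vector.
#' @export
beta_for_rr_targets <- function(rr_trend = 1.04, rr_level = 1.53,
                                rr_slope_ratio = 1.14, baseline_prob = 0.35) {
  rr_to_or <- function(rr, p0) {
    if (rr * p0 >= 1)
      stop_domain("target RR ", rr, " unattainable from baseline probability ", p0)
    rr * (1 - p0) / (1 - rr * p0)
  }
  b0 <- stats::qlogis(baseline_prob)
  b1 <- log(rr_to_or(rr_trend, baseline_prob))
  b2 <- log(rr_to_or(rr_level, baseline_prob))
  p_post <- rr_level * baseline_prob  # Zhang-Yu identity: RR * P0 = P1
  b13 <- log(rr_to_or(rr_trend * rr_slope_ratio, p_post))
  c(b0 = b0, b1_time = b1, b2_post = b2, b3_interaction = b13 - b1)
}
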