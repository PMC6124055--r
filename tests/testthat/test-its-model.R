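test_that("design construction maps days to 50-day units with the boundary rule", {
  policy <- as.Date("2015-03-01")
  records <- as.data.frame(make_small_table())[rep(2, 3), ]
  records$article_id <- c("c1", "c2", "c3")
  records$submission_date <- policy + c(-100, 0, 523)
  d <- build_design(coding_table(records, policy), "das")
  expect_equal(d$time, c(-2, 0, 10.46))
  expect_equal(d$post, c(0L, 1L, 1L))
  expect_equal(d$interaction, c(0, 0, 10.46))
  expect_error(build_design(make_small_table(), "nope"))
})

test_that("ITS maximizer agrees with a brute-force likelihood oracle", {
  d <- fixed_12row_design()
  fit <- fit_its_logistic(d)
  oracle <- brute_force_logistic(d)
  expect_equal(unname(fit$beta), oracle, tolerance = 1e-6)
  expect_true(fit$converged)
  # vcov is symmetric positive definite
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))

  # a second, larger instance
  tab <- generate_corpus(corpus_params(n_articles = 250, seed = 5))
  d2 <- build_design(tab, "das")
  expect_equal(unname(fit_its_logistic(d2)$beta), brute_force_logistic(d2),
               tolerance = 1e-6)
})

test_that("degenerate designs raise explicit separation errors", {
  d <- fixed_12row_design()
  d$outcome[d$post == 1] <- 1  # post period has only successes
  expect_error(fit_its_logistic(d), "separation")
  d2 <- fixed_12row_design()
  d2$interaction[2] <- 99
  expect_error(fit_its_logistic(d2), "interaction")
})

test_that("null model recovery: no spurious effects under beta = 0", {
  nrep <- 100
  covered <- matrix(NA, nrep, 4)
  for (r in seq_len(nrep)) {
    tab <- generate_corpus(corpus_params(n_articles = 600, beta = rep(0, 4),
                                         seed = 5000 + r))
    fit <- fit_its_logistic(build_design(tab, "das"))
    se <- sqrt(diag(fit$vcov))
    covered[r, ] <- abs(fit$beta) <= qnorm(0.975) * se
  }
  # each coefficient's 95% Wald CI covers zero in at least 90% of replicates
  expect_true(all(colMeans(covered) >= 0.90))
})

test_that("Zhang-Yu conversion equals the logistic probability ratio exactly", {
  expect_equal(zhang_yu_rr(1, 0.3), 1)
  expect_equal(zhang_yu_rr(2, 0.5), 4 / 3)
  expect_equal(zhang_yu_rr(2, 1e-12), 2, tolerance = 1e-9)
  expect_error(zhang_yu_rr(2, 1), "p0")
  expect_error(zhang_yu_rr(-1, 0.5), "odds_ratio")

  # algebraic identity: zhang_yu_rr(exp(b2), expit(b0)) == expit(b0+b2)/expit(b0)
  set.seed(42)
  for (i in 1:10000) {
    b0 <- runif(1, -4, 4); b2 <- runif(1, -3, 3)
    expect_equal(zhang_yu_rr(exp(b2), plogis(b0)),
                 plogis(b0 + b2) / plogis(b0), tolerance = 1e-12)
  }
})

test_that("square-root OR transformation", {
  expect_equal(vanderweele_sqrt_rr(1), 1)
  expect_equal(vanderweele_sqrt_rr(4), 2)
  expect_equal(vanderweele_sqrt_rr(2.25), 1.5)
  expect_error(vanderweele_sqrt_rr(0), "odds_ratio")
})

test_that("effect estimates transform coefficients at the stated anchors", {
  fit <- structure(list(beta = c(0, 0, log(2), 0), vcov = diag(4) * 0.01,
                        log_likelihood = 0, n = 100, converged = TRUE,
                        iterations = 1), class = "its_fit")
  eff <- estimate_effects(fit)
  lc <- eff[eff$label == "level_change", ]
  expect_equal(lc$odds_ratio, 2)
  expect_equal(lc$anchor_probability, 0.5)
  expect_equal(lc$risk_ratio, 4 / 3)
  # RR lies between 1 and OR, CI contains RR
  expect_true(all(pmin(1, eff$odds_ratio) - 1e-12 <= eff$risk_ratio &
                    eff$risk_ratio <= pmax(1, eff$odds_ratio) + 1e-12))
  expect_true(all(eff$ci_lower <= eff$risk_ratio &
                    eff$risk_ratio <= eff$ci_upper))

  # rare-outcome limit: RR approaches OR as the anchor probability -> 0
  fit$beta <- c(-12, 0, log(2), 0)
  eff2 <- estimate_effects(fit)
  expect_equal(eff2$risk_ratio[eff2$label == "level_change"], 2,
               tolerance = 1e-4)
})

test_that("effect CIs and p-values are delta-method/Wald consistent", {
  tab <- generate_corpus(corpus_params(seed = 9))
  fit <- fit_its_logistic(build_design(tab, "das"))
  eff <- estimate_effects(fit)
  # identity-transform check: with the anchor pinned to probability ~0 the
  # log-RR collapses to the coefficient itself and its CI to the Wald CI
  eff0 <- estimate_effects(fit, anchors = list(
    level_change = c(-1e8 / fit$beta[1], 0, 0, 0)))
  lc <- eff0[eff0$label == "level_change", ]
  se2 <- sqrt(fit$vcov[3, 3])
  expect_equal(log(c(lc$ci_lower, lc$ci_upper)),
               fit$beta[3] + c(-1, 1) * qnorm(0.975) * se2, tolerance = 1e-6)
  expect_equal(lc$p_value, unname(2 * pnorm(-abs(fit$beta[3] / se2))),
               tolerance = 1e-12)
  # slope ratio is the ratio of the converted trend RRs
  expect_equal(eff$risk_ratio[eff$label == "slope_ratio"],
               eff$risk_ratio[eff$label == "post_trend"] /
                 eff$risk_ratio[eff$label == "pre_trend"], tolerance = 1e-12)
})

test_that("risk-ratio recovery and CI coverage on simulated corpora", {
  truth <- c(pre_trend = 1.04, level_change = 1.53, slope_ratio = 1.14)
  nrep <- 120
  est <- matrix(NA_real_, nrep, 3)
  cover <- matrix(NA, nrep, 3)
  for (r in seq_len(nrep)) {
    tab <- generate_corpus(corpus_params(n_articles = 5000, seed = 7000 + r))
    eff <- estimate_effects(fit_its_logistic(build_design(tab, "das")))
    i <- match(names(truth), eff$label)
    est[r, ] <- eff$risk_ratio[i]
    cover[r, ] <- truth >= eff$ci_lower[i] & truth <= eff$ci_upper[i]
  }
  expect_true(all(abs(apply(est, 2, median) - truth) / truth < 0.03))
  expect_true(all(colMeans(cover) >= 0.90 & colMeans(cover) <= 0.98))
})

test_that("trend decomposition: shares sum to one and match closed forms", {
  # additive case: rr_time = 1.1, rr_policy = 1.4, rr_joint = 1.5 gives
  # shares (0.2, 0.8, 0) -- zero excess risk from interaction
  b1 <- 2 * log(1.1); b2 <- 2 * log(1.4)
  b3 <- 2 * log(1.5) - b1 - b2
  fit <- structure(list(beta = c(0, b1, b2, b3), vcov = diag(4) * 1e-4,
                        log_likelihood = 0, n = 100, converged = TRUE,
                        iterations = 1), class = "its_fit")
  dec <- decompose_trend(fit)
  expect_equal(dec$shares$share, c(0.2, 0.8, 0), tolerance = 1e-12)
  expect_equal(dec$rr_joint, 1.5, tolerance = 1e-12)

  # shares sum to 1 for arbitrary admissible coefficients
  set.seed(88)
  for (i in 1:200) {
    beta <- c(runif(1, -2, 2), runif(3, -0.5, 1))
    if (exp((beta[2] + beta[3] + beta[4]) / 2) <= 1) next
    fit$beta <- beta
    dec <- decompose_trend(fit)
    expect_equal(sum(dec$shares$share), 1, tolerance = 1e-10)
  }

  # undefined when the joint RR does not exceed 1
  fit$beta <- c(0, -0.2, -0.2, 0)
  expect_error(decompose_trend(fit), "undefined")
})

test_that("decomposition delta-method SEs match central-difference gradients", {
  tab <- generate_corpus(corpus_params(seed = 21))
  fit <- fit_its_logistic(build_design(tab, "das"))
  dec <- decompose_trend(fit)
  shares_fn <- function(b) {
    rt <- exp(b[2] / 2); rp <- exp(b[3] / 2)
    rj <- exp((b[2] + b[3] + b[4]) / 2)
    c((rt - 1) / (rj - 1), (rp - 1) / (rj - 1),
      (rj - rt - rp + 1) / (rj - 1))
  }
  h <- 1e-6
  J <- matrix(0, 3, 4)
  for (j in 1:4) {
    bp <- fit$beta; bm <- fit$beta
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    J[, j] <- (shares_fn(bp) - shares_fn(bm)) / (2 * h)
  }
  se_num <- sqrt(diag(J %*% fit$vcov %*% t(J)))
  expect_equal(dec$shares$se, se_num, tolerance = 1e-6)
  # one-sided p-values in (0, 1); CIs contain the shares
  expect_true(all(dec$shares$p_one_sided > 0 & dec$shares$p_one_sided < 1))
  expect_true(all(dec$shares$ci_lower <= dec$shares$share &
                    dec$shares$share <= dec$shares$ci_upper))
})

test_that("predicted probabilities match direct evaluation with bounded CIs", {
  fit <- structure(list(beta = c(0, 0, 0, 0), vcov = diag(4) * 0.05,
                        log_likelihood = 0, n = 50, converged = TRUE,
                        iterations = 1), class = "its_fit")
  pr <- predict_probability(fit, time = c(-5, 0, 5), post = c(0, 1, 1))
  expect_equal(pr$probability, rep(0.5, 3))

  tab <- generate_corpus(corpus_params(seed = 13))
  f2 <- fit_its_logistic(build_design(tab, "das"))
  set.seed(1)
  tt <- runif(20, -40, 10); pp <- as.integer(tt >= 0)
  pr2 <- predict_probability(f2, tt, pp)
  direct <- plogis(f2$beta[1] + f2$beta[2] * tt + f2$beta[3] * pp +
                     f2$beta[4] * tt * pp)
  expect_equal(pr2$probability, unname(direct), tolerance = 1e-12)
  expect_true(all(pr2$ci_lower >= 0 & pr2$ci_upper <= 1))
  expect_true(all(pr2$ci_lower <= pr2$probability &
                    pr2$probability <= pr2$ci_upper))
  # monotone in time when the trend is positive and interaction zero
  f2$beta <- c(-1, 0.3, 0.5, 0)
  mono <- predict_probability(f2, seq(-10, -1), 0)
  expect_true(all(diff(mono$probability) > 0))
})

test_that("beta_for_rr_targets inverts the effect transformations", {
  beta <- beta_for_rr_targets(1.04, 1.53, 1.14, 0.35)
  fit <- structure(list(beta = unname(beta), vcov = diag(4) * 1e-6,
                        log_likelihood = 0, n = 10, converged = TRUE,
                        iterations = 1), class = "its_fit")
  eff <- estimate_effects(fit)
  expect_equal(eff$risk_ratio[match(c("pre_trend", "level_change", "slope_ratio"),
                                    eff$label)],
               c(1.04, 1.53, 1.14), tolerance = 1e-10)
})
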