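# Interval and test procedures for proportions: Wilson continuity-corrected
# binomial intervals, Sison-Glaz simultaneous multinomial intervals, and the
# uncorrected Pearson chi-squared test for 2x2 tables.

#' Wilson score confidence interval with continuity correction
#'
#' Computes the continuity-corrected Wilson (score) confidence interval for a
#' binomial proportion, using Newcombe's closed-form bounds. The interval
#' always contains the point estimate `x/n`, is truncated to `[0, 1]`, and
#' reflects under `x -> n - x`. At `x = 0` the lower bound is pinned to 0 and
#' at `x = n` the upper bound is pinned to 1 before truncation of the other
#' bound.
#'
#' @param x number of successes (non-negative integer).
#' @param n number of trials (positive integer).
#' @param level confidence level in (0, 1); default 0.95.
#' @return an object of class `binomial_ci`: a list with elements `x`, `n`,
#'   `level`, `estimate`, `lower`, `upper`.
#' @examples
#' wilson_cc_interval(104, 417)   # [0.209, 0.294] -> 21--29%
#' @export
wilson_cc_interval <- function(x, n, level = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n))
    stop_domain("x and n must be single non-missing counts")
  if (n < 1) stop_domain("n must be >= 1")
  if (x < 0 || x > n) stop_domain("x must satisfy 0 <= x <= n")
  if (!(level > 0 && level < 1)) stop_domain("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  q <- 1 - p
  lower <- if (x == 0) 0 else {
    max(0, (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
          (2 * (n + z^2)))
  }
  upper <- if (x == n) 1 else {
    min(1, (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
          (2 * (n + z^2)))
  }
  structure(list(x = x, n = n, level = level, estimate = p,
                 lower = lower, upper = upper),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %d%%, %g%% CI [%d, %d] (Wilson, continuity-corrected)\n",
              x$x, x$n, as_pct(x$estimate), 100 * x$level,
              as_pct(x$lower), as_pct(x$upper)))
  invisible(x)
}

# Central moments (1..4) and the normalising mass of a Poisson(lambda)
# truncated to [max(0, lambda - c), lambda + c]; computed from factorial
# moments of the truncated distribution. Returns c(m1, m2c, m3c, k4, mass)
# where k4 is the 4th cumulant (m4c - 3 m2c^2).
.trunc_pois_moments <- function(lambda, c) {
  a <- lambda + c
  b <- max(0, lambda - c)
  den <- stats::ppois(a, lambda) - stats::ppois(b - 1, lambda)
  mu <- numeric(4)
  for (r in 1:4) {
    # factorial moment E[X(X-1)...(X-r+1)] of the truncated variable;
    # ppois at negative quantiles is 0, which gives the boundary cases.
    pA <- stats::ppois(a, lambda) - stats::ppois(a - r, lambda)
    pB <- stats::ppois(b - 1, lambda) - stats::ppois(b - r - 1, lambda)
    mu[r] <- lambda^r * (1 - (pA - pB) / den)
  }
  m1 <- mu[1]
  ex2 <- mu[2] + mu[1]
  ex3 <- mu[3] + 3 * mu[2] + mu[1]
  ex4 <- mu[4] + 6 * mu[3] + 7 * mu[2] + mu[1]
  m2c <- ex2 - m1^2
  m3c <- ex3 - 3 * m1 * ex2 + 2 * m1^3
  m4c <- ex4 - 4 * m1 * ex3 + 6 * m1^2 * ex2 - 3 * m1^4
  c(m1, m2c, m3c, m4c - 3 * m2c^2, den)
}

# Simultaneous coverage probability nu(c) for half-width c/n: the conditional
# probability that independent Poisson(x_i) variables all fall within +/- c of
# x_i given their sum equals n, with the density of the conditioning sum
# approximated by a second-order Edgeworth expansion.
.sison_glaz_nu <- function(c, counts, n) {
  if (c == 0) {
    # zero half-width: all truncated variables are degenerate at x_i, so the
    # conditional coverage is exact -- no Edgeworth approximation needed
    return(prod(stats::dpois(counts, counts)) / stats::dpois(n, n))
  }
  m <- vapply(counts, .trunc_pois_moments, numeric(5), c = c)
  s1 <- sum(m[1, ]); s2 <- sum(m[2, ]); s3 <- sum(m[3, ]); s4 <- sum(m[4, ])
  z <- (n - s1) / sqrt(s2)
  g1 <- s3 / s2^1.5
  g2 <- s4 / s2^2
  poly <- 1 + g1 * (z^3 - 3 * z) / 6 +
    g2 * (z^4 - 6 * z^2 + 3) / 24 +
    g1^2 * (z^6 - 15 * z^4 + 45 * z^2 - 15) / 72
  dens <- poly * exp(-z^2 / 2) / sqrt(2 * pi * s2)
  prod(m[5, ]) * dens / stats::dpois(n, n)
}

#' Sison-Glaz simultaneous confidence intervals for multinomial proportions
#'
#' Computes the simultaneous confidence intervals of Sison and Glaz (1995)
#' for the cell probabilities of a multinomial distribution. All intervals
#' share a common half-width `c/n` below the point estimates and
#' `c/n + 2*gamma/n` above them (before truncation to `[0, 1]`). The integer
#' calibration constant `c` is the smallest with coverage `nu(c) < level <=
#' nu(c + 1)`, where `nu` is evaluated with the truncated-Poisson /
#' Edgeworth approximation, and `gamma` in `[0, 1)` interpolates linearly
#' between `nu(c)` and `nu(c + 1)`. If `nu(c)` equals the level exactly,
#' that `c` is used with `gamma = 0`.
#'
#' @param counts vector of at least two non-negative cell counts with
#'   positive total.
#' @param level confidence level in (0, 1); default 0.95.
#' @return an object of class `multinomial_ci`: a list with elements
#'   `counts`, `n`, `level`, `c`, `gamma`, `estimate`, `lower`, `upper`.
#' @references Sison, C.P. and Glaz, J. (1995). Simultaneous confidence
#'   intervals and sample size determination for multinomial proportions.
#'   JASA 90, 366-369.
#' @examples
#' sison_glaz_intervals(c(11, 11, 13))  # bounds round to [17,51] [17,51] [23,57] %
#' @export
sison_glaz_intervals <- function(counts, level = 0.95) {
  if (length(counts) < 2L) stop_domain("need at least two categories")
  if (any(is.na(counts)) || any(counts < 0))
    stop_domain("counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop_domain("total count must be >= 1")
  if (!(level > 0 && level < 1)) stop_domain("level must be in (0, 1)")
  p <- counts / n

  nu_prev <- .sison_glaz_nu(0, counts, n)
  cc <- 1L
  c_cal <- NA_integer_
  gamma <- NA_real_
  repeat {
    nu <- .sison_glaz_nu(cc, counts, n)
    if (nu == level) {           # tie: use this c with gamma = 0
      c_cal <- cc; gamma <- 0; break
    }
    if (nu > level) {
      c_cal <- cc - 1L
      gamma <- (level - nu_prev) / (nu - nu_prev)
      break
    }
    if (cc >= n) {               # degenerate: intervals already span [0,1]
      c_cal <- cc; gamma <- 0; break
    }
    nu_prev <- nu
    cc <- cc + 1L
  }

  lower <- pmax(0, p - c_cal / n)
  upper <- pmin(1, p + c_cal / n + 2 * gamma / n)
  structure(list(counts = counts, n = n, level = level,
                 c = c_cal, gamma = gamma,
                 estimate = p, lower = lower, upper = upper),
            class = "multinomial_ci")
}

#' @export
print.multinomial_ci <- function(x, ...) {
  cat(sprintf("Sison-Glaz simultaneous %g%% CIs (n = %d, c = %d, gamma = %.3f)\n",
              100 * x$level, x$n, x$c, x$gamma))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %3d (%d%%): [%d, %d]\n", x$counts[i], as_pct(x$estimate[i]),
                as_pct(x$lower[i]), as_pct(x$upper[i])))
  }
  invisible(x)
}

#' Pearson chi-squared test of independence for a 2x2 table
#'
#' The classic Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins and *no* continuity correction, on 1 degree of freedom.
#'
#' @param tab a 2x2 matrix of non-negative counts; both row and both column
#'   margins must be positive.
#' @return an object of class `chi2_result`: a list with `statistic`, `df`,
#'   `p_value`, `n`.
#' @examples
#' pearson_chi2_2x2(matrix(c(104, 136, 313, 38), 2))  # 144.18
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop_domain("tab must be 2x2")
  if (any(is.na(tab)) || any(tab < 0)) stop_domain("cells must be non-negative")
  if (any(rowSums(tab) <= 0) || any(colSums(tab) <= 0))
    stop_domain("both margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 n = sum(tab)),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-squared(%d, n = %d) = %.2f, p %s\n", x$df, x$n, x$statistic,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  invisible(x)
}
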