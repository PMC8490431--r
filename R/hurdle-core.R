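# Poisson-Logit hurdle model: PMF, component log-likelihoods, analytic
# gradients and Hessians. The model factorizes as L(beta, gamma) =
# L1(beta) + L2(gamma): a Bernoulli log-likelihood for the zero/positive
# indicator w = 1(y > 0) under a logit link, and a zero-truncated Poisson
# (ZTP) log-likelihood over the positive rows under a log link. The joint
# Hessian is block diagonal, so the two components are information
# orthogonal and can be maximized separately.

# log(1 + exp(x)) without overflow; branchless, accurate for all x.
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# Truncation correction t(lam) = lam * exp(-lam) / (1 - exp(-lam))
# = lam / (exp(lam) - 1) = P(Y = 1 | Y > 0) for a ZTP(lam) variable.
# Second-order Taylor series below 1e-6 avoids 0/0.
ztp_correction <- function(lam) {
  out <- numeric(length(lam))
  tiny <- lam < 1e-6
  out[tiny] <- 1 - lam[tiny] / 2 + lam[tiny]^2 / 12
  out[!tiny] <- lam[!tiny] / expm1(lam[!tiny])
  out
}

# ZTP mean lam / (1 - exp(-lam)) = lam + t(lam); stable as lam -> 0.
ztp_mean <- function(lam) lam + ztp_correction(lam)

# ZTP variance m(lam) * (1 + lam - m(lam)) = m(lam) * (1 - t(lam)); equals
# lam * m'(lam), the curvature factor of the log-link ZTP log-likelihood.
ztp_variance <- function(lam) {
  t <- ztp_correction(lam)
  (lam + t) * (1 - t)
}

#' Log probability mass of the Poisson-Logit hurdle distribution
#'
#' The hurdle distribution places mass `1 - pi` on zero and distributes the
#' remaining mass `pi` over the positive integers in proportion to a
#' zero-truncated Poisson with rate `lam`.
#'
#' @param y Non-negative integer count(s).
#' @param pi Probability of a positive count, in `[0, 1]`.
#' @param lam Positive Poisson rate of the truncated component (ignored for
#'   `y = 0`).
#' @return `log P(Y = y)`, vectorized over the longest argument.
#' @examples
#' hurdle_logpmf(0, pi = 0.3, lam = 1.5) # log(0.7)
#' sum(exp(hurdle_logpmf(0:200, pi = 0.4, lam = 2))) # 1
#' @export
hurdle_logpmf <- function(y, pi, lam) {
  n <- max(length(y), length(pi), length(lam))
  y <- rep_len(y, n); pi <- rep_len(pi, n); lam <- rep_len(lam, n)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("y must be a non-negative integer", call. = FALSE)
  }
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]", call. = FALSE)
  pos <- y > 0
  if (any(pos & lam <= 0)) {
    stop("lam must be positive for positive counts", call. = FALSE)
  }
  out <- numeric(n)
  out[!pos] <- log1p(-pi[!pos])
  if (any(pos)) {
    yp <- y[pos]; lp <- lam[pos]
    # log pi + log ZTP mass: -lam + y log lam - log(1 - e^-lam) - log(y!)
    out[pos] <- log(pi[pos]) - lp + yp * log(lp) -
      log(-expm1(-lp)) - lgamma(yp + 1)
  }
  out
}

check_coef <- function(coef, mat, what) {
  if (length(coef) != ncol(mat)) {
    stop(sprintf("%s has length %d but design matrix has %d columns",
                 what, length(coef), ncol(mat)), call. = FALSE)
  }
  if (any(!is.finite(coef))) stop(what, " must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Logistic-component log-likelihood of the hurdle model
#'
#' Bernoulli log-likelihood of the zero/positive indicator `w = 1(y > 0)`
#' under a logit link: `sum_i w_i x_i'beta - log(1 + exp(x_i'beta))`.
#'
#' @param beta Coefficient vector, length `ncol(X)`.
#' @param data A `hurdle_data` object (or data frame coercible to one).
#' @return The log-likelihood (a sum over all rows, not an average).
#' @export
logistic_loglik <- function(beta, data) {
  data <- as_hurdle_data(data)
  check_coef(beta, data$X, "beta")
  eta <- drop(data$X %*% beta)
  sum((data$y > 0) * eta - log1pexp(eta))
}

#' @rdname logistic_loglik
#' @return `logistic_gradient()`: the score vector
#'   `sum_i x_i (w_i - expit(x_i'beta))`.
#' @export
logistic_gradient <- function(beta, data) {
  data <- as_hurdle_data(data)
  check_coef(beta, data$X, "beta")
  p <- stats::plogis(drop(data$X %*% beta))
  drop(crossprod(data$X, (data$y > 0) - p))
}

#' @rdname logistic_loglik
#' @return `logistic_hessian()`: the (negative semi-definite) Hessian
#'   `-sum_i x_i x_i' expit(x_i'beta)(1 - expit(x_i'beta))`.
#' @export
logistic_hessian <- function(beta, data) {
  data <- as_hurdle_data(data)
  check_coef(beta, data$X, "beta")
  p <- stats::plogis(drop(data$X %*% beta))
  -crossprod(data$X * (p * (1 - p)), data$X)
}

ztp_rows <- function(data) {
  pos <- data$y > 0
  if (!any(pos)) {
    stop("no positive counts; zero-truncated component undefined",
         call. = FALSE)
  }
  list(y = data$y[pos], Z = data$Z[pos, , drop = FALSE])
}

#' Zero-truncated Poisson component log-likelihood of the hurdle model
#'
#' Sum over positive-count rows of
#' `-lam_i + y_i z_i'gamma - log(1 - exp(-lam_i)) - log(y_i!)` with
#' `lam_i = exp(z_i'gamma)`. The `log(y_i!)` constant is included so the
#' value is a true ZTP log-likelihood.
#'
#' @param gamma Coefficient vector, length `ncol(Z)`.
#' @inheritParams logistic_loglik
#' @return The log-likelihood over positive rows.
#' @export
ztp_loglik <- function(gamma, data) {
  data <- as_hurdle_data(data)
  check_coef(gamma, data$Z, "gamma")
  r <- ztp_rows(data)
  eta <- drop(r$Z %*% gamma)
  lam <- exp(eta)
  sum(-lam + r$y * eta - log(-expm1(-lam)) - lgamma(r$y + 1))
}

#' @rdname ztp_loglik
#' @return `ztp_gradient()`: the score `sum_i z_i (y_i - m(lam_i))` over
#'   positive rows, where `m(lam)` is the ZTP mean `lam / (1 - exp(-lam))`.
#' @export
ztp_gradient <- function(gamma, data) {
  data <- as_hurdle_data(data)
  check_coef(gamma, data$Z, "gamma")
  r <- ztp_rows(data)
  lam <- exp(drop(r$Z %*% gamma))
  drop(crossprod(r$Z, r$y - ztp_mean(lam)))
}

#' @rdname ztp_loglik
#' @return `ztp_hessian()`: the Hessian `-sum_i z_i z_i' Var(lam_i)` over
#'   positive rows, with `Var(lam)` the ZTP variance; free of `y`, so
#'   observed and expected information coincide.
#' @export
ztp_hessian <- function(gamma, data) {
  data <- as_hurdle_data(data)
  check_coef(gamma, data$Z, "gamma")
  r <- ztp_rows(data)
  lam <- exp(drop(r$Z %*% gamma))
  -crossprod(r$Z * ztp_variance(lam), r$Z)
}
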