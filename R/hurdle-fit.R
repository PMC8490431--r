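# Newton-Raphson maximization with analytic derivatives and step-halving.
# `fgh(par)` returns list(f, g, H) from one shared linear-predictor pass;
# `fn(par)` is the cheap objective-only evaluator used during halving.
# Convergence: max |gradient| < tol. Divergence of the iterate (|par| above
# `bound`) is treated as a boundary/separation problem, not an error: the
# fit is returned with converged = FALSE and a diagnostic.
newton_maximize <- function(par, fgh, fn, tol = 1e-8, max_iter = 100L,
                            bound = 40) {
  diagnostic <- NA_character_
  converged <- FALSE
  iter <- 0L
  e <- fgh(par)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(e$g)) < tol) { converged <- TRUE; break }
    step <- newton_step(e$H, e$g)
    if (is.null(step) || any(!is.finite(step))) {
      diagnostic <- "singular_hessian"
      break
    }
    # step-halving on non-increase of the objective
    t <- 1
    repeat {
      cand <- par + t * step
      fc <- if (max(abs(cand)) > bound) -Inf else fn(cand)
      if (is.finite(fc) && fc >= e$f - 1e-12) break
      t <- t / 2
      if (t < 1e-10) break
    }
    if (t < 1e-10) { diagnostic <- "step_failure"; break }
    par <- par + t * step
    if (max(abs(par)) > bound - 1e-6) { diagnostic <- "diverged"; break }
    e <- fgh(par)
  }
  if (!converged && is.na(diagnostic)) diagnostic <- "max_iter"
  list(par = par, value = e$f, converged = converged, n_iter = iter,
       diagnostic = diagnostic)
}

# Ascent step for maximization. When -H is positive definite this is the
# plain Newton step; otherwise the Hessian is shifted (H - mu I, Levenberg
# damping) just far enough to restore negative definiteness, guaranteeing
# an ascent direction so step-halving can still make progress on locally
# non-concave objectives (e.g. a surrogate far from its expansion point).
newton_step <- function(H, g) {
  Hs <- (H + t(H)) / 2
  step <- tryCatch({
    R <- chol(-Hs)
    backsolve(R, forwardsolve(t(R), g))
  }, error = function(e) NULL)
  if (!is.null(step)) return(step)
  ev <- eigen(Hs, symmetric = TRUE, only.values = TRUE)$values
  mu <- max(ev) + max(abs(ev), 1e-8) * 1e-2
  tryCatch(solve(Hs - mu * diag(nrow(Hs)), -g), error = function(e) NULL)
}

# Newton's method on a score equation: finds the stationary point nearest
# the start, with a line search that enforces decrease of the score norm.
# Used for the surrogate log-likelihood, whose curvature correction can
# make it non-concave (even unbounded) far from the expansion point; the
# estimator is the stationary point near the initial estimate, so descent
# on ||g|| is the appropriate globalization. For a concave objective this
# reduces to ordinary Newton maximization.
newton_root <- function(par, gH, tol = 1e-8, max_iter = 100L, bound = 40) {
  diagnostic <- NA_character_
  converged <- FALSE
  iter <- 0L
  e <- gH(par)
  nrm <- max(abs(e$g))
  while (iter < max_iter) {
    iter <- iter + 1L
    if (nrm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(e$H, -e$g), error = function(err) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      diagnostic <- "singular_hessian"
      break
    }
    t <- 1
    repeat {
      cand <- par + t * step
      ec <- if (max(abs(cand)) > bound) NULL else
        tryCatch(gH(cand), error = function(err) NULL)
      if (!is.null(ec) && all(is.finite(ec$g)) &&
          max(abs(ec$g)) <= nrm * (1 - 1e-4 * t)) break
      t <- t / 2
      if (t < 1e-10) break
    }
    if (t < 1e-10) { diagnostic <- "stalled"; break }
    par <- cand
    e <- ec
    nrm <- max(abs(e$g))
  }
  if (!converged && is.na(diagnostic)) diagnostic <- "max_iter"
  list(par = par, converged = converged, n_iter = iter,
       diagnostic = diagnostic)
}

# Fused evaluators on raw matrices (one linear-predictor pass each).
logistic_fgh <- function(X, w) {
  function(beta) {
    eta <- drop(X %*% beta)
    l <- log1pexp(eta)
    p <- exp(eta - l)              # expit(eta), reusing the same pass
    list(f = sum(w * eta - l),
         g = drop(crossprod(X, w - p)),
         H = -crossprod(X * (p * (1 - p)), X))
  }
}

logistic_f <- function(X, w) {
  function(beta) {
    eta <- drop(X %*% beta)
    sum(w * eta - log1pexp(eta))
  }
}

ztp_fgh <- function(Z, y, lfact = lgamma(y + 1)) {
  function(gamma) {
    eta <- drop(Z %*% gamma)
    lam <- exp(eta)
    list(f = sum(-lam + y * eta - log(-expm1(-lam)) - lfact),
         g = drop(crossprod(Z, y - ztp_mean(lam))),
         H = -crossprod(Z * ztp_variance(lam), Z))
  }
}

ztp_f <- function(Z, y, lfact = lgamma(y + 1)) {
  function(gamma) {
    eta <- drop(Z %*% gamma)
    lam <- exp(eta)
    sum(-lam + y * eta - log(-expm1(-lam)) - lfact)
  }
}

# Starting value for the ZTP intercept: solve m(lam) = mean positive count.
# Returns NULL when the mean is at (or numerically at) the boundary 1,
# where the ZTP MLE diverges to lam -> 0.
ztp_start <- function(ybar) {
  if (ybar <= 1 + 1e-10) return(NULL)
  stats::uniroot(function(l) ztp_mean(exp(l)) - ybar,
                 lower = -30, upper = log(ybar) + 5, tol = 1e-10)$root
}

check_full_rank <- function(m, what) {
  qr_m <- qr(m)
  if (qr_m$rank < ncol(m)) {
    bad <- colnames(m)[qr_m$pivot[(qr_m$rank + 1):ncol(m)]]
    stop(sprintf("%s design matrix is rank deficient; collinear column(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Fit a Poisson-Logit hurdle model to one site's data
#'
#' Maximizes the two component log-likelihoods separately by Newton-Raphson
#' with analytic gradients and Hessians (information orthogonality makes the
#' separate fits equal to a joint fit). Coefficient covariance matrices are
#' the inverse negated Hessians at the optimum.
#'
#' Rare-event data can place the ZTP maximum on the boundary (all positive
#' counts equal to 1, so the likelihood increases as `lam -> 0`) and the
#' logistic maximum at infinity (complete separation). Such fits are
#' returned with `converged = FALSE` and a per-component diagnostic rather
#' than an error, so multi-site drivers can record and handle them.
#'
#' @inheritParams logistic_loglik
#' @param tol Convergence tolerance: maximum absolute component-likelihood
#'   gradient.
#' @param max_iter Newton iteration cap per component.
#' @param ... Passed to [hurdle_data()] when `data` is a data frame.
#' @return A `hurdle_fit` object; see [tidy.hurdle_fit()] and
#'   [glance.hurdle_fit()] for tibble summaries.
#' @examples
#' df <- simulate_site(5000, beta = c(-1, -1, 1), gamma = c(0.3, -1, 1),
#'                     seed = 7)
#' fit <- fit_hurdle(df)
#' tidy(fit)
#' @export
fit_hurdle <- function(data, tol = 1e-8, max_iter = 100L, ...) {
  data <- as_hurdle_data(data, ...)
  n <- length(data$y)
  n_pos <- sum(data$y > 0)
  if (n_pos == 0L) {
    stop("no positive counts; zero-truncated component undefined",
         call. = FALSE)
  }
  check_full_rank(data$X, "logistic")
  check_full_rank(data$Z, "zero-truncated Poisson")
  p <- ncol(data$X); q <- ncol(data$Z)

  w <- as.numeric(data$y > 0)
  # warm start at the marginal log-odds: saves several Newton iterations
  # on rare-event data, where the intercept dominates
  b0 <- stats::qlogis(min(max(mean(w), 1e-6), 1 - 1e-6))
  lg <- newton_maximize(
    c(b0, rep(0, p - 1)), fgh = logistic_fgh(data$X, w),
    fn = logistic_f(data$X, w), tol = tol, max_iter = max_iter)
  if (identical(lg$diagnostic, "diverged")) lg$diagnostic <- "separation"
  if (lg$converged) {
    # complete separation: the fitted direction classifies every row
    # strictly, so the true maximum is at infinity even though the score
    # is numerically flat at a finite iterate
    eta <- drop(data$X %*% lg$par)
    if (all((2 * w - 1) * eta > 0)) {
      lg$converged <- FALSE
      lg$diagnostic <- "separation"
    }
  }

  pos <- data$y > 0
  pos_y <- data$y[pos]
  Zp <- data$Z[pos, , drop = FALSE]
  g0 <- ztp_start(mean(pos_y))
  if (is.null(g0)) {
    zt <- list(par = rep(NA_real_, q), value = NA_real_, converged = FALSE,
               n_iter = 0L, diagnostic = "ztp_boundary")
  } else {
    zt <- newton_maximize(
      c(g0, rep(0, q - 1)), fgh = ztp_fgh(Zp, pos_y), fn = ztp_f(Zp, pos_y),
      tol = tol, max_iter = max_iter)
    if (identical(zt$diagnostic, "diverged")) zt$diagnostic <- "ztp_boundary"
  }

  cov_of <- function(res, he) {
    if (!res$converged) return(matrix(NA_real_, length(res$par), length(res$par)))
    v <- solve(-he(res$par))
    (v + t(v)) / 2
  }
  beta_var <- cov_of(lg, function(b) logistic_hessian(b, data))
  gamma_var <- if (all(is.finite(zt$par))) {
    cov_of(zt, function(g) ztp_hessian(g, data))
  } else {
    matrix(NA_real_, q, q)
  }
  dimnames(beta_var) <- list(colnames(data$X), colnames(data$X))
  dimnames(gamma_var) <- list(colnames(data$Z), colnames(data$Z))

  structure(
    list(
      params = list(beta = stats::setNames(lg$par, colnames(data$X)),
                    gamma = stats::setNames(zt$par, colnames(data$Z))),
      beta_var = beta_var, gamma_var = gamma_var,
      loglik_logistic = lg$value,
      loglik_ztp = zt$value,
      converged = lg$converged && zt$converged,
      logistic_converged = lg$converged,
      ztp_converged = zt$converged,
      n_iter = max(lg$n_iter, zt$n_iter),
      diagnostics = c(logistic = lg$diagnostic, ztp = zt$diagnostic),
      n = n, n_pos = n_pos, site_id = data$site_id),
    class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> site '%s': n = %d (%d positive), %s\n",
              x$site_id, x$n, x$n_pos,
              if (x$converged) "converged" else
                paste("NOT converged:",
                      paste(stats::na.omit(x$diagnostics), collapse = ", "))))
  print(tidy(x), ...)
  invisible(x)
}

fit_tidy_tbl <- function(params, beta_var, gamma_var) {
  one <- function(component, est, vcov) {
    se <- sqrt(pmax(diag(vcov), 0))
    tibble::tibble(
      component = component, term = names(est),
      estimate = unname(est), std.error = unname(se),
      statistic = unname(est / se),
      p.value = 2 * stats::pnorm(-abs(unname(est / se))))
  }
  dplyr::bind_rows(one("logistic", params$beta, beta_var),
                   one("ztp", params$gamma, gamma_var))
}

#' Tidy a hurdle-model fit
#'
#' @param x A `hurdle_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `component` ("logistic" or
#'   "ztp"), `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy hurdle_fit
#' @export
tidy.hurdle_fit <- function(x, ...) {
  fit_tidy_tbl(x$params, x$beta_var, x$gamma_var)
}

#' Glance at a hurdle-model fit
#'
#' @param x A `hurdle_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, component log-likelihoods,
#'   convergence flags and iteration count.
#' @method glance hurdle_fit
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_pos = x$n_pos,
    loglik_logistic = x$loglik_logistic, loglik_ztp = x$loglik_ztp,
    converged = x$converged, logistic_converged = x$logistic_converged,
    ztp_converged = x$ztp_converged, n_iter = x$n_iter)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
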