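# The one-shot distributed estimator (ODAH). Per-site likelihood quantities
# are exchanged on the AVERAGE scale: logistic gradients/Hessians are
# divided by the site's row count n_j, ZTP ones by its positive-count row
# count. Aggregation recombines them with n_j / N (resp. n_pos_j / N_pos)
# weights, so the aggregate equals the pooled average-likelihood gradient
# exactly. The surrogate log-likelihood corrects the lead site's average
# log-likelihood with the first- and second-order differences between the
# aggregated and lead-site derivatives at the initial estimate.

#' Round-1 aggregate message: a site's hurdle-fit summary
#'
#' Extracts the privacy-preserving summary a collaborating site shares in
#' the initialization round: coefficient estimates, per-coefficient
#' variances, sample sizes and convergence flags. No patient-level value is
#' included.
#'
#' @param fit A `hurdle_fit` object.
#' @return A `site_summary` object.
#' @export
site_summary <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  structure(
    list(site_id = fit$site_id, n = fit$n, n_pos = fit$n_pos,
         beta_hat = fit$params$beta,
         gamma_hat = fit$params$gamma,
         beta_var_diag = diag(fit$beta_var),
         gamma_var_diag = diag(fit$gamma_var),
         logistic_converged = fit$logistic_converged,
         ztp_converged = fit$ztp_converged),
    class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("<site_summary> '%s': n = %d (%d positive)%s\n", x$site_id,
              x$n, x$n_pos,
              if (x$logistic_converged && x$ztp_converged) "" else
                " [unconverged component(s)]"))
  invisible(x)
}

# Coordinate-wise fixed-effects (inverse-variance) combination.
# est, var: K x p matrices. Returns the combined estimate and variance.
meta_combine <- function(est, var) {
  if (nrow(est) == 0) stop("no converged site estimates", call. = FALSE)
  if (any(!is.finite(var)) || any(var <= 0)) {
    stop("site variances must be finite and strictly positive",
         call. = FALSE)
  }
  w <- 1 / var
  list(est = colSums(est * w) / colSums(w), var = 1 / colSums(w))
}

summary_matrices <- function(summaries, component) {
  ok_field <- paste0(if (component == "beta") "logistic" else "ztp",
                     "_converged")
  hat_field <- paste0(component, "_hat")
  var_field <- paste0(component, "_var_diag")
  ok <- vapply(summaries, `[[`, TRUE, ok_field)
  lens <- vapply(summaries, function(s) length(s[[hat_field]]), 1L)
  if (length(unique(lens)) != 1L) {
    stop("summaries have mismatched coefficient dimensions", call. = FALSE)
  }
  excluded <- vapply(summaries, `[[`, "", "site_id")[!ok]
  list(est = do.call(rbind, lapply(summaries[ok], `[[`, hat_field)),
       var = do.call(rbind, lapply(summaries[ok], `[[`, var_field)),
       excluded = excluded)
}

#' Initial estimates by fixed-effects meta-analysis
#'
#' Combines the round-1 site summaries coordinate-wise with inverse-variance
#' weights to form the initial estimates at which every site will evaluate
#' its likelihood gradients. Sites whose fit did not converge for a
#' component are excluded from that component's combination, with a warning.
#'
#' @param summaries A list of [site_summary()] objects.
#' @return An `odah_init` object with elements `beta_bar`, `gamma_bar`,
#'   `source = "meta"`.
#' @export
meta_initialize <- function(summaries) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "site_summary")))
  b <- summary_matrices(summaries, "beta")
  g <- summary_matrices(summaries, "gamma")
  excl <- union(b$excluded, g$excluded)
  if (length(excl)) {
    warning("excluding unconverged site fit(s) from meta initialization: ",
            paste(excl, collapse = ", "), call. = FALSE)
  }
  structure(
    list(beta_bar = meta_combine(b$est, b$var)$est,
         gamma_bar = meta_combine(g$est, g$var)$est,
         source = "meta"),
    class = "odah_init")
}

#' Initial estimates from the lead site's own fit
#'
#' The alternative initialization that skips the meta-analysis round: the
#' lead site's maximum-likelihood estimates are broadcast directly,
#' reducing the protocol to a single communication round.
#'
#' @param lead_fit A converged `hurdle_fit` for the lead site.
#' @return An `odah_init` object with `source = "lead"`.
#' @export
lead_initialize <- function(lead_fit) {
  stopifnot(inherits(lead_fit, "hurdle_fit"))
  if (!lead_fit$converged) {
    stop("lead-site fit did not converge; cannot initialize from it",
         call. = FALSE)
  }
  structure(
    list(beta_bar = lead_fit$params$beta,
         gamma_bar = lead_fit$params$gamma,
         source = "lead"),
    class = "odah_init")
}

#' @export
print.odah_init <- function(x, ...) {
  cat(sprintf("<odah_init> source = %s\n  beta_bar:  %s\n  gamma_bar: %s\n",
              x$source, paste(signif(x$beta_bar, 5), collapse = ", "),
              paste(signif(x$gamma_bar, 5), collapse = ", ")))
  invisible(x)
}

#' Round-2 aggregate message: likelihood derivatives at the initial estimate
#'
#' Evaluates the analytic first- and second-order derivatives of both
#' component log-likelihoods at the broadcast initial estimates and scales
#' them to per-row averages (logistic: all rows; ZTP: positive rows). The
#' payload carries only these aggregate arrays plus sample sizes.
#'
#' A site with no positive counts sets the ZTP fields to `NULL` (flagged
#' absent); it still contributes its full logistic derivatives.
#'
#' @inheritParams logistic_loglik
#' @param init An `odah_init` object.
#' @return A `gradient_payload` object.
#' @export
compute_gradients <- function(data, init) {
  data <- as_hurdle_data(data)
  stopifnot(inherits(init, "odah_init"))
  n <- length(data$y)
  n_pos <- sum(data$y > 0)
  out <- list(
    site_id = data$site_id, n = n, n_pos = n_pos,
    evaluated_at = init,
    grad1_logistic = logistic_gradient(init$beta_bar, data) / n,
    hess_logistic = logistic_hessian(init$beta_bar, data) / n,
    grad1_ztp = NULL, hess_ztp = NULL)
  if (n_pos > 0) {
    out$grad1_ztp <- ztp_gradient(init$gamma_bar, data) / n_pos
    out$hess_ztp <- ztp_hessian(init$gamma_bar, data) / n_pos
  }
  structure(out, class = "gradient_payload")
}

#' @export
print.gradient_payload <- function(x, ...) {
  cat(sprintf("<gradient_payload> '%s': n = %d, n_pos = %d%s\n",
              x$site_id, x$n, x$n_pos,
              if (is.null(x$grad1_ztp)) " (ZTP block absent)" else ""))
  invisible(x)
}

same_point <- function(a, b) {
  length(a) == length(b) && max(abs(a - b)) < 1e-12
}

#' Aggregate the sites' gradient payloads
#'
#' Forms the sample-size-weighted averages of the per-site average-scale
#' derivatives: `sum_j n_j A_j / N` for the logistic blocks and
#' `sum_j n_pos_j A_j / N_pos` for the ZTP blocks (sites without positive
#' counts drop out of the ZTP average with zero weight). The result equals
#' the pooled-data average-likelihood derivatives at the initial estimate.
#'
#' @param payloads A list of [compute_gradients()] payloads, all evaluated
#'   at the same initial estimates.
#' @return An `odah_aggregate` object with the combined blocks, `N`,
#'   `N_pos`, `K` and the shared `init`.
#' @export
aggregate_gradients <- function(payloads) {
  stopifnot(length(payloads) >= 1,
            all(vapply(payloads, inherits, TRUE, "gradient_payload")))
  init <- payloads[[1]]$evaluated_at
  agree <- vapply(payloads, function(p) {
    same_point(p$evaluated_at$beta_bar, init$beta_bar) &&
      same_point(p$evaluated_at$gamma_bar, init$gamma_bar)
  }, TRUE)
  if (!all(agree)) stop("gradient evaluation points differ", call. = FALSE)

  n <- vapply(payloads, `[[`, 1, "n")
  n_pos <- vapply(payloads, `[[`, 1, "n_pos")
  N <- sum(n); N_pos <- sum(n_pos)
  wavg <- function(field, w) {
    keep <- w > 0 & !vapply(payloads, function(p) is.null(p[[field]]), TRUE)
    if (!any(keep)) return(NULL)
    Reduce(`+`, Map(function(p, wt) wt * p[[field]],
                    payloads[keep], w[keep])) / sum(w[keep])
  }
  if (N_pos == 0) {
    stop("no site has positive counts; ZTP component undefined",
         call. = FALSE)
  }
  structure(
    list(init = init, K = length(payloads), N = N, N_pos = N_pos,
         grad1_logistic = wavg("grad1_logistic", n),
         hess_logistic = wavg("hess_logistic", n),
         grad1_ztp = wavg("grad1_ztp", n_pos),
         hess_ztp = wavg("hess_ztp", n_pos)),
    class = "odah_aggregate")
}

# Lead-site average-scale derivative helpers.
lead_avg <- function(lead_data) {
  n <- length(lead_data$y)
  n_pos <- sum(lead_data$y > 0)
  if (n_pos == 0) {
    stop("lead site has no positive counts; cannot build ZTP surrogate",
         call. = FALSE)
  }
  list(n = n, n_pos = n_pos)
}

#' Surrogate log-likelihoods at given parameter values
#'
#' The surrogate for each component is the lead site's average
#' log-likelihood plus a linear correction
#' `<gbar_N(theta_bar) - gbar_1(theta_bar), theta>` and a quadratic
#' correction
#' `(theta - theta_bar)' [Hbar_N - Hbar_1](theta - theta_bar) / 2`, built
#' from the aggregated round-2 derivatives. Its gradient at `theta_bar`
#' equals the pooled average-likelihood gradient exactly.
#'
#' @param params List with elements `beta` and `gamma`.
#' @param lead_data The lead site's `hurdle_data`.
#' @param aggregated An `odah_aggregate`.
#' @param init The shared initial estimates (defaults to those stored in
#'   `aggregated`).
#' @return Named numeric vector `c(logistic = , ztp = )`.
#' @export
surrogate_loglik <- function(params, lead_data, aggregated,
                             init = aggregated$init) {
  lead_data <- as_hurdle_data(lead_data)
  stopifnot(inherits(aggregated, "odah_aggregate"))
  sz <- lead_avg(lead_data)
  s1 <- surrogate_parts(lead_data, aggregated, init)
  beta <- params$beta; gamma <- params$gamma
  lg <- logistic_loglik(beta, lead_data) / sz$n +
    sum(s1$lg$dg * beta) +
    0.5 * drop(crossprod(beta - init$beta_bar,
                         s1$lg$dH %*% (beta - init$beta_bar)))
  zt <- ztp_loglik(gamma, lead_data) / sz$n_pos +
    sum(s1$zt$dg * gamma) +
    0.5 * drop(crossprod(gamma - init$gamma_bar,
                         s1$zt$dH %*% (gamma - init$gamma_bar)))
  c(logistic = lg, ztp = zt)
}

# First/second-order correction terms (global minus lead, at init).
surrogate_parts <- function(lead_data, aggregated, init) {
  sz <- lead_avg(lead_data)
  list(
    lg = list(
      dg = aggregated$grad1_logistic -
        logistic_gradient(init$beta_bar, lead_data) / sz$n,
      dH = aggregated$hess_logistic -
        logistic_hessian(init$beta_bar, lead_data) / sz$n),
    zt = list(
      dg = aggregated$grad1_ztp -
        ztp_gradient(init$gamma_bar, lead_data) / sz$n_pos,
      dH = aggregated$hess_ztp -
        ztp_hessian(init$gamma_bar, lead_data) / sz$n_pos))
}

#' Maximize the surrogate log-likelihoods: the ODAH estimator
#'
#' Newton-Raphson from the initial estimates, independently per component.
#' Coefficient covariance is the inverse of `N` (logistic) or `N_pos` (ZTP)
#' times the negated surrogate Hessian at the optimum, restoring absolute
#' scale from the averaged likelihood.
#'
#' @inheritParams surrogate_loglik
#' @param tol,max_iter Newton controls, as in [fit_hurdle()].
#' @return An `odah_fit` object; `tidy()` and `glance()` methods apply.
#' @export
odah_solve <- function(lead_data, aggregated, init = aggregated$init,
                       tol = 1e-8, max_iter = 100L) {
  lead_data <- as_hurdle_data(lead_data)
  stopifnot(inherits(aggregated, "odah_aggregate"),
            inherits(init, "odah_init"))
  sz <- lead_avg(lead_data)
  parts <- surrogate_parts(lead_data, aggregated, init)

  solve_component <- function(theta0, fgh, fn, scale, dg, dH, bar) {
    sfgh <- function(th) {
      e <- fgh(th)
      d <- th - bar
      list(f = e$f / scale + sum(dg * th) +
             0.5 * drop(crossprod(d, dH %*% d)),
           g = e$g / scale + dg + drop(dH %*% d),
           H = e$H / scale + dH)
    }
    H0 <- sfgh(theta0)$H
    ev <- eigen((H0 + t(H0)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (max(ev) >= 0) {
      stop(sprintf(
        "surrogate not concave at the initial estimate (max eigenvalue %.3g)",
        max(ev)), call. = FALSE)
    }
    res <- newton_root(theta0, function(th) sfgh(th)[c("g", "H")],
                       tol = tol, max_iter = max_iter)
    at_opt <- sfgh(res$par)
    res$value <- at_opt$f
    res$hess <- at_opt$H
    res
  }

  w <- as.numeric(lead_data$y > 0)
  pos <- lead_data$y > 0
  Zp <- lead_data$Z[pos, , drop = FALSE]
  yp <- lead_data$y[pos]
  lg <- solve_component(
    init$beta_bar,
    fgh = logistic_fgh(lead_data$X, w), fn = logistic_f(lead_data$X, w),
    scale = sz$n, dg = parts$lg$dg, dH = parts$lg$dH, bar = init$beta_bar)
  zt <- solve_component(
    init$gamma_bar,
    fgh = ztp_fgh(Zp, yp), fn = ztp_f(Zp, yp),
    scale = sz$n_pos, dg = parts$zt$dg, dH = parts$zt$dH,
    bar = init$gamma_bar)

  vcov_of <- function(res, scale) {
    v <- solve(scale * (-res$hess))
    (v + t(v)) / 2
  }
  beta_var <- vcov_of(lg, aggregated$N)
  gamma_var <- vcov_of(zt, aggregated$N_pos)
  nm_b <- colnames(lead_data$X); nm_g <- colnames(lead_data$Z)
  dimnames(beta_var) <- list(nm_b, nm_b)
  dimnames(gamma_var) <- list(nm_g, nm_g)

  structure(
    list(params = list(beta = stats::setNames(lg$par, nm_b),
                       gamma = stats::setNames(zt$par, nm_g)),
         beta_var = beta_var, gamma_var = gamma_var,
         initial = init,
         surrogate_loglik_logistic = lg$value,
         surrogate_loglik_ztp = zt$value,
         converged = lg$converged && zt$converged,
         logistic_converged = lg$converged,
         ztp_converged = zt$converged,
         n_iter = max(lg$n_iter, zt$n_iter),
         N = aggregated$N, N_pos = aggregated$N_pos, K = aggregated$K),
    class = "odah_fit")
}

#' @export
print.odah_fit <- function(x, ...) {
  cat(sprintf(
    "<odah_fit> K = %d sites, N = %d (%d positive), init = %s, %s\n",
    x$K, x$N, x$N_pos, x$initial$source,
    if (x$converged) "converged" else "NOT converged"))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname tidy.hurdle_fit
#' @method tidy odah_fit
#' @export
tidy.odah_fit <- function(x, ...) {
  fit_tidy_tbl(x$params, x$beta_var, x$gamma_var)
}

#' @rdname glance.hurdle_fit
#' @method glance odah_fit
#' @export
glance.odah_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, N = x$N, N_pos = x$N_pos, init_source = x$initial$source,
    surrogate_loglik_logistic = x$surrogate_loglik_logistic,
    surrogate_loglik_ztp = x$surrogate_loglik_ztp,
    converged = x$converged, n_iter = x$n_iter)
}

#' Run the full two-round ODAH protocol in memory
#'
#' Convenience driver over the site-level steps: fit each site
#' ([fit_hurdle()]), meta-analyze the summaries ([meta_initialize()]) or
#' take the lead fit ([lead_initialize()]), collect one gradient payload
#' per site ([compute_gradients()]), aggregate, and solve the surrogate at
#' the lead site. Exactly two aggregate messages per site pass between
#' sites when `init = "meta"`, one when `init = "lead"`.
#'
#' @param datasets List of per-site data (data frames or `hurdle_data`);
#'   the first element is the lead site.
#' @param init `"meta"` or `"lead"`.
#' @param tol,max_iter Newton controls.
#' @return An `odah_fit` object.
#' @examples
#' sites <- lapply(1:3, function(j)
#'   simulate_site(3000, beta = c(-1.5, -1, 1), gamma = c(0.5, -1, 1),
#'                 seed = j, site_id = paste0("s", j)))
#' fit <- odah(sites)
#' glance(fit)
#' @export
odah <- function(datasets, init = c("meta", "lead"), tol = 1e-8,
                 max_iter = 100L) {
  init <- match.arg(init)
  datasets <- lapply(datasets, as_hurdle_data)
  initial <- if (init == "meta") {
    fits <- lapply(datasets, fit_hurdle, tol = tol, max_iter = max_iter)
    meta_initialize(lapply(fits, site_summary))
  } else {
    lead_initialize(fit_hurdle(datasets[[1]], tol = tol,
                               max_iter = max_iter))
  }
  payloads <- lapply(datasets, compute_gradients, init = initial)
  odah_solve(datasets[[1]], aggregate_gradients(payloads), initial,
             tol = tol, max_iter = max_iter)
}
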