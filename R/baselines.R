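# Comparator estimators: pooled analysis (gold standard), fixed-effects
# meta-analysis of per-site fits, and lead-site-only analysis. All three
# return a common `method_estimate` container so the study runner can
# tabulate them next to ODAH.

method_estimate <- function(method, beta, gamma, beta_var_diag,
                            gamma_var_diag, converged = TRUE,
                            logistic_converged = converged,
                            ztp_converged = converged, n = NA_integer_) {
  structure(
    list(method = method,
         params = list(beta = beta, gamma = gamma),
         beta_var_diag = beta_var_diag, gamma_var_diag = gamma_var_diag,
         converged = converged,
         logistic_converged = logistic_converged,
         ztp_converged = ztp_converged, n = n),
    class = "method_estimate")
}

#' @export
print.method_estimate <- function(x, ...) {
  cat(sprintf("<method_estimate> %s%s\n", x$method,
              if (x$converged) "" else " [unconverged component(s)]"))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname tidy.hurdle_fit
#' @method tidy method_estimate
#' @export
tidy.method_estimate <- function(x, ...) {
  tbl <- fit_tidy_tbl(x$params,
                      diag(x$beta_var_diag, length(x$beta_var_diag)),
                      diag(x$gamma_var_diag, length(x$gamma_var_diag)))
  tbl$method <- x$method
  tbl[c("method", setdiff(names(tbl), "method"))]
}

as_method_estimate <- function(fit, method) {
  method_estimate(
    method,
    beta = fit$params$beta, gamma = fit$params$gamma,
    beta_var_diag = diag(fit$beta_var),
    gamma_var_diag = diag(fit$gamma_var),
    converged = fit$converged,
    logistic_converged = fit$logistic_converged,
    ztp_converged = fit$ztp_converged,
    n = if (!is.null(fit$n)) fit$n else fit$N)
}

#' Pooled analysis: the gold standard
#'
#' Concatenates all sites' patient-level rows and fits one hurdle model —
#' the estimate every distributed method is measured against.
#'
#' @param datasets List of per-site data (data frames or `hurdle_data`).
#' @param ... Passed to [fit_hurdle()].
#' @return A `method_estimate` with `method = "pooled"`.
#' @export
pooled_fit <- function(datasets, ...) {
  if (inherits(datasets, "hurdle_data") || is.data.frame(datasets)) {
    datasets <- list(datasets)
  }
  as_method_estimate(fit_hurdle(bind_hurdle_data(datasets), ...), "pooled")
}

#' Fixed-effects meta-analysis of per-site hurdle fits
#'
#' Coordinate-wise inverse-variance combination of the site summaries;
#' the combined variance of each coefficient is `1 / sum_j w_j`. Sites
#' whose fit did not converge for a component are excluded from that
#' component (with a warning via [meta_initialize()] semantics).
#'
#' @param summaries List of [site_summary()] objects.
#' @return A `method_estimate` with `method = "meta"`.
#' @export
meta_fit <- function(summaries) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "site_summary")))
  b <- summary_matrices(summaries, "beta")
  g <- summary_matrices(summaries, "gamma")
  excl <- union(b$excluded, g$excluded)
  if (length(excl)) {
    warning("excluding unconverged site fit(s) from meta-analysis: ",
            paste(excl, collapse = ", "), call. = FALSE)
  }
  cb <- meta_combine(b$est, b$var)
  cg <- meta_combine(g$est, g$var)
  method_estimate("meta", beta = cb$est, gamma = cg$est,
                  beta_var_diag = cb$var, gamma_var_diag = cg$var,
                  n = sum(vapply(summaries, `[[`, 1, "n")))
}

#' Lead-site-only analysis
#'
#' Fits the hurdle model on the lead site's data alone, emulating a
#' single-site study. Rare-event lead sites may fail to converge; the
#' convergence flags are propagated so a study runner can summarize over
#' successes (medians rather than means).
#'
#' @param lead_data The lead site's data.
#' @param ... Passed to [fit_hurdle()].
#' @return A `method_estimate` with `method = "lead"`.
#' @export
lead_fit <- function(lead_data, ...) {
  as_method_estimate(fit_hurdle(lead_data, ...), "lead")
}
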