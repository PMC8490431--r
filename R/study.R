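# Replicated simulation study: generate a multi-site draw, run all four
# estimators, and evaluate each distributed method by its bias relative to
# the pooled gold standard. Relative bias aggregates ratio-of-means:
# 100 * (mean_m - mean_pooled) / |mean_pooled|; the lead-site method is
# additionally summarized by the median of its per-replicate relative
# deviations, which is robust to the outlying estimates a rare-event lead
# site produces.

quiet_try <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NULL)
}

estimate_rows <- function(est, method) {
  if (is.null(est)) {
    return(tibble::tibble(
      method = method, component = c("logistic", "ztp"),
      term = NA_character_, estimate = NA_real_, variance = NA_real_,
      converged = FALSE))
  }
  dplyr::bind_rows(
    tibble::tibble(
      method = method, component = "logistic",
      term = names(est$params$beta),
      estimate = unname(est$params$beta),
      variance = unname(est$beta_var_diag),
      converged = est$logistic_converged),
    tibble::tibble(
      method = method, component = "ztp",
      term = names(est$params$gamma),
      estimate = unname(est$params$gamma),
      variance = unname(est$gamma_var_diag),
      converged = est$ztp_converged))
}

#' Run one replicate of a simulation setting
#'
#' Generates the K site tables, then computes all four estimators: pooled,
#' fixed-effects meta-analysis, lead-site-only, and ODAH with meta-analytic
#' initialization. A component fit failure (boundary ZTP likelihood,
#' separation, no positive counts) is recorded for that method, never
#' propagated as an error.
#'
#' @param setting One setting: a row of [reference_settings()] (or any list
#'   with `K`, `N`, `n_lead`, `beta0`, `gamma0` and optional slopes).
#' @param replicate Replicate index (deterministic child seed stream).
#' @param seed Study-level integer seed.
#' @return A tibble with columns `method`, `component`, `term`, `estimate`,
#'   `variance`, `converged`, plus attribute `realized` (a one-row tibble
#'   of realized marginal prevalence and event rate).
#' @export
run_replicate <- function(setting, replicate = 1L, seed = 1L) {
  rep_seed <- derive_seed(seed, replicate)
  sites <- simulate_sites(setting, rep_seed)
  fits <- lapply(sites, function(s) quiet_try(fit_hurdle(s)))
  summaries <- lapply(Filter(Negate(is.null), fits), site_summary)

  pooled <- quiet_try(pooled_fit(sites))
  meta <- if (length(summaries)) quiet_try(meta_fit(summaries)) else NULL
  lead <- if (!is.null(fits[[1]])) as_method_estimate(fits[[1]], "lead")

  odah_est <- NULL
  if (length(summaries)) {
    odah_est <- quiet_try({
      init <- meta_initialize(summaries)
      payloads <- lapply(sites, compute_gradients, init = init)
      as_method_estimate(
        odah_solve(sites[[1]], aggregate_gradients(payloads), init), "odah")
    })
  }

  out <- dplyr::bind_rows(
    estimate_rows(pooled, "pooled"), estimate_rows(meta, "meta"),
    estimate_rows(lead, "lead"), estimate_rows(odah_est, "odah"))
  out$replicate <- as.integer(replicate)
  y_all <- unlist(lapply(sites, `[[`, "y"), use.names = FALSE)
  attr(out, "realized") <- tibble::tibble(
    replicate = as.integer(replicate),
    prevalence = mean(y_all > 0), event_rate = mean(y_all),
    n_pos = sum(y_all > 0))
  out
}

#' Run a replicated simulation study for one setting
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of Monte-Carlo replicates (>= 2).
#' @param progress Print a dot every 10 replicates.
#' @return An `odah_study` object: list with the per-replicate `estimates`
#'   tibble, the `summary` tibble of per-method/per-coefficient bias
#'   statistics (see Details), `realized` rates, `failures` counts, and the
#'   setting.
#'
#' @details The `summary` tibble reports, per method, component and term:
#'   `n_ok` (converged replicates), `mean_estimate` and its Monte-Carlo
#'   standard error `mc_se`, `rel_bias_pct` (ratio-of-means relative bias vs
#'   pooled, in %), its Monte-Carlo SE `rel_bias_mc_se`, and
#'   `median_rel_dev_pct` (median per-replicate relative deviation vs the
#'   same replicate's pooled estimate, the lead-site reporting metric).
#' @examples
#' \donttest{
#' setting <- list(K = 4, N = 8000, n_lead = 2000, beta0 = -2, gamma0 = -0.5)
#' st <- run_study(setting, n_replicates = 5, seed = 3)
#' summary(st)
#' }
#' @export
run_study <- function(setting, n_replicates, seed = 1L, progress = FALSE) {
  stopifnot(n_replicates >= 2)
  reps <- vector("list", n_replicates)
  realized <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- run_replicate(setting, r, seed)
    realized[[r]] <- attr(reps[[r]], "realized")
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  estimates <- dplyr::bind_rows(reps)
  structure(
    list(setting = tibble::as_tibble(setting_params(setting)[
           c("K", "N", "n_lead", "n_collab", "beta0", "gamma0")]),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         estimates = estimates,
         summary = summarise_study(estimates),
         realized = dplyr::bind_rows(realized),
         failures = study_failures(estimates)),
    class = "odah_study")
}

study_failures <- function(estimates) {
  estimates |>
    dplyr::distinct(.data$replicate, .data$method, .data$component,
                    .data$converged) |>
    dplyr::group_by(.data$method, .data$component) |>
    dplyr::summarise(n_fail = sum(!.data$converged), .groups = "drop")
}

# Per-method bias summaries against pooled, over converged pairs.
summarise_study <- function(estimates) {
  ok <- estimates |>
    dplyr::filter(.data$converged, is.finite(.data$estimate))
  pooled <- ok |>
    dplyr::filter(.data$method == "pooled") |>
    dplyr::select("replicate", "component", "term",
                  pooled_estimate = "estimate")
  denom <- pooled |>
    dplyr::group_by(.data$component, .data$term) |>
    dplyr::summarise(pooled_mean = mean(.data$pooled_estimate),
                     .groups = "drop")
  ok |>
    dplyr::inner_join(pooled, by = c("replicate", "component", "term")) |>
    dplyr::inner_join(denom, by = c("component", "term")) |>
    dplyr::group_by(.data$method, .data$component, .data$term) |>
    dplyr::summarise(
      n_ok = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      mc_se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      rel_bias_pct = 100 * mean(.data$estimate - .data$pooled_estimate) /
        abs(.data$pooled_mean[1]),
      rel_bias_mc_se = 100 *
        stats::sd(.data$estimate - .data$pooled_estimate) /
        (abs(.data$pooled_mean[1]) * sqrt(dplyr::n())),
      median_rel_dev_pct = stats::median(
        100 * (.data$estimate - .data$pooled_estimate) /
          abs(.data$pooled_estimate)),
      .groups = "drop")
}

#' @export
print.odah_study <- function(x, ...) {
  cat(sprintf(
    "<odah_study> %d replicates, K = %d, N = %d, n_lead = %d, beta0 = %g, gamma0 = %g\n",
    x$n_replicates, x$setting$K, x$setting$N, x$setting$n_lead,
    x$setting$beta0, x$setting$gamma0))
  cat(sprintf("realized marginal prevalence %.3f%%, event rate %.5f\n",
              100 * mean(x$realized$prevalence), mean(x$realized$event_rate)))
  print(x$summary, ...)
  invisible(x)
}

#' Summarize a simulation study
#'
#' @param object An `odah_study`.
#' @param ... Unused.
#' @return The study's summary tibble (see [run_study()]).
#' @export
summary.odah_study <- function(object, ...) object$summary

#' Extract the headline bias metric of a study
#'
#' Returns the bias-vs-pooled statistic the study design reports: the mean
#' relative bias for `meta` and `odah`, and the median per-replicate
#' relative deviation for `lead` (whose mean is distorted by outlying
#' rare-event fits).
#'
#' @param study An `odah_study`.
#' @param method One of `"meta"`, `"odah"`, `"lead"`.
#' @param component `"ztp"` or `"logistic"`.
#' @param term Coefficient name (default the binary covariate of interest).
#' @return A single relative bias in percent.
#' @export
study_bias <- function(study, method, component = "ztp", term = "x2") {
  stopifnot(inherits(study, "odah_study"))
  row <- dplyr::filter(study$summary, .data$method == !!method,
                       .data$component == !!component, .data$term == !!term)
  if (nrow(row) != 1) {
    stop("no unique summary row for the requested coefficient", call. = FALSE)
  }
  if (method == "lead") row$median_rel_dev_pct else row$rel_bias_pct
}

#' Plot the estimate distributions of a simulation study
#'
#' Boxplots of the per-replicate coefficient estimates by method, with a
#' horizontal line at the true value — the study's standard display for
#' comparing distributed estimators against the pooled gold standard.
#'
#' @param object An `odah_study`.
#' @param component,term Coefficient to display.
#' @param truth Optional true value for the reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odah_study
#' @export
autoplot.odah_study <- function(object, component = "ztp", term = "x2",
                                truth = NULL, ...) {
  dat <- object$estimates |>
    dplyr::filter(.data$component == !!component, .data$term == !!term,
                  .data$converged, is.finite(.data$estimate)) |>
    dplyr::mutate(method = factor(.data$method,
                                  c("pooled", "odah", "meta", "lead")))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$method,
                                         y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(
      x = NULL, y = sprintf("estimate of %s (%s component)", term, component),
      title = sprintf("K = %d, N = %d, n_lead = %d",
                      object$setting$K, object$setting$N,
                      object$setting$n_lead)) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_hline(yintercept = truth, colour = "steelblue")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
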