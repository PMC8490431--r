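# File exchange for the two-round protocol. All inter-site traffic is
# directory-based JSON, one file per site per round, serialized at full
# double precision; site patient data travel as headered CSV. Message
# readers validate structure before any computation.

write_json_full <- function(x, path) {
  # 17 significant digits: exact double round trip
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
}

read_json_msg <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

require_fields <- function(msg, fields, what, path) {
  miss <- setdiff(fields, names(msg))
  if (length(miss)) {
    stop(sprintf("%s message '%s' is missing field(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

num_vec <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  as.numeric(x)
}

num_mat <- function(x, d, what) {
  m <- as.matrix(x)
  if (!is.numeric(m) || nrow(m) != d || ncol(m) != d) {
    stop(what, " must be a ", d, "x", d, " numeric matrix", call. = FALSE)
  }
  storage.mode(m) <- "double"
  unname(m)
}

#' Read and write site patient-level CSV files
#'
#' CSV dialect: comma-separated, header mandatory, UTF-8, no index column.
#' Counts must be integer-valued (integral doubles such as `2.0` are
#' accepted). The site label defaults to the file name.
#'
#' @param path CSV file path.
#' @param config An [analysis_config()] (controls outcome/covariate columns).
#' @return `read_site_csv()`: a `hurdle_data`; `write_site_csv()`: `path`,
#'   invisibly.
#' @export
read_site_csv <- function(path, config = analysis_config()) {
  df <- utils::read.csv(path, check.names = FALSE)
  hurdle_data(df, outcome = config$outcome_column,
              logistic_covariates = config$logistic_covariates,
              ztp_covariates = config$ztp_covariates,
              site_id = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_site_csv
#' @param data A data frame with the outcome and covariate columns.
#' @export
write_site_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Settings shared by every site of one analysis: which columns to model
#' (all institutions must analyze the exact same set of variables), how to
#' initialize ODAH, and optimizer controls.
#'
#' @param outcome_column Count outcome column name.
#' @param logistic_covariates,ztp_covariates Covariate column names per
#'   component (`NULL`: all non-outcome columns, file order).
#' @param initializer `"meta"` or `"lead"`.
#' @param lead_site Site id of the lead site (used by `initializer =
#'   "lead"` and by [cmd_solve()] reporting).
#' @param tol,max_iter Newton controls.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(outcome_column = "y",
                            logistic_covariates = NULL,
                            ztp_covariates = NULL,
                            initializer = c("meta", "lead"),
                            lead_site = NULL,
                            tol = 1e-8, max_iter = 100L) {
  structure(
    list(outcome_column = outcome_column,
         logistic_covariates = logistic_covariates,
         ztp_covariates = ztp_covariates,
         initializer = match.arg(initializer),
         lead_site = lead_site, tol = tol, max_iter = as.integer(max_iter)),
    class = "analysis_config")
}

#' @rdname analysis_config
#' @param path JSON file with any subset of the configuration fields.
#' @export
read_analysis_config <- function(path) {
  raw <- read_json_msg(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, raw)
}

## ---- round-1 summary messages -------------------------------------------

#' Serialize protocol messages as JSON
#'
#' One file per site per round. Summary messages carry `site_id`, sample
#' sizes, coefficient estimates, per-coefficient variances, term names and
#' convergence flags; gradient messages carry the average-scale first- and
#' second-order derivative blocks and the initial estimates they were
#' evaluated at. Numbers are written at full double precision, so a write/
#' read round trip is exact.
#'
#' @param x The object to write ([site_summary()], [compute_gradients()]
#'   payload, or `odah_init`).
#' @param path Output JSON path.
#' @return `path`, invisibly (writers); the reconstructed object (readers).
#' @export
write_site_summary <- function(x, path) {
  stopifnot(inherits(x, "site_summary"))
  msg <- list(
    message = "summary", site_id = x$site_id, n = x$n, n_pos = x$n_pos,
    terms_logistic = names(x$beta_hat), terms_ztp = names(x$gamma_hat),
    beta_hat = unname(x$beta_hat), gamma_hat = unname(x$gamma_hat),
    beta_var = unname(x$beta_var_diag), gamma_var = unname(x$gamma_var_diag),
    logistic_converged = x$logistic_converged,
    ztp_converged = x$ztp_converged)
  write_json_full(msg, path)
  invisible(path)
}

#' @rdname write_site_summary
#' @export
read_site_summary <- function(path) {
  msg <- read_json_msg(path)
  require_fields(msg, c("site_id", "n", "beta_hat", "gamma_hat", "beta_var",
                        "gamma_var"), "summary", path)
  beta <- num_vec(msg$beta_hat, "beta_hat")
  gamma <- num_vec(msg$gamma_hat, "gamma_hat")
  if (!is.null(msg$terms_logistic)) names(beta) <- msg$terms_logistic
  if (!is.null(msg$terms_ztp)) names(gamma) <- msg$terms_ztp
  structure(
    list(site_id = msg$site_id, n = as.integer(msg$n),
         n_pos = as.integer(msg$n_pos %||% NA),
         beta_hat = beta, gamma_hat = gamma,
         beta_var_diag = num_vec(msg$beta_var, "beta_var"),
         gamma_var_diag = num_vec(msg$gamma_var, "gamma_var"),
         logistic_converged = isTRUE(msg$logistic_converged %||% TRUE),
         ztp_converged = isTRUE(msg$ztp_converged %||% TRUE)),
    class = "site_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- initial-estimate broadcast -----------------------------------------

#' @rdname write_site_summary
#' @export
write_initial_estimates <- function(x, path) {
  stopifnot(inherits(x, "odah_init"))
  write_json_full(
    list(message = "initial_estimates", source = x$source,
         terms_logistic = names(x$beta_bar), terms_ztp = names(x$gamma_bar),
         beta_bar = unname(x$beta_bar), gamma_bar = unname(x$gamma_bar)),
    path)
  invisible(path)
}

#' @rdname write_site_summary
#' @export
read_initial_estimates <- function(path) {
  msg <- read_json_msg(path)
  require_fields(msg, c("beta_bar", "gamma_bar", "source"),
                 "initial-estimates", path)
  beta <- num_vec(msg$beta_bar, "beta_bar")
  gamma <- num_vec(msg$gamma_bar, "gamma_bar")
  if (!is.null(msg$terms_logistic)) names(beta) <- msg$terms_logistic
  if (!is.null(msg$terms_ztp)) names(gamma) <- msg$terms_ztp
  structure(list(beta_bar = beta, gamma_bar = gamma, source = msg$source),
            class = "odah_init")
}

## ---- round-2 gradient messages ------------------------------------------

#' @rdname write_site_summary
#' @export
write_gradient_payload <- function(x, path) {
  stopifnot(inherits(x, "gradient_payload"))
  msg <- list(
    message = "gradient", site_id = x$site_id, n = x$n, n_pos = x$n_pos,
    evaluated_at = list(source = x$evaluated_at$source,
                        beta_bar = unname(x$evaluated_at$beta_bar),
                        gamma_bar = unname(x$evaluated_at$gamma_bar)),
    grad1_logistic = unname(x$grad1_logistic),
    hess_logistic = unname(x$hess_logistic),
    grad1_ztp = if (is.null(x$grad1_ztp)) NULL else unname(x$grad1_ztp),
    hess_ztp = if (is.null(x$hess_ztp)) NULL else unname(x$hess_ztp))
  write_json_full(msg, path)
  invisible(path)
}

#' @rdname write_site_summary
#' @export
read_gradient_payload <- function(path) {
  msg <- read_json_msg(path)
  require_fields(msg, c("site_id", "n", "n_pos", "evaluated_at",
                        "grad1_logistic", "hess_logistic"), "gradient", path)
  require_fields(msg$evaluated_at, c("beta_bar", "gamma_bar"),
                 "gradient evaluated_at", path)
  p <- length(msg$grad1_logistic)
  init <- structure(
    list(beta_bar = num_vec(msg$evaluated_at$beta_bar, "beta_bar"),
         gamma_bar = num_vec(msg$evaluated_at$gamma_bar, "gamma_bar"),
         source = msg$evaluated_at$source %||% "meta"),
    class = "odah_init")
  out <- list(
    site_id = msg$site_id, n = as.integer(msg$n),
    n_pos = as.integer(msg$n_pos), evaluated_at = init,
    grad1_logistic = num_vec(msg$grad1_logistic, "grad1_logistic"),
    hess_logistic = num_mat(msg$hess_logistic, p, "hess_logistic"),
    grad1_ztp = NULL, hess_ztp = NULL)
  if (!is.null(msg$grad1_ztp)) {
    q <- length(msg$grad1_ztp)
    out$grad1_ztp <- num_vec(msg$grad1_ztp, "grad1_ztp")
    out$hess_ztp <- num_mat(msg$hess_ztp, q, "hess_ztp")
  }
  structure(out, class = "gradient_payload")
}

## ---- command layer -------------------------------------------------------

log_msg <- function(...) message(sprintf(...))

#' Materialize a simulation scenario as per-site CSV files
#'
#' Writes one CSV per site plus `manifest.json` recording the true
#' parameters, seeds and site sizes — everything needed to reproduce or
#' audit the files.
#'
#' @param scenario A scenario list or JSON path with fields `K`, `N`,
#'   `n_lead`, `beta0`, `gamma0` (optional slopes `beta1`, `beta2`,
#'   `gamma1`, `gamma2`) and `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
cmd_simulate <- function(scenario, out_dir) {
  if (is.character(scenario)) scenario <- read_json_msg(scenario)
  seed <- scenario$seed %||% 1L
  s <- setting_params(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sites <- simulate_sites(s, seed)
  files <- character(length(sites))
  for (j in seq_along(sites)) {
    files[j] <- file.path(out_dir, sprintf("site%02d.csv", j))
    write_site_csv(sites[[j]], files[j])
  }
  manifest <- list(
    K = s$K, N = s$N, n_lead = s$n_lead, n_collab = s$n_collab,
    seed = seed, site_seeds = vapply(seq_len(s$K), derive_seed, 1L,
                                     seed = seed),
    truth = list(beta = s$beta, gamma = s$gamma),
    files = basename(files), lead_site = "site01")
  write_json_full(manifest, file.path(out_dir, "manifest.json"))
  log_msg("simulated %d sites (N = %d) under seed %d into %s", s$K, s$N,
          seed, out_dir)
  invisible(manifest)
}

#' Site-side step: fit locally and write the round-1 summary
#'
#' @param csv_path Site patient-level CSV.
#' @param out_path Output summary JSON.
#' @param config An [analysis_config()].
#' @return Invisibly, the `site_summary`.
#' @export
cmd_fit_local <- function(csv_path, out_path, config = analysis_config()) {
  data <- read_site_csv(csv_path, config)
  fit <- suppressWarnings(fit_hurdle(data, tol = config$tol,
                                     max_iter = config$max_iter))
  s <- site_summary(fit)
  write_site_summary(s, out_path)
  log_msg("site '%s': n = %d, converged = %s -> %s", s$site_id, s$n,
          fit$converged, out_path)
  invisible(s)
}

#' Coordinator step: combine round-1 summaries into initial estimates
#'
#' With `initializer = "meta"`, applies the fixed-effects meta-analysis to
#' every converged summary in `summaries_dir`; with `"lead"`, broadcasts
#' the lead site's own estimates (taken from its summary file), skipping
#' the combination.
#'
#' @param summaries_dir Directory of round-1 summary JSON files.
#' @param out_path Output initial-estimates JSON.
#' @param config An [analysis_config()].
#' @return Invisibly, the `odah_init`.
#' @export
cmd_init <- function(summaries_dir, out_path, config = analysis_config()) {
  paths <- list.files(summaries_dir, "\\.json$", full.names = TRUE)
  summaries <- lapply(paths, read_site_summary)
  if (!length(summaries)) stop("no summary messages found", call. = FALSE)
  init <- if (config$initializer == "lead") {
    lead_id <- config$lead_site %||% summaries[[1]]$site_id
    s <- summaries[[match(lead_id, vapply(summaries, `[[`, "", "site_id"))]]
    if (is.null(s)) stop("lead site summary not found", call. = FALSE)
    if (!s$logistic_converged || !s$ztp_converged) {
      stop("lead-site fit did not converge; cannot initialize from it",
           call. = FALSE)
    }
    structure(list(beta_bar = s$beta_hat, gamma_bar = s$gamma_hat,
                   source = "lead"), class = "odah_init")
  } else {
    withCallingHandlers(
      meta_initialize(summaries),
      warning = function(w) {
        log_msg("%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  write_initial_estimates(init, out_path)
  log_msg("initial estimates (%s) from %d summaries -> %s", init$source,
          length(summaries), out_path)
  invisible(init)
}

#' Site-side step: evaluate gradients at the broadcast initial estimates
#'
#' @param csv_path Site patient-level CSV.
#' @param init_path Initial-estimates JSON from [cmd_init()].
#' @param out_path Output gradient-payload JSON.
#' @param config An [analysis_config()].
#' @return Invisibly, the `gradient_payload`.
#' @export
cmd_gradients <- function(csv_path, init_path, out_path,
                          config = analysis_config()) {
  data <- read_site_csv(csv_path, config)
  init <- read_initial_estimates(init_path)
  payload <- compute_gradients(data, init)
  write_gradient_payload(payload, out_path)
  log_msg("site '%s': gradients at %s estimates -> %s", payload$site_id,
          init$source, out_path)
  invisible(payload)
}

#' Lead-site step: aggregate payloads and solve the surrogate
#'
#' Prints a human-readable report (coefficients, standard errors and 95%
#' Wald intervals) and writes the full result as JSON.
#'
#' @param lead_csv Lead site's patient-level CSV.
#' @param payloads_dir Directory of gradient-payload JSON files (all sites,
#'   lead included).
#' @param out_path Output result JSON.
#' @param config An [analysis_config()].
#' @return Invisibly, the `odah_fit`.
#' @export
cmd_solve <- function(lead_csv, payloads_dir, out_path,
                      config = analysis_config()) {
  lead <- read_site_csv(lead_csv, config)
  paths <- list.files(payloads_dir, "\\.json$", full.names = TRUE)
  payloads <- lapply(paths, read_gradient_payload)
  agg <- aggregate_gradients(payloads)
  fit <- odah_solve(lead, agg, tol = config$tol,
                    max_iter = config$max_iter)
  tbl <- tidy(fit)
  tbl$conf.low <- tbl$estimate - 1.96 * tbl$std.error
  tbl$conf.high <- tbl$estimate + 1.96 * tbl$std.error
  cat(sprintf("ODAH estimates (K = %d, N = %d, %d positive)\n",
              fit$K, fit$N, fit$N_pos))
  print(as.data.frame(tbl), digits = 4, row.names = FALSE)
  write_json_full(
    list(message = "odah_result", K = fit$K, N = fit$N, N_pos = fit$N_pos,
         init_source = fit$initial$source, converged = fit$converged,
         terms_logistic = names(fit$params$beta),
         terms_ztp = names(fit$params$gamma),
         beta = unname(fit$params$beta), gamma = unname(fit$params$gamma),
         beta_var = unname(fit$beta_var), gamma_var = unname(fit$gamma_var),
         surrogate_loglik_logistic = fit$surrogate_loglik_logistic,
         surrogate_loglik_ztp = fit$surrogate_loglik_ztp),
    out_path)
  log_msg("ODAH solved from %d payloads -> %s", length(payloads), out_path)
  invisible(fit)
}

#' End-to-end step: run a replicated simulation study from a scenario file
#'
#' @param scenario Scenario list or JSON path (as [cmd_simulate()], plus
#'   optional `n_replicates`).
#' @param out_csv Tidy study-summary CSV (setting, method, component, term,
#'   statistic columns); a provenance JSON with seeds, replicate and
#'   failure counts is written next to it.
#' @param n_replicates,seed Override the scenario's values.
#' @return Invisibly, the `odah_study`.
#' @export
cmd_study <- function(scenario, out_csv, n_replicates = NULL, seed = NULL) {
  if (is.character(scenario)) scenario <- read_json_msg(scenario)
  n_replicates <- n_replicates %||% scenario$n_replicates %||% 100L
  seed <- seed %||% scenario$seed %||% 1L
  study <- run_study(scenario, n_replicates = n_replicates, seed = seed)
  utils::write.csv(
    cbind(beta0 = study$setting$beta0, gamma0 = study$setting$gamma0,
          n_lead = study$setting$n_lead, study$summary),
    out_csv, row.names = FALSE)
  write_json_full(
    list(message = "study_provenance", seed = seed,
         n_replicates = n_replicates,
         setting = as.list(study$setting),
         realized_prevalence = mean(study$realized$prevalence),
         realized_event_rate = mean(study$realized$event_rate),
         failures = study$failures),
    sub("\\.csv$", "_provenance.json", out_csv))
  log_msg("study (%d replicates, seed %d) -> %s", n_replicates, seed,
          out_csv)
  invisible(study)
}
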