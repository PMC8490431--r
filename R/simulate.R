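# Synthetic multi-site generator for rare-event zero-inflated counts.
# Covariates emulate the EHR structure of a pediatric avoidable-
# hospitalization cohort: a continuous utilization-style covariate
# (truncated normal) and a binary insurance-style covariate (Bernoulli).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate seed stream; exact in double arithmetic and
# always below 2^31 - 1.
derive_seed <- function(seed, replicate) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + replicate) %%
               2147483647)
}

#' Simulate patient covariates
#'
#' `x1` is drawn from a Normal(3, sd 2) truncated to (0, 18) by inverse-CDF
#' sampling (a primary-care-visits-per-year style covariate); `x2` is
#' Bernoulli(0.33) (a public-insurance style covariate).
#'
#' @param n Number of rows.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return A tibble with columns `x1`, `x2`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  stopifnot(n > 0)
  with_seed(seed, {
    lo <- stats::pnorm(0, 3, 2)
    hi <- stats::pnorm(18, 3, 2)
    tibble::tibble(
      x1 = stats::qnorm(lo + stats::runif(n) * (hi - lo), 3, 2),
      x2 = stats::rbinom(n, 1L, 0.33))
  })
}

#' Simulate hurdle counts given covariates
#'
#' Draws `w_i ~ Bernoulli(expit(x_i'beta))`; rows with `w_i = 0` get
#' `y_i = 0`, rows with `w_i = 1` get a zero-truncated Poisson draw with
#' `lam_i = exp(z_i'gamma)` by conditional inverse-CDF sampling
#' (`u ~ Uniform(exp(-lam), 1)` inverted through the Poisson CDF).
#'
#' @param covariates Data frame of covariates; an intercept is prepended.
#' @param beta,gamma Coefficient vectors of length `ncol(covariates) + 1`
#'   (intercept first) for the logistic and ZTP components.
#' @inheritParams simulate_covariates
#' @return Integer count vector of length `nrow(covariates)`.
#' @export
simulate_outcome <- function(covariates, beta, gamma, seed = NULL) {
  M <- cbind(1, as.matrix(covariates))
  stopifnot(length(beta) == ncol(M), length(gamma) == ncol(M))
  with_seed(seed, {
    n <- nrow(M)
    pi <- stats::plogis(drop(M %*% beta))
    w <- stats::runif(n) < pi
    y <- integer(n)
    if (any(w)) {
      lam <- exp(drop(M[w, , drop = FALSE] %*% gamma))
      u <- exp(-lam) + stats::runif(sum(w)) * (-expm1(-lam))
      # u may round to 1 when lam is tiny; qpois(1, lam) = Inf
      u <- pmin(u, 1 - 1e-16)
      y[w] <- as.integer(pmax(1, stats::qpois(u, lam)))
    }
    y
  })
}

#' Simulate one site's patient-level table
#'
#' @param n Site sample size.
#' @inheritParams simulate_outcome
#' @param seed Integer seed (the covariate and outcome draws share it).
#' @param site_id Site label, stored as attribute `site_id`.
#' @return A tibble with columns `y`, `x1`, `x2`, ready for [hurdle_data()].
#' @examples
#' df <- simulate_site(2000, beta = c(-2, -1, 1), gamma = c(0.5, -1, 1),
#'                     seed = 42)
#' table(df$y)
#' @export
simulate_site <- function(n, beta, gamma, seed = NULL, site_id = "site") {
  df <- with_seed(seed, {
    covars <- simulate_covariates(n)
    covars$y <- simulate_outcome(covars, beta, gamma)
    covars
  })
  df <- df[c("y", "x1", "x2")]
  attr(df, "site_id") <- site_id
  df
}

#' The ten simulation settings of the reference design
#'
#' Ten multi-site scenarios over a 10-site network of 200,000 patients:
#' four baseline-prevalence levels (5%, 2.5%, 1%, 0.5% at baseline event
#' rate 0.03), three additional baseline event rates (0.25, 0.01, 0.005 at
#' 2.5% baseline prevalence), and three enlarged lead-site sizes (38,000;
#' 56,000; 74,000). Intercepts are the logit/log of the baseline labels;
#' slopes are (-1, 1) in both components. The nominal labels describe
#' prevalence and event rate at covariates equal to zero; realized marginal
#' rates under the covariate distribution are lower, and [run_study()]
#' records them.
#'
#' @return A tibble with one row per setting: `setting`, `prevalence_label`,
#'   `lambda_label`, `K`, `N`, `n_lead`, `n_collab`, `beta0`, `gamma0`,
#'   `beta1`, `beta2`, `gamma1`, `gamma2`.
#' @export
reference_settings <- function() {
  s <- tibble::tribble(
    ~prevalence_label, ~lambda_label, ~n_lead, ~beta0, ~gamma0,
    5,    0.03,  20000L, -3.0, -3.6,
    2.5,  0.03,  20000L, -3.7, -3.6,
    1,    0.03,  20000L, -4.5, -3.6,
    0.5,  0.03,  20000L, -5.3, -3.6,
    2.5,  0.25,  20000L, -3.7, -1.4,
    2.5,  0.01,  20000L, -3.7, -4.5,
    2.5,  0.005, 20000L, -3.7, -5.3,
    2.5,  0.03,  38000L, -3.7, -3.6,
    2.5,  0.03,  56000L, -3.7, -3.6,
    2.5,  0.03,  74000L, -3.7, -3.6)
  s$setting <- sprintf("S%02d", seq_len(nrow(s)))
  s$K <- 10L
  s$N <- 200000L
  s$n_collab <- as.integer((s$N - s$n_lead) / (s$K - 1L))
  s$beta1 <- -1; s$beta2 <- 1; s$gamma1 <- -1; s$gamma2 <- 1
  s[c("setting", "prevalence_label", "lambda_label", "K", "N", "n_lead",
      "n_collab", "beta0", "gamma0", "beta1", "beta2", "gamma1", "gamma2")]
}

setting_params <- function(setting) {
  setting <- as.list(setting)
  need <- c("K", "N", "n_lead", "beta0", "gamma0")
  if (!all(need %in% names(setting))) {
    stop("setting must provide ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(setting$beta1)) setting$beta1 <- -1
  if (is.null(setting$beta2)) setting$beta2 <- 1
  if (is.null(setting$gamma1)) setting$gamma1 <- -1
  if (is.null(setting$gamma2)) setting$gamma2 <- 1
  if (is.null(setting$n_collab)) {
    setting$n_collab <- (setting$N - setting$n_lead) / (setting$K - 1)
  }
  stopifnot(setting$n_lead + (setting$K - 1) * setting$n_collab == setting$N)
  setting$beta <- c(setting$beta0, setting$beta1, setting$beta2)
  setting$gamma <- c(setting$gamma0, setting$gamma1, setting$gamma2)
  setting
}

# Generate the K site tables of one replicate (site 1 is the lead site).
simulate_sites <- function(setting, seed) {
  s <- setting_params(setting)
  sizes <- c(s$n_lead, rep(s$n_collab, s$K - 1))
  lapply(seq_len(s$K), function(j) {
    simulate_site(sizes[j], s$beta, s$gamma,
                  seed = derive_seed(seed, j),
                  site_id = sprintf("site%02d", j))
  })
}
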