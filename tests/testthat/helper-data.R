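# Shared fixtures and oracles, all built in code.

# report the whole suite even when several acceptance criteria are red
options(testthat.progress.max_fails = Inf)

# A small, well-behaved hurdle dataset (moderate prevalence and event rate
# so every component has information).
make_data <- function(n = 400, beta = c(-0.5, -0.6, 0.8),
                      gamma = c(0.4, -0.3, 0.5), seed = 1,
                      site_id = "test") {
  hurdle_data(simulate_site(n, beta, gamma, seed = seed), site_id = site_id)
}

# Random coefficients near zero for derivative checks.
rand_coef <- function(p, seed) {
  set.seed(seed)
  stats::runif(p, -0.8, 0.8)
}

# Central finite-difference gradient of scalar-valued f at x.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Central finite-difference Jacobian of vector-valued g at x.
fd_jacobian <- function(g, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (g(x + e) - g(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1, max(abs(b)))
}

# Independent ZTP log-likelihood oracle built on stats::dpois only
# (dpois already carries the -log(y!) term).
ztp_loglik_oracle <- function(gamma, data) {
  pos <- data$y > 0
  lam <- exp(drop(data$Z[pos, , drop = FALSE] %*% gamma))
  sum(stats::dpois(data$y[pos], lam, log = TRUE) - log(1 - exp(-lam)))
}
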