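#' Assemble one site's patient-level data for hurdle regression
#'
#' Bundles a count outcome with the design matrices of the two hurdle-model
#' components: a logistic component for the zero/positive indicator and a
#' zero-truncated Poisson (ZTP) component for the magnitude of positive
#' counts. The binary response of the logistic component is never stored; it
#' is always recomputed as `y > 0`.
#'
#' @param data A data frame with one row per patient.
#' @param outcome Name of the count-outcome column. Values must be
#'   non-negative and integer-valued (integral doubles such as `2.0` are
#'   accepted).
#' @param logistic_covariates,ztp_covariates Character vectors of covariate
#'   column names for each component, in design-matrix order. Default: all
#'   non-outcome columns, in file order, for both components. An intercept
#'   column is always prepended.
#' @param site_id Site label stored with the data.
#'
#' @return A `hurdle_data` object: a list with elements `y` (integer vector),
#'   `X` and `Z` (design matrices with leading intercept column) and
#'   `site_id`.
#' @examples
#' df <- simulate_site(500, beta = c(-1, -1, 1), gamma = c(0.2, -1, 1),
#'                     seed = 1)
#' hd <- hurdle_data(df)
#' hd
#' @export
hurdle_data <- function(data, outcome = "y",
                        logistic_covariates = NULL,
                        ztp_covariates = NULL,
                        site_id = "site") {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  y <- data[[outcome]]
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
      any(abs(y - round(y)) > 1e-8)) {
    stop("outcome must be a non-negative integer count", call. = FALSE)
  }
  y <- as.integer(round(y))
  covars <- setdiff(names(data), outcome)
  if (is.null(logistic_covariates)) logistic_covariates <- covars
  if (is.null(ztp_covariates)) ztp_covariates <- covars
  miss <- setdiff(union(logistic_covariates, ztp_covariates), names(data))
  if (length(miss)) {
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design <- function(cols) {
    m <- cbind(`(Intercept)` = 1, as.matrix(data[cols]))
    storage.mode(m) <- "double"
    m
  }
  structure(
    list(y = y, X = design(logistic_covariates), Z = design(ztp_covariates),
         site_id = as.character(site_id)),
    class = "hurdle_data"
  )
}

#' @export
print.hurdle_data <- function(x, ...) {
  cat(sprintf(
    "<hurdle_data> site '%s': n = %d, positives = %d (%.2f%%), p = %d, q = %d\n",
    x$site_id, length(x$y), sum(x$y > 0), 100 * mean(x$y > 0),
    ncol(x$X), ncol(x$Z)))
  invisible(x)
}

#' @export
dim.hurdle_data <- function(x) c(length(x$y), ncol(x$X), ncol(x$Z))

as_hurdle_data <- function(data, ...) {
  if (inherits(data, "hurdle_data")) data else hurdle_data(data, ...)
}

# Concatenate sites row-wise; used by the pooled estimator.
bind_hurdle_data <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  datasets <- lapply(datasets, as_hurdle_data)
  p <- vapply(datasets, function(d) ncol(d$X), 1L)
  q <- vapply(datasets, function(d) ncol(d$Z), 1L)
  if (length(unique(p)) != 1L || length(unique(q)) != 1L) {
    stop("sites have differing design dimensions", call. = FALSE)
  }
  structure(
    list(y = unlist(lapply(datasets, `[[`, "y"), use.names = FALSE),
         X = do.call(rbind, lapply(datasets, `[[`, "X")),
         Z = do.call(rbind, lapply(datasets, `[[`, "Z")),
         site_id = paste(vapply(datasets, `[[`, "", "site_id"),
                         collapse = "+")),
    class = "hurdle_data"
  )
}
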