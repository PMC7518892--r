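#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the fitted strand-bias beta prior
#'
#' @param x a `cf_beta_prior`.
#' @param ... unused.
#' @return One row per hyperparameter: `term`, `estimate`.
#' @export
tidy.cf_beta_prior <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' One-row summary of the fitted beta prior
#'
#' @param x a `cf_beta_prior`.
#' @param ... unused.
#' @return A one-row tibble with the hyperparameters, the implied mean
#'   (+)-strand fraction, the number of informing repeat units and the
#'   log-likelihood.
#' @export
glance.cf_beta_prior <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta,
         mean_plus_fraction = x$alpha / (x$alpha + x$beta),
         n_units = x$n_units, logLik = x$loglik)
}

#' Tidy a strand-bias test result
#'
#' @param x a `cf_strand_bias` table from [strand_bias_test()].
#' @param ... unused.
#' @return The per-unit results as a plain tibble.
#' @export
tidy.cf_strand_bias <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cf_strand_bias")
  attr(out, "prior") <- NULL
  as_tibble(out)
}

#' One-row summary of a strand-bias test
#'
#' @param x a `cf_strand_bias` table.
#' @param ... unused.
#' @return A one-row tibble: units tested, units flagged significant, the
#'   decision thresholds and the prior hyperparameters.
#' @export
glance.cf_strand_bias <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble(n_units = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         delta_min = attr(x, "delta_min"),
         bf_threshold = attr(x, "bf_threshold"),
         prior_alpha = prior$alpha, prior_beta = prior$beta)
}

#' Tidy an enrichment test's null distribution
#'
#' @param x a `cf_enrichment`.
#' @param ... unused.
#' @return One row per null set: `set`, `null_value`.
#' @export
tidy.cf_enrichment <- function(x, ...) {
  tibble(set = seq_along(x$null_values), null_value = x$null_values)
}

#' One-row summary of an enrichment test
#'
#' @param x a `cf_enrichment`.
#' @param ... unused.
#' @return A one-row tibble: statistic name, observed value, null mean and
#'   SD, number of sets, tail, empirical p.
#' @export
glance.cf_enrichment <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         null_mean = mean(x$null_values), null_sd = stats::sd(x$null_values),
         n_sets = x$n_sets, tail = x$tail, empirical_p = x$empirical_p)
}
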