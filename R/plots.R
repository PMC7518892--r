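#' @import ggplot2
NULL

#' Plot an enrichment test: null distribution and observed statistic
#'
#' @param object a `cf_enrichment` from [rbp_enrichment_test()] or
#'   [mfe_enrichment_test()].
#' @param ... unused.
#' @return A ggplot: histogram of the null values with the observed value
#'   as a dashed line and the empirical p in the subtitle.
#' @export
autoplot.cf_enrichment <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_value)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    geom_vline(xintercept = object$observed, linetype = "dashed",
               colour = "firebrick") +
    labs(x = object$statistic, y = "null sets",
         title = "Matched-size random-peak null",
         subtitle = sprintf("observed = %.4g; %s-tail empirical p = %.4g",
                            object$observed, object$tail,
                            object$empirical_p)) +
    theme_minimal()
}

#' Plot per-repeat strand-bias posteriors
#'
#' @param object a `cf_strand_bias` table from [strand_bias_test()].
#' @param ... unused.
#' @return A ggplot of the posterior Delta %(+) (RNA - DNA) per canonical
#'   repeat unit: median and 95% credible interval, coloured by the
#'   Bayes-factor significance call; the dotted line marks the effect-size
#'   floor.
#' @export
autoplot.cf_strand_bias <- function(object, ...) {
  d <- tidy(object) %>%
    arrange(.data$delta_median) %>%
    mutate(canonical_unit = factor(.data$canonical_unit,
                                   levels = .data$canonical_unit))
  ggplot(d, aes(x = .data$delta_median, y = .data$canonical_unit,
                colour = .data$significant)) +
    geom_vline(xintercept = attr(object, "delta_min"),
               linetype = "dotted") +
    geom_vline(xintercept = 0, colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$delta_ci_lo, xmax = .data$delta_ci_hi),
                   height = 0.25) +
    geom_point(size = 2) +
    scale_colour_manual(values = c(`FALSE` = "grey40",
                                   `TRUE` = "firebrick")) +
    labs(x = expression(Delta ~ "%(+) (RNA - DNA)"), y = NULL,
         colour = "BF > threshold") +
    theme_minimal()
}

#' Plot the empirical beta prior fit
#'
#' @param object a `cf_beta_prior` from [fit_beta_prior()].
#' @param ... unused.
#' @return A ggplot: histogram of the observed DNA (+)-strand fractions
#'   with the fitted beta density overlaid.
#' @export
autoplot.cf_beta_prior <- function(object, ...) {
  grid <- tibble(x = seq(0.001, 0.999, length.out = 400)) %>%
    mutate(density = dbeta(.data$x, object$alpha, object$beta))
  ggplot(tibble(p = object$fractions), aes(x = .data$p)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)), bins = 20,
                   fill = "grey70", colour = "grey35") +
    geom_line(data = grid, aes(x = .data$x, y = .data$density),
              colour = "firebrick") +
    labs(x = "observed %(+) fraction (plasma DNA)", y = "density",
         title = sprintf("Fitted prior Beta(%.2f, %.2f), %d repeat units",
                         object$alpha, object$beta, object$n_units)) +
    theme_minimal()
}

#' Plot a pileup track with called peaks
#'
#' @param coverage a `cf_coverage` from [build_coverage()].
#' @param chrom chromosome to plot (default: the first).
#' @param from,to 0-based plotting window (default: whole chromosome).
#' @param peaks optional peak tibble; peaks in the window are shaded.
#' @return A ggplot of the per-base pileup.
#' @export
plot_coverage <- function(coverage, chrom = NULL, from = 0L, to = NULL,
                          peaks = NULL) {
  stopifnot(inherits(coverage, "cf_coverage"))
  if (is.null(chrom)) chrom <- names(coverage$pileup)[1]
  v <- coverage$pileup[[chrom]]
  if (is.null(to)) to <- length(v)
  d <- tibble(pos = seq.int(from, to - 1L), pileup = v[(from + 1):to])
  p <- ggplot(d, aes(x = .data$pos, y = .data$pileup))
  if (!is.null(peaks)) {
    pk <- peaks %>%
      filter(.data$chrom == !!chrom, .data$end > from, .data$start < to)
    if (nrow(pk) > 0) {
      p <- p + geom_rect(data = pk, inherit.aes = FALSE,
                         aes(xmin = .data$start, xmax = .data$end,
                             ymin = 0, ymax = Inf),
                         fill = "firebrick", alpha = 0.15)
    }
  }
  p + geom_step(colour = "grey25") +
    labs(x = paste0(chrom, " position (nt)"), y = "fragment pileup",
         subtitle = paste("strand:", coverage$strand)) +
    theme_minimal()
}
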