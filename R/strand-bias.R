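#' Aggregate strand-specific fragment counts per canonical repeat unit
#'
#' Tandem-repeat units are merged with their reverse complements under a
#' canonical representative (the lexicographically smaller of the unit and
#' its reverse complement, both expressed on the genomic (+) strand). A
#' fragment's strand is flipped when its locus's unit canonicalises to the
#' reverse complement, so a (+) fragment over a locus annotated with the
#' reverse-complement unit counts toward the canonical unit's (-) tally.
#' Palindromic units (reverse complement equal to itself) merge without a
#' flip. Total counts are conserved.
#'
#' @param frags deduplicated fragment tibble for one dataset.
#' @param repeats repeat-locus tibble: `chrom`, `start`, `end`, `strand`,
#'   `unit` (the repeat unit on the annotated strand, A/C/G/T only).
#' @return A tibble: `canonical_unit`, `n_plus`, `n_minus`.
#' @export
aggregate_repeat_counts <- function(frags, repeats) {
  check_fragment_cols(frags)
  stopifnot(all(c("chrom", "start", "end", "strand", "unit") %in%
                  names(repeats)))
  if (any(grepl("[^ACGT]", repeats$unit))) {
    abort("repeat units must be over the alphabet {A,C,G,T}")
  }
  # express every unit on the genomic (+) strand, then canonicalise
  plus_unit <- if_else(repeats$strand == "-", revcomp_chr(repeats$unit),
                       repeats$unit)
  rc <- revcomp_chr(plus_unit)
  canonical <- if_else(plus_unit <= rc, plus_unit, rc)
  flip <- plus_unit > rc

  counts <- purrr::map_dfr(unique(repeats$chrom), function(ch) {
    ri <- which(repeats$chrom == ch)
    f <- frags %>% filter(.data$chrom == ch)
    if (nrow(f) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      as_iranges0(f$start, f$end),
      as_iranges0(repeats$start[ri], repeats$end[ri]))
    if (length(hits) == 0) return(NULL)
    fi <- S4Vectors::queryHits(hits)
    li <- ri[S4Vectors::subjectHits(hits)]
    plus <- (f$strand[fi] == "+") != flip[li]   # XOR with orientation flip
    tibble(canonical_unit = canonical[li], plus = plus)
  })
  if (nrow(counts) == 0) {
    return(tibble(canonical_unit = character(0), n_plus = integer(0),
                  n_minus = integer(0)))
  }
  counts %>%
    group_by(.data$canonical_unit) %>%
    summarise(n_plus = sum(.data$plus), n_minus = sum(!.data$plus),
              .groups = "drop")
}

#' Fit the empirical beta prior of (+)-strand fractions from plasma DNA
#'
#' The Empirical Bayes step: repeat units with high total counts
#' (> `min_total` deduplicated fragments, regardless of strand) in the
#' combined plasma-DNA datasets define an empirical distribution of
#' (+)-orientation fractions; a Beta(alpha, beta) population distribution is
#' fitted to them by maximum likelihood under the beta-binomial marginal of
#' the counts (method-of-moments initialisation on the observed fractions),
#' so binomial counting noise is separated from the unit-to-unit dispersion
#' rather than inflating it. The fitted beta represents how much apparent
#' strand bias a pure DNA sample shows - mapping artefacts included - and
#' becomes the prior for the per-unit posteriors.
#'
#' @param dna_counts tibble from [aggregate_repeat_counts()] on the DNA
#'   control fragments (`canonical_unit`, `n_plus`, `n_minus`).
#' @param min_total minimum total count for a unit to inform the prior.
#' @return A `cf_beta_prior` object with elements `alpha`, `beta`,
#'   `n_units`, `fractions`, `loglik`.
#' @export
fit_beta_prior <- function(dna_counts, min_total = 50L) {
  tot <- dna_counts$n_plus + dna_counts$n_minus
  keep <- tot > min_total
  if (sum(keep) < 2) {
    abort(paste0("only ", sum(keep), " repeat unit(s) exceed min_total = ",
                 min_total, "; lower min_total to fit a prior"))
  }
  k <- dna_counts$n_plus[keep]
  n <- tot[keep]
  p <- (k + 0.5) / (n + 1)

  mu <- mean(p); v <- stats::var(p)
  v <- min(max(v, 1e-6), mu * (1 - mu) * 0.999)
  k0 <- mu * (1 - mu) / v - 1            # method-of-moments concentration
  init <- log(c(mu * k0, (1 - mu) * k0))

  # marginal beta-binomial log-likelihood (binomial constant dropped)
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(lbeta(a + k, b + n - k) - lbeta(a, b))
  }
  fit <- optim(init, negll, method = "Nelder-Mead")

  structure(list(alpha = exp(fit$par[1]), beta = exp(fit$par[2]),
                 n_units = sum(keep), fractions = p,
                 loglik = -fit$value),
            class = "cf_beta_prior")
}

#' @export
print.cf_beta_prior <- function(x, ...) {
  cat(sprintf(
    "<cf_beta_prior> Beta(%.3f, %.3f) fitted to %d repeat units (mean %%(+) = %.3f)\n",
    x$alpha, x$beta, x$n_units, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Conjugate posterior of the (+)-strand fraction
#'
#' Beta-binomial update: with prior Beta(alpha, beta) and `n_plus` /
#' `n_minus` observed fragments, the posterior of the (+) fraction is
#' Beta(alpha + n_plus, beta + n_minus). With no counts the posterior equals
#' the prior.
#'
#' @param prior a `cf_beta_prior` or any list with `alpha` and `beta`.
#' @param n_plus,n_minus strand counts (>= 0).
#' @return A list with `alpha` and `beta` of the posterior.
#' @export
posterior_plus_fraction <- function(prior, n_plus, n_minus) {
  if (n_plus < 0 || n_minus < 0) abort("counts must be >= 0")
  list(alpha = prior$alpha + n_plus, beta = prior$beta + n_minus)
}

#' Posterior distribution of the RNA-vs-DNA (+)-strand difference
#'
#' Draws the (+) fraction independently from the RNA and DNA posteriors and
#' forms the difference Delta = theta_RNA - theta_DNA. The Bayes factor for
#' the interval hypothesis {Delta >= delta_min} is the posterior odds
#' divided by the prior odds, the prior odds being estimated from two
#' independent draws of the prior itself (the distribution the difference
#' would follow with no data). A unit is flagged significant when the Bayes
#' factor exceeds `bf_threshold` (default 3) for at least `delta_min`
#' (default 10 percentage points) more (+) fragments in RNA than DNA.
#'
#' @param post_rna,post_dna posterior parameter lists from
#'   [posterior_plus_fraction()].
#' @param prior the fitted `cf_beta_prior` (for the prior odds).
#' @param n_draws Monte-Carlo draws (>= 1000).
#' @param delta_min effect-size floor on Delta.
#' @param bf_threshold Bayes-factor significance threshold.
#' @return A one-row tibble: `delta_mean`, `delta_median`, `delta_ci_lo`,
#'   `delta_ci_hi` (95% credible interval), `prob_delta_ge`,
#'   `bayes_factor`, `bf_infinite`, `significant`.
#' @export
delta_distribution <- function(post_rna, post_dna, prior, n_draws = 1e5,
                               delta_min = 0.10, bf_threshold = 3) {
  if (n_draws < 1000) abort("n_draws must be >= 1000")
  for (p in list(post_rna, post_dna)) {
    if (p$alpha <= 0 || p$beta <= 0) abort("degenerate posterior parameters")
  }
  d_post <- rbeta(n_draws, post_rna$alpha, post_rna$beta) -
    rbeta(n_draws, post_dna$alpha, post_dna$beta)
  d_prior <- rbeta(n_draws, prior$alpha, prior$beta) -
    rbeta(n_draws, prior$alpha, prior$beta)

  p_post <- mean(d_post >= delta_min)
  p_prior <- mean(d_prior >= delta_min)
  odds <- function(p) if (p >= 1) Inf else p / (1 - p)
  bf_inf <- p_prior == 0
  bf <- if (bf_inf) {
    if (p_post > 0) Inf else 0
  } else {
    odds(p_post) / odds(p_prior)
  }
  ci <- unname(quantile(d_post, c(0.025, 0.975)))
  tibble(delta_mean = mean(d_post), delta_median = median(d_post),
         delta_ci_lo = ci[1], delta_ci_hi = ci[2],
         prob_delta_ge = p_post, bayes_factor = bf, bf_infinite = bf_inf,
         significant = bf > bf_threshold)
}

#' Empirical Bayes strand-bias test across repeat units
#'
#' The full pipeline: fit the beta prior from the DNA counts, form the
#' conjugate posterior of the (+) fraction per canonical unit separately for
#' the RNA and DNA counts, sample the posterior difference
#' Delta %(+) (RNA - DNA), and flag units with Bayes factor >
#' `bf_threshold` for Delta >= `delta_min`.
#'
#' @param counts tibble with `canonical_unit`, `n_plus_rna`, `n_minus_rna`,
#'   `n_plus_dna`, `n_minus_dna` (see [repeat_strand_counts()]).
#' @param min_total prior-fit total-count threshold (DNA).
#' @param hold_out_prior if TRUE, units used to fit the prior are excluded
#'   from testing; by default the DNA counts inform both the prior and the
#'   per-unit posterior.
#' @inheritParams delta_distribution
#' @param seed integer seed for the posterior sampling.
#' @return A `cf_strand_bias` tibble, one row per canonical unit, with the
#'   columns of [delta_distribution()] plus the counts; the fitted prior is
#'   attached as attribute `"prior"`.
#' @export
strand_bias_test <- function(counts, min_total = 50L, n_draws = 1e5,
                             delta_min = 0.10, bf_threshold = 3,
                             hold_out_prior = FALSE, seed = 1L) {
  need <- c("canonical_unit", "n_plus_rna", "n_minus_rna", "n_plus_dna",
            "n_minus_dna")
  stopifnot(all(need %in% names(counts)))
  prior <- fit_beta_prior(
    counts %>% select(canonical_unit = "canonical_unit",
                      n_plus = "n_plus_dna", n_minus = "n_minus_dna"),
    min_total = min_total)

  test_set <- counts
  if (hold_out_prior) {
    tot_dna <- counts$n_plus_dna + counts$n_minus_dna
    test_set <- counts[tot_dna <= min_total, ]
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  res <- purrr::map_dfr(seq_len(nrow(test_set)), function(i) {
    row <- test_set[i, ]
    post_rna <- posterior_plus_fraction(prior, row$n_plus_rna,
                                        row$n_minus_rna)
    post_dna <- posterior_plus_fraction(prior, row$n_plus_dna,
                                        row$n_minus_dna)
    delta_distribution(post_rna, post_dna, prior, n_draws = n_draws,
                       delta_min = delta_min, bf_threshold = bf_threshold) %>%
      mutate(canonical_unit = row$canonical_unit, .before = 1)
  })
  out <- test_set %>% left_join(res, by = "canonical_unit")
  attr(out, "prior") <- prior
  attr(out, "delta_min") <- delta_min
  attr(out, "bf_threshold") <- bf_threshold
  class(out) <- c("cf_strand_bias", class(out))
  out
}

#' Join RNA and DNA repeat strand counts into one test-ready table
#'
#' @param rna_counts,dna_counts tibbles from [aggregate_repeat_counts()].
#' @return A tibble with `canonical_unit` and the four count columns; units
#'   absent from one dataset get zero counts.
#' @export
repeat_strand_counts <- function(rna_counts, dna_counts) {
  dplyr::full_join(
    rna_counts %>% rename(n_plus_rna = "n_plus", n_minus_rna = "n_minus"),
    dna_counts %>% rename(n_plus_dna = "n_plus", n_minus_dna = "n_minus"),
    by = "canonical_unit") %>%
    mutate(across(dplyr::starts_with("n_"),
                  ~ tidyr::replace_na(as.integer(.x), 0L)))
}
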