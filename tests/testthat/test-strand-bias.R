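rep_locus <- function(unit, start, end, strand = "+", chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, unit = unit)
}

test_that("repeat units merge with their reverse complements under a canonical unit", {
  loci <- dplyr::bind_rows(rep_locus("CCG", 100, 200),
                           rep_locus("CGG", 1000, 1100))
  f <- dplyr::bind_rows(
    frag(start = 120, end = 180, strand = "+"),   # CCG locus, +
    frag(start = 130, end = 190, strand = "-"),   # CCG locus, -
    frag(start = 1010, end = 1080, strand = "+"), # CGG locus: flips to -
    frag(start = 1020, end = 1090, strand = "-")) # CGG locus: flips to +
  counts <- aggregate_repeat_counts(f, loci)
  expect_equal(nrow(counts), 1)
  expect_equal(counts$canonical_unit, "CCG")  # revcomp(CCG) = CGG
  expect_equal(counts$n_plus, 2L)
  expect_equal(counts$n_minus, 2L)
  # totals conserved
  expect_equal(counts$n_plus + counts$n_minus, 4L)
})

test_that("a (-)-annotated locus contributes via its plus-strand unit", {
  # unit CCG annotated on (-) means the genomic (+) strand carries CGG,
  # which canonicalises to CCG with a strand flip
  loci <- rep_locus("CCG", 100, 200, strand = "-")
  f <- frag(start = 120, end = 180, strand = "+")
  counts <- aggregate_repeat_counts(f, loci)
  expect_equal(counts$canonical_unit, "CCG")
  expect_equal(counts$n_minus, 1L)
  expect_equal(counts$n_plus, 0L)
})

test_that("palindromic units merge without a strand flip", {
  loci <- rep_locus("AT", 100, 200)
  f <- dplyr::bind_rows(frag(start = 120, end = 180, strand = "+"),
                        frag(start = 130, end = 190, strand = "-"))
  counts <- aggregate_repeat_counts(f, loci)
  expect_equal(counts$n_plus, 1L)
  expect_equal(counts$n_minus, 1L)
})

test_that("all-plus fragments over a plus locus leave the minus tally empty", {
  # AAG is its own canonical unit (revcomp CTT sorts after it)
  counts <- aggregate_repeat_counts(
    frag(start = rep(120, 5), end = rep(180, 5), strand = "+"),
    rep_locus("AAG", 100, 200))
  expect_equal(counts$n_minus, 0L)
  expect_error(aggregate_repeat_counts(frag(start = 1, end = 2),
                                       rep_locus("TTN", 0, 10)),
               "alphabet")
})

test_that("a near-symmetric low-dispersion sample fits a large symmetric prior", {
  set.seed(1)
  n <- 100
  counts <- tibble::tibble(
    canonical_unit = sprintf("u%03d", 1:n),
    n_plus = rbinom(n, 400, 0.5))
  counts$n_minus <- 400L - counts$n_plus
  prior <- fit_beta_prior(counts, min_total = 50)
  expect_equal(prior$alpha / (prior$alpha + prior$beta), 0.5,
               tolerance = 0.02)
  expect_gt(prior$alpha, 20)
  expect_equal(prior$alpha, prior$beta, tolerance = 0.25 * prior$alpha)
})

test_that("the prior fit tracks the best-achievable fit on the latent fractions", {
  skip_if_not_installed("MASS")
  # the estimator only sees binomial counts; it should agree closely with a
  # direct beta MLE on the latent per-unit fractions it cannot observe
  for (seed in 1:5) {
    set.seed(seed)
    theta <- rbeta(200, 5, 5)
    counts <- tibble::tibble(
      canonical_unit = sprintf("u%03d", 1:200),
      n_plus = rbinom(200, 500, theta))
    counts$n_minus <- 500L - counts$n_plus
    prior <- fit_beta_prior(counts, min_total = 50)
    oracle <- suppressWarnings(
      MASS::fitdistr(theta, "beta",
                     start = list(shape1 = 5, shape2 = 5))$estimate)
    expect_lt(abs(prior$alpha - oracle[["shape1"]]) / oracle[["shape1"]], 0.15,
              label = paste("alpha, seed", seed))
    expect_lt(abs(prior$beta - oracle[["shape2"]]) / oracle[["shape2"]], 0.15,
              label = paste("beta, seed", seed))
  }
  # asymmetric population: the implied mean tracks the latent mean
  for (seed in 1:5) {
    set.seed(seed)
    theta <- rbeta(200, 2, 8)
    counts <- tibble::tibble(
      canonical_unit = sprintf("u%03d", 1:200),
      n_plus = rbinom(200, 500, theta))
    counts$n_minus <- 500L - counts$n_plus
    prior <- fit_beta_prior(counts, min_total = 50)
    expect_equal(prior$alpha / (prior$alpha + prior$beta), mean(theta),
                 tolerance = 0.02 / mean(theta))
  }
})

test_that("too few qualifying repeats point the user at min_total", {
  counts <- tibble::tibble(canonical_unit = c("a", "b"),
                           n_plus = c(10L, 400L), n_minus = c(10L, 100L))
  expect_error(fit_beta_prior(counts, min_total = 50), "min_total")
})

test_that("the posterior is the conjugate beta update", {
  flat <- list(alpha = 1, beta = 1)
  post <- posterior_plus_fraction(flat, 3, 1)
  expect_equal(post$alpha, 4)
  expect_equal(post$beta, 2)
  expect_equal(post$alpha / (post$alpha + post$beta), 2 / 3)

  expect_equal(posterior_plus_fraction(list(alpha = 2.5, beta = 7), 0, 0),
               list(alpha = 2.5, beta = 7))

  post2 <- posterior_plus_fraction(list(alpha = 2, beta = 2), 8, 2)
  expect_equal(post2$alpha / (post2$alpha + post2$beta), 10 / 14)
  expect_error(posterior_plus_fraction(flat, -1, 0), ">= 0")
})

test_that("identical posteriors give a centred delta; swapping negates it", {
  prior <- list(alpha = 10, beta = 10)
  set.seed(1)
  same <- delta_distribution(list(alpha = 30, beta = 20),
                             list(alpha = 30, beta = 20), prior,
                             n_draws = 1e5)
  expect_lt(abs(same$delta_median), 0.01)
  expect_false(same$significant)

  set.seed(2)
  ab <- delta_distribution(list(alpha = 60, beta = 20),
                           list(alpha = 20, beta = 60), prior, n_draws = 2e5)
  set.seed(2)
  ba <- delta_distribution(list(alpha = 20, beta = 60),
                           list(alpha = 60, beta = 20), prior, n_draws = 2e5)
  expect_equal(ab$delta_mean, -ba$delta_mean, tolerance = 0.01)
})

test_that("a strong planted strand bias is significant", {
  prior <- list(alpha = 10, beta = 10)
  post_rna <- posterior_plus_fraction(prior, 950, 50)
  post_dna <- posterior_plus_fraction(prior, 500, 500)
  set.seed(1)
  res <- delta_distribution(post_rna, post_dna, prior, n_draws = 1e5)
  expect_true(res$significant)
  expect_gt(res$bayes_factor, 3)
  expect_gt(res$delta_mean, 0.3)
})

test_that("sampled posterior means agree with the conjugate closed form", {
  prior <- list(alpha = 4, beta = 6)
  set.seed(3)
  grid <- expand.grid(n_plus = c(0, 1, 5, 20, 200),
                      n_minus = c(0, 3, 50, 500))
  for (i in seq_len(nrow(grid))) {
    a <- prior$alpha + grid$n_plus[i]
    b <- prior$beta + grid$n_minus[i]
    draws <- rbeta(1e5, a, b)
    closed <- a / (a + b)
    se <- sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(1e5)
    expect_lt(abs(mean(draws) - closed), 3 * se)
  }
})

test_that("the end-to-end test flags the planted biased repeat and only it", {
  # null units share a latent per-unit fraction between RNA and DNA (a
  # locus-level mapping artefact looks the same in both libraries); the
  # planted unit is strand-biased in RNA only
  for (seed in 1:3) {
    set.seed(seed * 100)
    units <- c("AATGG", sprintf("u%02d", 1:10))
    null_theta <- rbeta(10, 8, 8)
    rna_theta <- c(0.95, null_theta)
    dna_theta <- c(0.5, null_theta)
    counts <- tibble::tibble(
      canonical_unit = units,
      n_plus_rna = rbinom(11, 800, rna_theta),
      n_plus_dna = rbinom(11, 800, dna_theta))
    counts$n_minus_rna <- 800L - counts$n_plus_rna
    counts$n_minus_dna <- 800L - counts$n_plus_dna
    res <- strand_bias_test(counts, n_draws = 2e4, seed = seed)
    expect_true(res$significant[res$canonical_unit == "AATGG"],
                info = paste("seed", seed))
    expect_equal(sum(res$significant), 1L, info = paste("seed", seed))
  }
})

test_that("determinism under a fixed seed and tidier contracts hold", {
  counts <- tibble::tibble(
    canonical_unit = sprintf("u%02d", 1:20),
    n_plus_rna = rbinom(20, 300, 0.5), n_plus_dna = rbinom(20, 300, 0.5))
  counts$n_minus_rna <- 300L - counts$n_plus_rna
  counts$n_minus_dna <- 300L - counts$n_plus_dna
  r1 <- strand_bias_test(counts, n_draws = 5e3, seed = 42)
  r2 <- strand_bias_test(counts, n_draws = 5e3, seed = 42)
  expect_equal(tidy(r1), tidy(r2))

  g <- glance(r1)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_units, 20L)
  expect_equal(g$delta_min, 0.10)
  td <- tidy(attr(r1, "prior"))
  expect_equal(td$term, c("alpha", "beta"))
})
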