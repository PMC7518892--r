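test_that("pileup equals the per-position definition", {
  lens <- c(chr1 = 100L)
  one <- frag(start = 10, end = 20)
  cov <- build_coverage(one, lens, "+")$pileup$chr1
  expect_equal(cov, c(rep(0L, 10), rep(1L, 10), rep(0L, 80)))

  two <- dplyr::bind_rows(frag(start = 10, end = 20), frag(start = 15, end = 25))
  cov2 <- build_coverage(two, lens, "+")$pileup$chr1
  expect_equal(cov2[16:20], rep(2L, 5))
  expect_equal(cov2[11:15], rep(1L, 5))
  expect_equal(sum(cov2), 20L)  # sum of fragment lengths
})

test_that("pileup matches a brute-force position count on random input", {
  set.seed(42)
  n <- 200
  s <- sample(0:900, n, replace = TRUE)
  f <- frag(start = s, end = s + sample(20:80, n, replace = TRUE),
            strand = sample(c("+", "-"), n, TRUE))
  lens <- c(chr1 = 1000L)
  for (st in c("+", "-", "both")) {
    cov <- build_coverage(f, lens, st)$pileup$chr1
    keep <- if (st == "both") rep(TRUE, n) else f$strand == st
    brute <- vapply(0:999, function(x)
      sum(f$start[keep] <= x & x < f$end[keep]), integer(1))
    expect_equal(cov, brute, info = st)
  }
})

test_that("no peaks are called when RNA matches the scaled control", {
  set.seed(1)
  lens <- c(chr1 = 20000L)
  mk <- function(n, seed) {
    set.seed(seed)
    s <- sample(0:19900, n, replace = TRUE)
    frag(start = s, end = s + 100L, strand = sample(c("+", "-"), n, TRUE))
  }
  rna <- mk(2000, 1)
  ctrl <- mk(4000, 2)
  peaks <- call_peaks_stranded(rna, ctrl, lens)
  expect_true(nrow(peaks) == 0 || all(peaks$q_value > 0.05))
})

test_that("a single strongly enriched region yields one peak containing it", {
  set.seed(3)
  lens <- c(chr1 = 20000L)
  bg_s <- sample(0:19900, 200, replace = TRUE)
  pk_s <- sample(5000:5150, 120, replace = TRUE)
  rna <- frag(start = c(bg_s, pk_s), end = c(bg_s, pk_s) + 100L, strand = "+")
  ctrl_s <- sample(0:19900, 2000, replace = TRUE)
  ctrl <- frag(start = ctrl_s, end = ctrl_s + 100L,
               strand = sample(c("+", "-"), 2000, TRUE))
  peaks <- call_peaks_stranded(rna, ctrl, lens)
  sig <- dplyr::filter(peaks, q_value <= 0.05)
  expect_equal(nrow(sig), 1)
  expect_lte(sig$start, 5050)          # planted core is 5050..5200
  expect_gte(sig$end, 5200)
  expect_gte(sig$pileup_max, 50)
  expect_true(sig$summit >= sig$start & sig$summit < sig$end)
})

test_that("minus-strand fragments never contribute to plus-strand peaks", {
  set.seed(4)
  lens <- c(chr1 = 20000L)
  pk_s <- sample(5000:5100, 150, replace = TRUE)
  rna <- frag(start = pk_s, end = pk_s + 100L, strand = "-")
  ctrl_s <- sample(0:19900, 1000, replace = TRUE)
  ctrl <- frag(start = ctrl_s, end = ctrl_s + 100L,
               strand = sample(c("+", "-"), 1000, TRUE))
  plus <- call_peaks(build_coverage(rna, lens, "+"),
                     build_coverage(ctrl, lens, "both"))
  minus <- call_peaks(build_coverage(rna, lens, "-"),
                      build_coverage(ctrl, lens, "both"))
  expect_equal(nrow(plus), 0)
  expect_gte(nrow(minus), 1)
})

test_that("tightening the per-base threshold never yields more peaks", {
  set.seed(5)
  lens <- c(chr1 = 30000L)
  s <- c(sample(0:29900, 1500, TRUE), sample(8000:8200, 60, TRUE),
         sample(20000:20100, 25, TRUE))
  rna <- frag(start = s, end = s + 100L, strand = "+")
  ctrl_s <- sample(0:29900, 3000, TRUE)
  ctrl <- frag(start = ctrl_s, end = ctrl_s + 100L,
               strand = sample(c("+", "-"), 3000, TRUE))
  thresholds <- c(1e-2, 1e-3, 1e-5, 1e-8)
  n_peaks <- vapply(thresholds, function(p) {
    nrow(call_peaks_stranded(rna, ctrl, lens, p_call = p))
  }, numeric(1))
  expect_true(all(diff(n_peaks) <= 0))
})

test_that("q-values are a monotone BH transform, invariant to input order", {
  set.seed(6)
  lens <- c(chr1 = 30000L)
  s <- c(sample(0:29900, 1000, TRUE), sample(5000:5200, 80, TRUE),
         sample(15000:15100, 40, TRUE), sample(25000:25200, 60, TRUE))
  rna <- frag(start = s, end = s + 100L, strand = "+")
  ctrl_s <- sample(0:29900, 2000, TRUE)
  ctrl <- frag(start = ctrl_s, end = ctrl_s + 100L,
               strand = sample(c("+", "-"), 2000, TRUE))
  p1 <- call_peaks_stranded(rna, ctrl, lens)
  p2 <- call_peaks_stranded(rna[sample(nrow(rna)), ], ctrl, lens)
  expect_true(all(p1$q_value <= 1 & p1$q_value > 0))
  ord <- order(p1$p_value)
  expect_true(all(diff(p1$q_value[ord]) >= -1e-12))
  expect_equal(dplyr::arrange(p1, start)[c("start", "end", "p_value", "q_value")],
               dplyr::arrange(p2, start)[c("start", "end", "p_value", "q_value")])
})

test_that("zero-depth control falls back to the RNA background with a warning", {
  lens <- c(chr1 = 5000L)
  set.seed(7)
  s <- sample(0:4900, 300, TRUE)
  rna <- build_coverage(frag(start = s, end = s + 80L, strand = "+"), lens, "+")
  empty <- build_coverage(frag(start = 1, end = 2)[0, ], lens, "both")
  expect_warning(call_peaks(rna, empty), "zero-depth control")
})

test_that("control-vs-control calling keeps the called genome fraction low", {
  lens <- c(chr1 = 50000L)
  for (seed in 1:3) {
    set.seed(seed)
    mk <- function(n) {
      s <- sample(0:49900, n, TRUE)
      frag(start = s, end = s + 100L, strand = sample(c("+", "-"), n, TRUE))
    }
    a <- mk(3000); b <- mk(3000)
    peaks <- call_peaks_stranded(a, b, lens)
    sig <- dplyr::filter(peaks, q_value <= 0.05)
    called_bases <- if (nrow(sig) == 0) 0 else sum(sig$end - sig$start)
    expect_lte(called_bases / 50000, 0.05)
  }
})

test_that("tier filters enforce support, pileup, q and high-quality coverage", {
  # one planted peak whose per-sample summit support is fully controlled:
  # each sample contributes only peak fragments (plus one far-away anchor
  # fragment so every sample exists in the table)
  lens <- c(chr1 = 10000L)
  mk_cohort <- function(n_supporting, mapq = 60L) {
    dplyr::bind_rows(lapply(1:15, function(i) {
      id <- paste0("s", i)
      anchor <- frag(start = 9000L + 10L * i, end = 9050L + 10L * i,
                     strand = "-", sample_id = id)
      if (i > n_supporting) return(anchor)
      dplyr::bind_rows(
        anchor,
        frag(start = rep(3000L, 6), end = rep(3150L, 6), strand = "+",
             mapq = mapq, sample_id = id, umi = random_umis(6)))
    }))
  }
  set.seed(99)
  ctrl_s <- sample(0:9900, 3000, TRUE)
  ctrl <- frag(start = ctrl_s, end = ctrl_s + 100L,
               strand = sample(c("+", "-"), 3000, TRUE))

  pooled4 <- mk_cohort(4)
  peaks4 <- dplyr::filter(call_peaks_stranded(pooled4, ctrl, lens),
                          strand == "+")
  expect_equal(nrow(peaks4), 1)
  t4 <- filter_peaks(peaks4, pooled4, min_support = 5)
  expect_equal(t4$n_supporting_samples, 4L)
  expect_equal(t4$tier, "low_confidence")

  # support from 5 samples with high-quality reads -> high confidence
  pooled5 <- mk_cohort(5)
  peaks5 <- dplyr::filter(call_peaks_stranded(pooled5, ctrl, lens),
                          strand == "+")
  t5 <- filter_peaks(peaks5, pooled5, min_support = 5)
  expect_equal(t5$n_supporting_samples, 5L)
  expect_equal(t5$tier, "high_confidence")
  expect_gte(t5$hq_summit_frags, 5L)

  # same support but low-MAPQ reads -> candidate only
  pooled_lowq <- mk_cohort(5, mapq = 20L)
  peaks_lowq <- dplyr::filter(call_peaks_stranded(pooled_lowq, ctrl, lens),
                              strand == "+")
  t_lowq <- filter_peaks(peaks_lowq, pooled_lowq, min_support = 5)
  expect_equal(t_lowq$tier, "candidate")
  expect_equal(t_lowq$hq_summit_frags, 0L)

  expect_error(filter_peaks(peaks4, pooled4, min_support = 16), "exceeds")
})

test_that("narrowPeak output has ten columns and a valid summit offset", {
  peaks <- tibble::tibble(
    chrom = "chr1", start = 100L, end = 300L, strand = "+", summit = 180L,
    pileup_max = 50L, p_value = 1e-8, q_value = 1e-6, peak_id = "peak_fwd_00001")
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(peaks, path)
  got <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(ncol(got), 10)
  expect_equal(got$X10, 80)  # summit - start
  expect_equal(got$X5, as.integer(-10 * log10(1e-6)))
})
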