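peak_row <- function(id, start, end, strand = "+", chrom = "chr1") {
  tibble::tibble(peak_id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}
feat_row <- function(name, start, end, strand = "+", category = "RBP_site",
                     chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, name = name,
                 category = category)
}

test_that("overlap score is the reciprocal product with its boundary cases", {
  expect_equal(overlap_score(100, 100, 100), 1)
  expect_equal(overlap_score(0, 100, 50), 0)
  expect_equal(overlap_score(100, 200, 100), 0.5)
  expect_equal(overlap_score(50, 100, 200), (50 / 100) * (50 / 200))
  # symmetric in the two widths
  expect_equal(overlap_score(30, 60, 90), overlap_score(30, 90, 60))
  expect_error(overlap_score(120, 100, 200), "overlap_bases")
  expect_error(overlap_score(10, 0, 10), ">= 1")
})

test_that("intersection reports exact overlaps and orientation", {
  ann <- annotate_peaks(
    peak_row("p1", 100, 200),
    dplyr::bind_rows(feat_row("sense_f", 150, 250, "+"),
                     feat_row("anti_f", 150, 250, "-")))
  expect_equal(nrow(ann), 2)
  expect_equal(ann$overlap_bases, c(50L, 50L))
  expect_equal(sort(ann$orientation), c("antisense", "sense"))
  # unstranded features are always sense
  ann2 <- annotate_peaks(peak_row("p1", 100, 200, strand = "-"),
                         feat_row("unstranded", 150, 250, "*"))
  expect_equal(ann2$orientation, "sense")
})

test_that("pair set matches a brute-force all-pairs interval check", {
  set.seed(8)
  n <- 100
  ps <- sample(0:5000, n, TRUE)
  pk <- peak_row(sprintf("p%03d", 1:n), ps, ps + sample(20:200, n, TRUE))
  fs <- sample(0:5000, n, TRUE)
  ft <- feat_row(sprintf("f%03d", 1:n), fs, fs + sample(20:200, n, TRUE),
                 strand = sample(c("+", "-"), n, TRUE),
                 category = sample(c("RBP_site", "repeat", "long_RNA"), n, TRUE))
  ann <- annotate_peaks(pk, ft)
  brute <- expand.grid(pi = 1:n, fi = 1:n)
  brute$ov <- pmin(pk$end[brute$pi], ft$end[brute$fi]) -
    pmax(pk$start[brute$pi], ft$start[brute$fi])
  brute <- brute[brute$ov > 0, ]
  expect_equal(nrow(ann), nrow(brute))
  got <- sort(paste(ann$peak_id, ann$feature))
  want <- sort(paste(pk$peak_id[brute$pi], ft$name[brute$fi]))
  expect_equal(got, want)
})

test_that("best feature follows highest score then category priority", {
  pk <- peak_row("p1", 1000, 1100)
  # equal scores: RBP beats repeat
  tie <- annotate_peaks(pk, dplyr::bind_rows(
    feat_row("rbp", 1000, 1100, category = "RBP_site"),
    feat_row("rep", 1000, 1100, category = "repeat")))
  expect_equal(tie$feature[tie$is_best], "rbp")
  # strict maximum wins regardless of category
  strict <- annotate_peaks(pk, dplyr::bind_rows(
    feat_row("rep", 1000, 1100, category = "repeat"),          # score 1
    feat_row("rbp", 1000, 1050, category = "RBP_site")))       # score 0.5
  expect_equal(strict$feature[strict$is_best], "rep")
  # two RBP sites tied at the top score are both reported
  both <- annotate_peaks(pk, dplyr::bind_rows(
    feat_row("rbpA", 950, 1050, category = "RBP_site"),
    feat_row("rbpB", 1050, 1150, category = "RBP_site")))
  expect_equal(sort(both$feature[both$is_best]), c("rbpA", "rbpB"))
  # repeat beats long_RNA at the same score
  rl <- annotate_peaks(pk, dplyr::bind_rows(
    feat_row("gene", 1000, 1100, category = "long_RNA"),
    feat_row("rep", 1000, 1100, category = "repeat")))
  expect_equal(rl$feature[rl$is_best], "rep")
})

test_that("best-feature flagging is order-independent and prefers sense", {
  pk <- peak_row("p1", 1000, 1100)
  ft <- dplyr::bind_rows(
    feat_row("anti_exact", 1000, 1100, strand = "-", category = "RBP_site"),
    feat_row("sense_half", 1000, 1050, strand = "+", category = "long_RNA"))
  a1 <- annotate_peaks(pk, ft)
  a2 <- annotate_peaks(pk, ft[2:1, ])
  # the sense annotation wins despite its lower score
  expect_equal(a1$feature[a1$is_best], "sense_half")
  expect_equal(dplyr::arrange(a1, feature), dplyr::arrange(a2, feature))
})

test_that("peaks are classified sense / antisense / unannotated", {
  pks <- dplyr::bind_rows(peak_row("p_sense", 100, 200),
                          peak_row("p_anti", 1000, 1100),
                          peak_row("p_none", 3000, 3100))
  ft <- dplyr::bind_rows(feat_row("f1", 100, 200, "+"),
                         feat_row("f2", 1000, 1100, "-"))
  s <- summarise_annotation(pks, annotate_peaks(pks, ft))
  expect_equal(s$annotation_class[match(c("p_sense", "p_anti", "p_none"),
                                        s$peak_id)],
               c("sense", "antisense", "unannotated"))
})

test_that("overlap score is invariant to coordinate translation", {
  for (shift in c(0L, 137L, 10000L)) {
    ann <- annotate_peaks(peak_row("p1", 100 + shift, 300 + shift),
                          feat_row("f", 200 + shift, 500 + shift))
    expect_equal(ann$overlap_score, (100 / 200) * (100 / 300))
  }
})

test_that("conservation averaging matches the per-base mean", {
  pk <- peak_row("p1", 100, 200)
  flat <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L, score = 0.8)
  expect_equal(conservation_mean(pk, flat)$mean_score, 0.8)

  halves <- tibble::tibble(chrom = "chr1", start = c(100L, 150L),
                           end = c(150L, 200L), score = c(1, 0))
  expect_equal(conservation_mean(pk, halves)$mean_score, 0.5)

  # random binned track vs brute-force per-base mean
  set.seed(9)
  bins <- tibble::tibble(chrom = "chr1", start = seq(0L, 990L, 10L),
                         end = seq(10L, 1000L, 10L),
                         score = runif(100))
  got <- conservation_mean(pk, bins)
  per_base <- rep(bins$score, each = 10)[101:200]
  expect_equal(got$mean_score, mean(per_base))
  expect_equal(got$n_bases_covered, 100L)

  # uncovered bases are excluded and counted; no coverage warns with NA
  partial <- tibble::tibble(chrom = "chr1", start = 100L, end = 120L,
                            score = 0.4)
  got2 <- conservation_mean(pk, partial)
  expect_equal(got2$mean_score, 0.4)
  expect_equal(got2$n_bases_covered, 20L)
  expect_warning(none <- conservation_mean(peak_row("p2", 5000, 5100), partial),
                 "no conservation")
  expect_true(is.na(none$mean_score))
})

test_that("planted category proportions are recovered on a synthetic set", {
  g <- synth_genome(chrom_length = 30000, n_genes = 3, n_peaks = 6,
                    n_rbp_peaks = 6, repeat_units = c("CCG", "CATTC"),
                    intron_lengths = c(90), seed = 21)
  feats <- dplyr::bind_rows(
    g$rbp_sites %>% dplyr::mutate(category = "RBP_site"),
    g$repeats %>% dplyr::transmute(chrom, start, end, strand,
                                   name = unit, category = "repeat"),
    g$genes %>% dplyr::transmute(chrom, start, end, strand,
                                 name = gene_id, category = "long_RNA"))
  pk <- g$peaks_truth %>% dplyr::select(peak_id, chrom, start, end, strand)
  best <- annotate_peaks(pk, feats) %>% dplyr::filter(is_best)
  # every planted peak sits under its planted RBP site, which wins the
  # priority rule over the surrounding gene
  expect_equal(sort(unique(best$category)), "RBP_site")
  expect_equal(nrow(best), 6)
})
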