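#' Simulate a full scaled-down plasma cfRNA study
#'
#' Builds one synthetic genome and a matched cohort of UMI-tagged fragment
#' libraries: `n_rna` DNase-treated plasma RNA samples carrying the planted
#' peak, repeat and intron signal over background, and `n_dna`
#' alkaline-hydrolysis plasma DNA control samples with uniform background
#' (plus strand-balanced repeat coverage). Sample seeds are derived from
#' `seed`, so the whole study is reproducible from one integer.
#'
#' @param n_rna,n_dna numbers of RNA and DNA-control samples.
#' @param seed master seed.
#' @param genome_args list of overrides passed to [synth_genome()].
#' @param rna_args,dna_args lists of overrides passed to
#'   [synth_fragments()] for the two roles.
#' @return A list of class `cf_study`: `genome`, `rna` (named list of
#'   fragment tibbles), `dna` (same for controls), `seed`.
#' @export
#' @examples
#' study <- synth_study(n_rna = 3, n_dna = 1, seed = 1,
#'                      genome_args = list(chrom_length = 20000,
#'                                         n_genes = 2, n_peaks = 3))
synth_study <- function(n_rna = 15L, n_dna = 4L, seed = 1L,
                        genome_args = list(), rna_args = list(),
                        dna_args = list()) {
  genome <- do.call(synth_genome, c(list(seed = seed), genome_args))
  rna <- lapply(seq_len(n_rna), function(i) {
    do.call(synth_fragments, c(list(
      genome = genome, role = "rna",
      sample_id = sprintf("rna%02d", i), seed = seed * 1000L + i),
      rna_args))
  })
  names(rna) <- sprintf("rna%02d", seq_len(n_rna))
  dna <- lapply(seq_len(n_dna), function(i) {
    do.call(synth_fragments, c(list(
      genome = genome, role = "dna",
      sample_id = sprintf("dna%02d", i), seed = seed * 1000L + 500L + i),
      dna_args))
  })
  names(dna) <- sprintf("dna%02d", seq_len(n_dna))
  structure(list(genome = genome, rna = rna, dna = dna, seed = seed),
            class = "cf_study")
}

#' @export
print.cf_study <- function(x, ...) {
  cat("<cf_study>", length(x$rna), "RNA +", length(x$dna),
      "DNA-control samples over",
      sum(x$genome$chrom_lengths), "nt; seed", x$seed, "\n")
  invisible(x)
}

#' Run peak calling end to end on a simulated study
#'
#' Per-sample deduplication, pooling of the RNA samples, strand-split
#' calling against the combined-strand pooled DNA control, and the
#' candidate / high-confidence tier filters with per-sample summit support.
#'
#' @param study a `cf_study` from [synth_study()].
#' @param min_support minimum supporting samples for the candidate tier.
#' @param p_call per-base Poisson threshold of the caller.
#' @param ... further arguments to [filter_peaks()].
#' @return A list: `peaks` (tiered peak tibble), `rna_pooled` and
#'   `dna_pooled` (deduplicated fragment tibbles), `per_sample`
#'   (deduplicated per-sample RNA fragments, one tibble).
#' @export
run_peak_calling <- function(study, min_support = 5L, p_call = 1e-3, ...) {
  stopifnot(inherits(study, "cf_study"))
  per_sample <- bind_rows(lapply(study$rna, deduplicate))
  dna_pooled <- bind_rows(lapply(study$dna, deduplicate))
  peaks <- call_peaks_stranded(per_sample, dna_pooled,
                               study$genome$chrom_lengths, p_call = p_call)
  peaks <- filter_peaks(peaks, per_sample, min_support = min_support, ...)
  list(peaks = peaks, rna_pooled = per_sample, dna_pooled = dna_pooled,
       per_sample = per_sample)
}

#' Score called peaks against a planted truth table
#'
#' Recall = fraction of truth intervals overlapped by at least one called
#' peak; precision = fraction of called peaks overlapping at least one
#' truth interval. Overlap is strand-aware when both sides carry strand
#' (`"*"` in the truth matches either strand).
#'
#' @param called called-peak tibble (`chrom`, `start`, `end`, `strand`).
#' @param truth truth tibble of planted intervals.
#' @return A one-row tibble: `n_called`, `n_truth`, `recall`, `precision`.
#' @export
peak_recovery_stats <- function(called, truth) {
  overlaps <- function(a, b) {
    # rows of `a` overlapping any row of `b`
    if (nrow(a) == 0 || nrow(b) == 0) return(logical(nrow(a)))
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i] &
            (!"strand" %in% names(b) | !"strand" %in% names(a) |
               b$strand == "*" | a$strand[i] == "*" |
               b$strand == a$strand[i]))
    }, logical(1))
  }
  tibble(n_called = nrow(called), n_truth = nrow(truth),
         recall = if (nrow(truth) == 0) NA_real_
                  else mean(overlaps(truth, called)),
         precision = if (nrow(called) == 0) NA_real_
                     else mean(overlaps(called, truth)))
}

#' All planted signal intervals of a synthetic genome
#'
#' Convenience union of the planted peak, repeat-locus and intron truth
#' intervals, for precision scoring: a called peak over any planted element
#' is a true signal even if that element is not in the peak truth table.
#'
#' @param genome a `cf_genome`.
#' @return A tibble `chrom`, `start`, `end`, `strand`, `what`.
#' @export
planted_intervals <- function(genome) {
  bind_rows(
    genome$peaks_truth %>%
      select("chrom", "start", "end", "strand") %>% mutate(what = "peak"),
    genome$repeats %>%
      select("chrom", "start", "end") %>%
      mutate(strand = "*", what = "repeat"),
    genome$introns %>%
      select("chrom", "start", "end", "strand") %>% mutate(what = "intron")
  )
}
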