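#' Build a per-base fragment pileup track
#'
#' The pileup at position x is the number of fragments with
#' start <= x < end on the requested strand; `"both"` pools the strands
#' (the convention used for the DNA baseline control).
#'
#' @param frags fragment tibble (deduplicated).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @return A `cf_coverage` object: per-chromosome integer pileup vectors
#'   plus the contributing fragment count.
#' @export
build_coverage <- function(frags, chrom_lengths, strand = "both") {
  check_fragment_cols(frags)
  if (!strand %in% c("+", "-", "both")) abort('strand must be "+", "-" or "both"')
  if (strand != "both") frags <- frags %>% filter(.data$strand == !!strand)
  pile <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch] ]
    f <- frags %>% filter(.data$chrom == ch)
    if (nrow(f) == 0) return(integer(len))
    cov <- IRanges::coverage(as_iranges0(f$start, f$end), width = len)
    as.integer(cov)
  })
  names(pile) <- names(chrom_lengths)
  structure(list(pileup = pile, strand = strand,
                 n_fragments = nrow(frags),
                 chrom_lengths = chrom_lengths),
            class = "cf_coverage")
}

#' @export
print.cf_coverage <- function(x, ...) {
  cat("<cf_coverage> strand:", x$strand, "| fragments:", x$n_fragments,
      "| chroms:", paste(names(x$pileup), collapse = ", "), "\n")
  invisible(x)
}

# truncated centred running mean, vectorised via cumulative sums
window_mean <- function(v, w) {
  n <- length(v)
  cs <- c(0, cumsum(as.numeric(v)))
  i <- seq_len(n)
  lo <- pmax(i - 1L - w %/% 2L, 0L)
  hi <- pmin(i + w %/% 2L, n)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Call enriched peaks from an RNA pileup against a DNA baseline
#'
#' A local-lambda Poisson caller in the spirit of ChIP-seq peak callers: the
#' background rate at each base is the maximum of the genome-wide, 1-kb and
#' 10-kb window means of the depth-scaled control pileup (scaling factor =
#' total RNA fragments / total control fragments), so local background
#' structure in the control suppresses spurious calls. Bases whose Poisson
#' upper-tail p-value falls below `p_call` are merged into peaks when
#' separated by at most `merge_gap` nt; peaks narrower than `min_width` are
#' discarded. Each peak reports its minimum per-base p-value, and q-values
#' are assigned across peaks by Benjamini-Hochberg.
#'
#' If the control track is empty (or `control` is `NULL`, the
#' transcriptome-space mode), the RNA genome-wide rate is used as a flat
#' background with a warning.
#'
#' @param rna_track `cf_coverage` of pooled RNA fragments on one strand.
#' @param control `cf_coverage` of the both-strand DNA control, or `NULL`.
#' @param p_call per-base Poisson p-value threshold that seeds peaks.
#' @param merge_gap maximum gap (nt) bridged when merging called bases.
#' @param min_width minimum peak width (nt) retained.
#' @param windows local background window sizes (nt).
#' @return A tibble of peaks: `chrom`, `start`, `end`, `strand`, `summit`
#'   (absolute 0-based position of the pileup maximum), `pileup_max`,
#'   `p_value`, `q_value`, `peak_id`.
#' @export
call_peaks <- function(rna_track, control = NULL, p_call = 1e-3,
                       merge_gap = 50L, min_width = 50L,
                       windows = c(1000L, 10000L)) {
  stopifnot(inherits(rna_track, "cf_coverage"))
  use_control <- !is.null(control) && control$n_fragments > 0
  if (!is.null(control) && control$n_fragments == 0) {
    warn("zero-depth control; falling back to RNA genome-wide background rate")
  }
  genome_len <- sum(vapply(rna_track$pileup, length, integer(1)))
  scale <- if (use_control) rna_track$n_fragments / control$n_fragments else 1

  peaks <- purrr::map_dfr(names(rna_track$pileup), function(ch) {
    v <- rna_track$pileup[[ch]]
    if (use_control) {
      cv <- as.numeric(control$pileup[[ch]]) * scale
      lam_bg <- sum(vapply(control$pileup, function(x) sum(as.numeric(x)),
                           numeric(1))) * scale / genome_len
      lam <- pmax(lam_bg, Reduce(pmax, lapply(windows, function(w)
        window_mean(cv, w))))
    } else {
      lam_bg <- sum(vapply(rna_track$pileup, function(x) sum(as.numeric(x)),
                           numeric(1))) / genome_len
      lam <- rep(lam_bg, length(v))
    }
    lam <- pmax(lam, 1e-9)
    pv <- ppois(v - 1L, lam, lower.tail = FALSE)
    called <- pv < p_call & v > 0
    if (!any(called)) return(NULL)
    reg <- IRanges::reduce(IRanges::IRanges(which(called), which(called)),
                           min.gapwidth = merge_gap + 1L)
    reg <- reg[IRanges::width(reg) >= min_width]
    if (length(reg) == 0) return(NULL)
    purrr::map_dfr(seq_along(reg), function(i) {
      s <- IRanges::start(reg)[i]; e <- IRanges::end(reg)[i]
      seg <- v[s:e]
      tibble(chrom = ch,
             start = s - 1L, end = e,
             strand = rna_track$strand,
             summit = s - 1L + which.max(seg) - 1L,
             pileup_max = max(seg),
             p_value = max(min(pv[s:e]), .Machine$double.xmin))
    })
  })
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), summit = integer(0),
                  pileup_max = integer(0), p_value = numeric(0),
                  q_value = numeric(0), peak_id = character(0)))
  }
  peaks %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           peak_id = sprintf("peak_%s_%05d",
                             if_else(.data$strand == "+", "fwd",
                                     if_else(.data$strand == "-", "rev", "b")),
                             row_number())) %>%
    as_tibble()
}

#' Call peaks on both strands against the combined-strand DNA control
#'
#' Splits the pooled RNA fragments by strand, calls each strand against the
#' both-strand control, and assigns Benjamini-Hochberg q-values across the
#' combined peak list.
#'
#' @param rna_frags pooled deduplicated RNA fragment tibble.
#' @param control_frags pooled deduplicated DNA-control fragment tibble, or
#'   `NULL` for transcriptome-space calling against the RNA background rate.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @inheritParams call_peaks
#' @return A peak tibble as in [call_peaks()], both strands combined.
#' @export
call_peaks_stranded <- function(rna_frags, control_frags, chrom_lengths,
                                p_call = 1e-3, merge_gap = 50L,
                                min_width = 50L, windows = c(1000L, 10000L)) {
  control <- if (is.null(control_frags)) NULL else
    build_coverage(control_frags, chrom_lengths, "both")
  peaks <- bind_rows(lapply(c("+", "-"), function(st) {
    call_peaks(build_coverage(rna_frags, chrom_lengths, st), control,
               p_call = p_call, merge_gap = merge_gap, min_width = min_width,
               windows = windows)
  }))
  if (nrow(peaks) == 0) return(peaks)
  peaks %>%
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           peak_id = sprintf("peak_%s_%05d",
                             if_else(.data$strand == "+", "fwd", "rev"),
                             row_number()))
}

#' Tier called peaks by replicate support and high-quality coverage
#'
#' Applies the candidate and high-confidence filters: a *candidate* peak has
#' pileup >= `min_pileup` at the peak maximum, q-value <= `max_q`, and summit
#' support from at least `min_support` of the samples (a sample supports a
#' peak if at least one of its deduplicated fragments overlaps the summit).
#' A candidate is promoted to *high confidence* when at least `min_hq_summit`
#' fragments passing the MAPQ >= `mapq_min` / NM <= `nm_max` filter overlap
#' the summit. Everything else is *low confidence*.
#'
#' @param peaks peak tibble from [call_peaks_stranded()].
#' @param sample_frags deduplicated fragments of all samples in one tibble
#'   with a `sample_id` column (strand-matched to the peak).
#' @param min_support minimum number of supporting samples.
#' @param min_pileup minimum pileup at the peak maximum.
#' @param max_q maximum Benjamini-Hochberg q-value.
#' @param min_hq_summit minimum high-quality fragments over the summit.
#' @param mapq_min,nm_max high-quality fragment thresholds.
#' @return The peak tibble with `n_supporting_samples`, `hq_summit_frags`
#'   and `tier` (`high_confidence` / `candidate` / `low_confidence`) added.
#' @export
filter_peaks <- function(peaks, sample_frags, min_support = 5L,
                         min_pileup = 5L, max_q = 0.05,
                         min_hq_summit = 5L, mapq_min = 30L, nm_max = 4L) {
  check_fragment_cols(sample_frags, c("chrom", "start", "end", "strand",
                                      "sample_id"))
  n_samples <- length(unique(sample_frags$sample_id))
  if (min_support > n_samples) {
    abort(paste0("min_support (", min_support, ") exceeds the number of ",
                 "samples (", n_samples, ")"))
  }
  if (nrow(peaks) == 0) {
    return(peaks %>% mutate(n_supporting_samples = integer(0),
                            hq_summit_frags = integer(0),
                            tier = character(0)))
  }
  hq <- sample_frags %>% filter(.data$mapq >= mapq_min, .data$nm <= nm_max)
  support <- integer(nrow(peaks))
  hq_n <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    at_summit <- sample_frags %>%
      filter(.data$chrom == p$chrom, .data$strand == p$strand,
             .data$start <= p$summit, .data$end > p$summit)
    support[i] <- length(unique(at_summit$sample_id))
    hq_n[i] <- hq %>%
      filter(.data$chrom == p$chrom, .data$strand == p$strand,
             .data$start <= p$summit, .data$end > p$summit) %>%
      nrow()
  }
  peaks %>%
    mutate(
      n_supporting_samples = support,
      hq_summit_frags = hq_n,
      candidate = .data$pileup_max >= min_pileup &
        .data$q_value <= max_q &
        .data$n_supporting_samples >= min_support,
      tier = dplyr::case_when(
        candidate & hq_summit_frags >= min_hq_summit ~ "high_confidence",
        candidate ~ "candidate",
        TRUE ~ "low_confidence")
    ) %>%
    select(-"candidate")
}

#' Write peaks in ENCODE narrowPeak format
#'
#' Ten columns: chrom, start, end, name, score (`int(-10 log10 q)`), strand,
#' signalValue (pileup at maximum), pValue and qValue (-log10), and summit
#' offset relative to peak start.
#'
#' @param peaks peak tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$peak_id,
    score = as.integer(pmin(-10 * log10(pmax(peaks$q_value, 1e-100)), 1000)),
    strand = peaks$strand,
    signalValue = peaks$pileup_max,
    pValue = -log10(pmax(peaks$p_value, .Machine$double.xmin)),
    qValue = -log10(pmax(peaks$q_value, .Machine$double.xmin)),
    peak = peaks$summit - peaks$start
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
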