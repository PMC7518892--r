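#' The reciprocal peak/feature overlap score
#'
#' Defined as the product of (overlapping bases / peak width) and
#' (overlapping bases / feature size). The score is 1 - the highest
#' possible - exactly when the peak and the feature coincide, i.e. the peak
#' is fully explained by the full-length feature; it is symmetric in the two
#' widths and invariant to coordinate translation.
#'
#' @param overlap_bases number of overlapping bases.
#' @param peak_width peak width in nt (>= 1).
#' @param feature_size feature size in nt (>= 1).
#' @return Numeric score in [0, 1].
#' @export
#' @examples
#' overlap_score(100, 100, 100)  # 1: exact coincidence
#' overlap_score(100, 200, 100)  # 0.5
overlap_score <- function(overlap_bases, peak_width, feature_size) {
  if (any(peak_width < 1) || any(feature_size < 1)) {
    abort("peak_width and feature_size must be >= 1")
  }
  if (any(overlap_bases < 0) ||
      any(overlap_bases > pmin(peak_width, feature_size))) {
    abort("overlap_bases must lie in [0, min(peak_width, feature_size)]")
  }
  (overlap_bases / peak_width) * (overlap_bases / feature_size)
}

# category priority used to break exact overlap-score ties
.category_rank <- c(RBP_site = 1, "repeat" = 2, long_RNA = 3,
                    sncRNA = 4, other = 5)

#' Annotate peaks against feature sets with the overlap score
#'
#' Intersects peaks with features (all categories at once - equivalent to a
#' sequential per-category intersection under this scoring), computes the
#' overlap score for every overlapping pair, classifies each pair as sense
#' or antisense, and flags each peak's best feature(s): the highest overlap
#' score wins; exact ties are broken by category priority RBP binding site >
#' repeat > long RNA (unlisted categories rank after long RNA); several
#' features of the winning category tied at the top score are all flagged.
#' Best-feature selection prefers sense annotations; a peak with only
#' antisense annotations gets its best feature among those.
#'
#' @param peaks peak tibble with `peak_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param features tibble with `chrom`, `start`, `end`, `strand`, `name`,
#'   `category` (one of `RBP_site`, `repeat`, `long_RNA`, `sncRNA`,
#'   `other`). Features with strand `"*"` or `"."` are treated as
#'   both-strand and always sense.
#' @return A tibble with one row per overlapping (peak, feature) pair:
#'   `peak_id`, `feature`, `category`, `feature_start`, `feature_end`,
#'   `overlap_bases`, `overlap_score`, `orientation`, `is_best`.
#' @export
annotate_peaks <- function(peaks, features) {
  stopifnot(all(c("peak_id", "chrom", "start", "end", "strand") %in%
                  names(peaks)))
  stopifnot(all(c("chrom", "start", "end", "strand", "name", "category") %in%
                  names(features)))
  bad <- setdiff(unique(features$category), names(.category_rank))
  if (length(bad) > 0) {
    abort(paste0("unknown feature category: ", paste(bad, collapse = ", ")))
  }
  empty <- tibble(peak_id = character(0), feature = character(0),
                  category = character(0), feature_start = integer(0),
                  feature_end = integer(0), overlap_bases = integer(0),
                  overlap_score = numeric(0), orientation = character(0),
                  is_best = logical(0))
  if (nrow(peaks) == 0 || nrow(features) == 0) return(empty)

  ann <- purrr::map_dfr(unique(peaks$chrom), function(ch) {
    pk <- peaks %>% filter(.data$chrom == ch)
    ft <- features %>% filter(.data$chrom == ch)
    if (nrow(ft) == 0) return(NULL)
    hits <- IRanges::findOverlaps(as_iranges0(pk$start, pk$end),
                                  as_iranges0(ft$start, ft$end))
    if (length(hits) == 0) return(NULL)
    pi <- S4Vectors::queryHits(hits)
    fi <- S4Vectors::subjectHits(hits)
    ov <- pmin(pk$end[pi], ft$end[fi]) - pmax(pk$start[pi], ft$start[fi])
    tibble(
      peak_id = pk$peak_id[pi],
      feature = ft$name[fi],
      category = ft$category[fi],
      feature_start = ft$start[fi],
      feature_end = ft$end[fi],
      overlap_bases = as.integer(ov),
      overlap_score = overlap_score(ov, pk$end[pi] - pk$start[pi],
                                    ft$end[fi] - ft$start[fi]),
      orientation = if_else(ft$strand[fi] %in% c("*", ".") |
                              ft$strand[fi] == pk$strand[pi],
                            "sense", "antisense")
    )
  })
  if (nrow(ann) == 0) return(empty)

  ann %>%
    group_by(.data$peak_id) %>%
    mutate(is_best = flag_best(.data$overlap_score, .data$category,
                               .data$orientation)) %>%
    ungroup() %>%
    arrange(.data$peak_id, desc(.data$is_best), desc(.data$overlap_score))
}

# best-feature rule within one peak's annotations
flag_best <- function(score, category, orientation) {
  pool <- if (any(orientation == "sense")) orientation == "sense"
          else rep(TRUE, length(score))
  best <- pool & score == max(score[pool])
  if (sum(best) > 1) {
    top_rank <- min(.category_rank[category[best]])
    best <- best & .category_rank[category] == top_rank
  }
  unname(best)
}

#' Summarise each peak's annotation status
#'
#' @param peaks peak tibble.
#' @param annotations output of [annotate_peaks()].
#' @return One row per peak: `peak_id`, `annotation_class` (`sense`,
#'   `antisense`, or `unannotated`), the best feature name(s)
#'   (comma-joined), category and score.
#' @export
summarise_annotation <- function(peaks, annotations) {
  best <- annotations %>%
    filter(.data$is_best) %>%
    group_by(.data$peak_id) %>%
    summarise(best_feature = paste(.data$feature, collapse = ","),
              best_category = first(.data$category),
              best_score = max(.data$overlap_score),
              annotation_class = if_else(any(.data$orientation == "sense"),
                                         "sense", "antisense"),
              .groups = "drop")
  peaks %>%
    select("peak_id") %>%
    left_join(best, by = "peak_id") %>%
    mutate(annotation_class = if_else(is.na(.data$annotation_class),
                                      "unannotated", .data$annotation_class))
}

#' Average a per-base conservation track over peaks
#'
#' Computes, for each peak, the arithmetic mean of the per-nucleotide
#' conservation score over the bases the track covers; uncovered bases are
#' excluded from the mean and counted. A peak with no covered base gets
#' `NA` with a warning.
#'
#' @param peaks peak tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param track conservation tibble in bedGraph layout: `chrom`, `start`,
#'   `end`, `score` (0-based half-open intervals of constant score).
#' @return A tibble: `peak_id`, `mean_score`, `n_bases_covered`.
#' @export
conservation_mean <- function(peaks, track) {
  res <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    tr <- track %>%
      filter(.data$chrom == p$chrom, .data$end > p$start,
             .data$start < p$end)
    if (nrow(tr) == 0) {
      return(tibble(peak_id = p$peak_id, mean_score = NA_real_,
                    n_bases_covered = 0L))
    }
    ov <- pmin(tr$end, p$end) - pmax(tr$start, p$start)
    tibble(peak_id = p$peak_id,
           mean_score = sum(tr$score * ov) / sum(ov),
           n_bases_covered = as.integer(sum(ov)))
  })
  if (any(res$n_bases_covered == 0)) {
    warn("some peaks have no conservation coverage; mean_score is NA")
  }
  res
}
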