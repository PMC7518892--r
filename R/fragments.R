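#' Read UMI-tagged fragment records
#'
#' Reads template-level fragment alignments from a headerless BED-like TSV
#' (chrom, start, end, UMI, MAPQ, strand, CIGAR, NM, optional 3'-clip and
#' sample id) or from 10-column BEDPE, in which case each read pair is
#' collapsed to its outermost template span. Coordinates are 0-based
#' half-open.
#'
#' @param path file path.
#' @param format `"bed"` (default) or `"bedpe"`.
#' @param umi_len expected UMI length; records are validated against it.
#' @return A fragment tibble (see [synth_fragments()] for the columns).
#'   Malformed rows raise an error naming the offending line number.
#' @export
read_fragments <- function(path, format = c("bed", "bedpe"), umi_len = 6L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))

  if (format == "bed") {
    cols <- c("chrom", "start", "end", "umi", "mapq", "strand", "cigar",
              "nm", "clip3", "sample_id")
    raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    if (ncol(raw) < 8) {
      abort("BED-like fragment file needs >= 8 columns (incl. UMI, CIGAR, NM)")
    }
    raw <- raw[, seq_len(min(ncol(raw), 10L))]
    names(raw) <- cols[seq_len(ncol(raw))]
    if (!"clip3" %in% names(raw)) raw$clip3 <- "."
    if (!"sample_id" %in% names(raw)) raw$sample_id <- "s1"
    frags <- raw %>%
      mutate(start = suppressWarnings(as.integer(.data$start)),
             end = suppressWarnings(as.integer(.data$end)),
             mapq = suppressWarnings(as.integer(.data$mapq)),
             nm = suppressWarnings(as.integer(.data$nm)),
             clip3 = if_else(.data$clip3 == ".", "", .data$clip3))
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    if (ncol(raw) < 10) abort("BEDPE fragment file needs >= 10 columns")
    frags <- tibble(
      chrom = raw[[1]],
      start = pmin(suppressWarnings(as.integer(raw[[2]])),
                   suppressWarnings(as.integer(raw[[5]]))),
      end = pmax(suppressWarnings(as.integer(raw[[3]])),
                 suppressWarnings(as.integer(raw[[6]]))),
      umi = raw[[7]],
      mapq = suppressWarnings(as.integer(raw[[8]])),
      strand = raw[[9]],
      cigar = if (ncol(raw) >= 11) raw[[11]] else "*",
      nm = if (ncol(raw) >= 12)
        suppressWarnings(as.integer(raw[[12]])) else 0L,
      clip3 = "",
      sample_id = "s1"
    )
    bad_chrom <- which(raw[[1]] != raw[[4]])
    if (length(bad_chrom) > 0) {
      abort(paste0("BEDPE mates on different chromosomes at line ",
                   bad_chrom[1]))
    }
  }

  bad <- which(is.na(frags$start) | is.na(frags$end) | frags$start < 0)
  if (length(bad) > 0) {
    abort(paste0("unparseable or negative coordinates at line ", bad[1]))
  }
  bad <- which(frags$start >= frags$end)
  if (length(bad) > 0) {
    abort(paste0("start >= end at line ", bad[1]))
  }
  if (any(is.na(frags$umi)) || any(frags$umi == "")) {
    abort("missing UMI column values; configure the UMI field")
  }
  bad <- which(nchar(frags$umi) != umi_len)
  if (length(bad) > 0) {
    abort(paste0("UMI of unexpected length at line ", bad[1],
                 " (expected ", umi_len, " nt)"))
  }
  as_tibble(frags)
}

#' Filter fragments by blacklist, mapping quality and mismatch count
#'
#' Applies the preprocessing filters used before and during peak calling:
#' fragments overlapping any blacklist interval are dropped from every tier;
#' the `"high_quality"` tier additionally drops fragments with
#' MAPQ < `mapq_min` (default 30, excluding multi-mapping reads) or
#' NM >= `nm_max + 1` (default: >= 5 mismatches from the mapped locus). The
#' `"candidate"` tier applies only the blacklist, mirroring the candidate ->
#' high-confidence flow of the peak filters.
#'
#' @param frags fragment tibble.
#' @param blacklist optional tibble with `chrom`, `start`, `end` of regions
#'   to exclude (0-based half-open).
#' @param tier `"candidate"` or `"high_quality"`.
#' @param mapq_min minimum MAPQ kept in the high-quality tier.
#' @param nm_max maximum mismatch count kept in the high-quality tier.
#' @return The filtered fragment tibble.
#' @export
filter_fragments <- function(frags, blacklist = NULL,
                             tier = c("high_quality", "candidate"),
                             mapq_min = 30L, nm_max = 4L) {
  tier <- match.arg(tier)
  check_fragment_cols(frags)
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(frags) > 0) {
    hit <- logical(nrow(frags))
    for (ch in unique(frags$chrom)) {
      fi <- which(frags$chrom == ch)
      bl <- blacklist %>% filter(.data$chrom == ch)
      if (nrow(bl) == 0) next
      ov <- IRanges::overlapsAny(as_iranges0(frags$start[fi], frags$end[fi]),
                                 as_iranges0(bl$start, bl$end))
      hit[fi] <- ov
    }
    frags <- frags[!hit, ]
  }
  if (tier == "high_quality") {
    frags <- frags %>%
      filter(.data$mapq >= mapq_min, .data$nm <= nm_max)
  }
  frags
}

#' Deduplicate fragments by coordinates, CIGAR and UMI
#'
#' Collapses PCR duplicates: fragments with the same chromosome, start, end
#' (and by default strand) and CIGAR string whose UMIs are identical or
#' differ by at most one nucleotide are merged into a single molecule. Within
#' each coordinate/CIGAR group, UMIs are clustered as connected components of
#' the Hamming-distance-<=1 graph; a position containing N never matches.
#' A `"directional"` variant seeds clusters from the most frequent UMI and
#' only absorbs neighbours with lower counts, following the count-ordered
#' network scheme used by UMI-tools.
#'
#' @param frags fragment tibble.
#' @param umi_mismatch maximum Hamming distance collapsed (0 or 1).
#' @param use_strand whether strand is part of the dedup key (default TRUE).
#' @param method `"components"` (default) or `"directional"`.
#' @return A tibble of unique molecules: one row per UMI cluster with the
#'   group's coordinates, the cluster's most frequent UMI, and a
#'   `multiplicity` column whose sum equals the input record count. Other
#'   per-record columns keep the first record's value.
#' @export
deduplicate <- function(frags, umi_mismatch = 1L, use_strand = TRUE,
                        method = c("components", "directional")) {
  method <- match.arg(method)
  check_fragment_cols(frags, c("chrom", "start", "end", "strand", "umi",
                               "cigar"))
  if (nrow(frags) == 0) {
    return(frags %>% mutate(multiplicity = integer(0)))
  }
  key <- paste(frags$chrom, frags$start, frags$end, frags$cigar,
               if (use_strand) frags$strand else "", sep = "\r")
  split_idx <- split(seq_len(nrow(frags)), key)

  out_idx <- integer(0)
  out_mult <- integer(0)
  out_umi <- character(0)
  for (idx in split_idx) {
    umis <- frags$umi[idx]
    if (length(unique(nchar(umis))) > 1) {
      abort("UMIs of unequal length within a dedup group")
    }
    cl <- cluster_umis(umis, max_mismatch = umi_mismatch, method = method)
    for (cid in unique(cl)) {
      members <- idx[cl == cid]
      mumis <- frags$umi[members]
      top <- names(sort(table(mumis), decreasing = TRUE))[1]
      out_idx <- c(out_idx, members[1])
      out_mult <- c(out_mult, length(members))
      out_umi <- c(out_umi, top)
    }
  }
  res <- frags[out_idx, ]
  res$umi <- out_umi
  res$multiplicity <- out_mult
  res %>% arrange(.data$chrom, .data$start, .data$end) %>% as_tibble()
}

# cluster UMIs within one coordinate group; returns integer cluster ids
cluster_umis <- function(umis, max_mismatch = 1L, method = "components") {
  n <- length(umis)
  if (n == 1) return(1L)
  tab <- table(umis)
  uniq <- names(tab)
  m <- length(uniq)
  if (m == 1) return(rep(1L, n))

  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      adj[i, j] <- adj[j, i] <- umi_hamming(uniq[i], uniq[j]) <= max_mismatch
    }
  }

  if (method == "components") {
    # union-find over the adjacency
    parent <- seq_len(m)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    comp <- vapply(seq_len(m), find, integer(1))
  } else {
    # directional: visit UMIs by descending count; an unassigned UMI seeds a
    # cluster and absorbs unassigned neighbours with count <= its own
    ord <- order(-as.integer(tab), uniq)
    comp <- rep(NA_integer_, m)
    next_id <- 0L
    for (i in ord) {
      if (!is.na(comp[i])) next
      next_id <- next_id + 1L
      comp[i] <- next_id
      nb <- which(adj[i, ] & is.na(comp) &
                    as.integer(tab) <= as.integer(tab)[i])
      comp[nb] <- next_id
    }
  }
  comp_of_umi <- setNames(comp, uniq)
  as.integer(factor(comp_of_umi[umis]))
}

#' Correct a molecule count for UMI saturation
#'
#' With `L` possible UMI labels (default 4^6 = 4096 for 6-nt UMIs), distinct
#' molecules collide on the same label at high depth, so the observed number
#' of distinct UMIs `k` undercounts molecules. The label-collision estimator
#' `m = -L * log(1 - k / L)` inverts the expected occupancy; it is strictly
#' increasing and convex in `k` and approximately `k` when `k << L`.
#' At full saturation (`k = L`) the estimate diverges; it is capped at
#' `-L * log(1 / (2 * L))` with a warning.
#'
#' @param k_observed observed distinct-molecule count(s) after dedup.
#' @param L_labels number of possible UMI labels.
#' @return Numeric vector of readjusted molecule counts.
#' @export
#' @examples
#' saturation_adjust(2048, 4096)  # -4096 * log(0.5)
saturation_adjust <- function(k_observed, L_labels = 4096L) {
  if (any(k_observed < 0) || any(k_observed > L_labels)) {
    abort("k_observed must lie in [0, L_labels]")
  }
  sat <- k_observed >= L_labels
  if (any(sat)) {
    warn("UMI labels fully saturated; estimate capped at -L*log(1/(2L))")
  }
  out <- ifelse(sat, -L_labels * log(1 / (2 * L_labels)),
                -L_labels * log(1 - k_observed / L_labels))
  as.numeric(out)
}
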