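# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / exhaustive search, never through the package's
# own code paths.

# fragment tibble shorthand for hand-built cases
frag <- function(chrom = "chr1", start, end, strand = "+", umi = "AAAAAA",
                 mapq = 60L, nm = 0L, cigar = NULL, clip3 = "",
                 sample_id = "s1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), umi = umi, mapq = as.integer(mapq),
                 strand = strand,
                 cigar = if (is.null(cigar)) paste0(end - start, "M") else cigar,
                 nm = as.integer(nm), clip3 = clip3, sample_id = sample_id)
}

# exhaustive connected-components dedup oracle: adjacency over ALL record
# pairs under (same coords+cigar+strand) AND Hamming<=1 (N never matches)
oracle_dedup_clusters <- function(frags, umi_mismatch = 1L) {
  n <- nrow(frags)
  ham <- function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    sum(va != vb | va == "N" | vb == "N")
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- frags$chrom[i] == frags$chrom[j] &&
      frags$start[i] == frags$start[j] && frags$end[i] == frags$end[j] &&
      frags$strand[i] == frags$strand[j] &&
      frags$cigar[i] == frags$cigar[j]
    if (same && ham(frags$umi[i], frags$umi[j]) <= umi_mismatch) {
      g <- igraph::add_edges(g, c(i, j))
    }
  }
  igraph::components(g)$no
}

# exhaustive maximum-base-pair oracle: plain recursion over all nested
# structures (no memoisation), min hairpin loop 3, pairs AU/GC/GU
oracle_max_pairs <- function(seq_rna) {
  chars <- strsplit(gsub("T", "U", toupper(seq_rna)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (ok(chars[k], chars[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        best <- max(best, left + rec(k + 1L, j - 1L) + 1L)
      }
    }
    best
  }
  n <- length(chars)
  if (n < 5) 0L else rec(1L, n)
}

random_frag_instance <- function(n, seed, n_positions = 5, umi_pool = NULL) {
  set.seed(seed)
  if (is.null(umi_pool)) {
    # small UMI pool so Hamming-1 neighbours actually occur
    base <- c("AAAAAA", "AAAAAT", "AAAATT", "CCCCCC", "CCCCCG", "GGGGGG")
    umi_pool <- base
  }
  starts <- sample(seq(0, 1000, by = 50), n_positions)
  s <- sample(starts, n, replace = TRUE)
  frag(start = s, end = s + 100L,
       strand = sample(c("+", "-"), n, TRUE),
       umi = sample(umi_pool, n, TRUE))
}
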