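#' Fold an RNA sequence
#'
#' The built-in `"proxy"` engine maximises the number of nested base pairs
#' (Nussinov dynamic programming) with Watson-Crick and GU wobble pairs and
#' a minimum hairpin loop of 3 unpaired nt; its score is minus the pair
#' count, so lower = more paired, analogous to a minimum free energy. The
#' `"external"` engine shells out to `RNAfold` (ViennaRNA) when it is on the
#' PATH and returns its thermodynamic MFE in kcal/mol. T and U are
#' interchangeable on input; reports use U.
#'
#' @param sequence a single RNA/DNA sequence over A/C/G/T/U, length >= 5.
#' @param engine `"proxy"` (default) or `"external"`.
#' @return A `cf_fold` object: `sequence` (RNA alphabet), `structure`
#'   (dot-bracket, same length), `score` (proxy: -pairs; external: MFE),
#'   `n_pairs`, `engine`.
#' @export
#' @examples
#' fold_rna("GGGGAAAACCCC")$structure  # "((((....))))"
fold_rna <- function(sequence, engine = c("proxy", "external")) {
  engine <- match.arg(engine)
  seq_rna <- toupper(gsub("T", "U", sequence))
  if (grepl("[^ACGU]", seq_rna)) {
    abort("sequence contains non-nucleotide characters")
  }
  if (nchar(seq_rna) < 5) abort("sequence must be at least 5 nt")

  if (engine == "external") {
    rnafold <- Sys.which("RNAfold")
    if (rnafold == "") abort("RNAfold not found on PATH; use engine='proxy'")
    out <- system2(rnafold, args = "--noPS", input = seq_rna, stdout = TRUE)
    sline <- out[2]
    db <- sub("^([.()]+).*$", "\\1", sline)
    mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", sline))
    return(structure(list(sequence = seq_rna, structure = db, score = mfe,
                          n_pairs = sum(strsplit(db, "")[[1]] == "("),
                          engine = "external"), class = "cf_fold"))
  }

  res <- nussinov_cpp(seq_rna, min_loop = 3L)
  structure(list(sequence = seq_rna,
                 structure = res$structure,
                 score = -res$n_pairs, n_pairs = res$n_pairs,
                 engine = "proxy"),
            class = "cf_fold")
}

#' @export
print.cf_fold <- function(x, ...) {
  cat("<cf_fold>", x$engine, "| score", x$score, "|", x$n_pairs, "pairs\n")
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

# sense-strand sequence of a 0-based half-open genomic interval
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  seqs <- if (inherits(genome, "cf_genome")) genome$seq else genome
  s <- Biostrings::subseq(seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Classify peaks as full-length excised intron RNAs
#'
#' A peak is a full-length excised intron RNA when it coincides with an
#' annotated intron (both boundaries within `tol` nt, default exact), the
#' intron's sense-strand boundaries are 5' GU and 3' AG (genomic GT..AG),
#' and at least `min_reads` deduplicated fragments span the complete intron
#' - start and end exactly at the intron boundaries on the gene strand.
#' Each call also reports the fold of the intron sequence and the
#' non-templated 3' tails observed on the full-length fragments.
#'
#' @param peaks peak tibble (`peak_id`, `chrom`, `start`, `end`, `strand`).
#' @param frags deduplicated fragment tibble.
#' @param introns annotated intron tibble (`intron_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param genome a `cf_genome` or named [Biostrings::DNAStringSet].
#' @param min_reads minimum exact full-length fragments (default 5).
#' @param tol boundary tolerance in nt when matching a peak to an intron.
#' @param engine folding engine passed to [fold_rna()].
#' @return A tibble, one row per peak: intron coordinates (NA when the peak
#'   matches no annotated intron), `n_full_length_reads`, `boundary_5p`,
#'   `boundary_3p` (RNA alphabet), `intron_length`, `fold_score`,
#'   `fold_structure`, `tails` (comma-joined `tail:count`), and
#'   `classification` (`full_length_excised_intron` / `not_intron`).
#' @export
call_introns <- function(peaks, frags, introns, genome, min_reads = 5L,
                         tol = 0L, engine = "proxy") {
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    base <- tibble(peak_id = p$peak_id, intron_id = NA_character_,
                   intron_start = NA_integer_, intron_end = NA_integer_,
                   strand = p$strand, n_full_length_reads = 0L,
                   boundary_5p = NA_character_, boundary_3p = NA_character_,
                   intron_length = NA_integer_, fold_score = NA_real_,
                   fold_structure = NA_character_, tails = "",
                   classification = "not_intron")
    hit <- introns %>%
      filter(.data$chrom == p$chrom,
             abs(.data$start - p$start) <= tol,
             abs(.data$end - p$end) <= tol)
    if (nrow(hit) == 0) return(base)
    iv <- hit[1, ]

    full <- frags %>%
      filter(.data$chrom == iv$chrom, .data$start == iv$start,
             .data$end == iv$end, .data$strand == iv$strand)
    sense <- genome_seq(genome, iv$chrom, iv$start, iv$end, iv$strand)
    sense_rna <- gsub("T", "U", sense)
    b5 <- substr(sense_rna, 1, 2)
    b3 <- substr(sense_rna, nchar(sense_rna) - 1, nchar(sense_rna))
    fold <- fold_rna(sense_rna, engine = engine)

    tails <- call_tails(full, iv, genome)
    tail_str <- if (nrow(tails) == 0) "" else
      paste(sprintf("%s:%d", tails$tail, tails$n), collapse = ",")

    cls <- if (b5 == "GU" && b3 == "AG" && nrow(full) >= min_reads) {
      "full_length_excised_intron"
    } else "not_intron"
    base %>% mutate(
      intron_id = iv$intron_id, intron_start = iv$start,
      intron_end = iv$end, strand = iv$strand,
      n_full_length_reads = nrow(full),
      boundary_5p = b5, boundary_3p = b3,
      intron_length = iv$end - iv$start,
      fold_score = fold$score, fold_structure = fold$structure,
      tails = tail_str, classification = cls)
  })
}

#' Tally non-templated 3' tails over a reference interval
#'
#' Inspects the 3'-soft-clipped bases (1-2 nt) of fragments whose 3'
#' terminus matches the interval's 3' end on the interval strand; a clip
#' that differs from the templated genomic continuation downstream of the
#' interval is reported as a non-templated tail (RNA alphabet, so a clipped
#' T is a U tail). A clip matching the genome is templated read-through,
#' never a tail.
#'
#' @param frags fragment tibble with a `clip3` column.
#' @param interval one-row tibble/list with `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome a `cf_genome` or named [Biostrings::DNAStringSet].
#' @return A tibble `tail`, `n`, sorted by count. If `clip3` is absent a
#'   warning is raised and an empty tibble returned.
#' @export
call_tails <- function(frags, interval, genome) {
  empty <- tibble(tail = character(0), n = integer(0))
  if (!"clip3" %in% names(frags)) {
    warn("no clip3 column; 3' tails unavailable")
    return(empty)
  }
  at_end <- if (interval$strand == "+") {
    frags %>% filter(.data$chrom == interval$chrom,
                     .data$end == interval$end)
  } else {
    frags %>% filter(.data$chrom == interval$chrom,
                     .data$start == interval$start)
  }
  clips <- at_end$clip3[!is.na(at_end$clip3) & at_end$clip3 != "" &
                          nchar(at_end$clip3) <= 2]
  if (length(clips) == 0) return(empty)

  seqs <- if (inherits(genome, "cf_genome")) genome$seq else genome
  chrom_len <- length(seqs[[interval$chrom]])
  templ <- vapply(clips, function(cl) {
    w <- nchar(cl)
    if (interval$strand == "+") {
      if (interval$end + w > chrom_len) return(FALSE)
      g <- genome_seq(genome, interval$chrom, interval$end,
                      interval$end + w, "+")
    } else {
      if (interval$start - w < 0) return(FALSE)
      g <- genome_seq(genome, interval$chrom, interval$start - w,
                      interval$start, "-")
    }
    toupper(cl) == g
  }, logical(1))

  tails <- gsub("T", "U", toupper(clips[!templ]))
  if (length(tails) == 0) return(empty)
  tibble(tail = tails) %>% count(.data$tail, name = "n") %>%
    arrange(desc(.data$n))
}

#' Detect RNAs with discrete 5' and 3' ends
#'
#' For each peak, finds the modal (start, end) pair among the fragments
#' overlapping it on the peak strand; the peak is a discrete-end RNA when
#' strictly more than half of those fragments share that exact pair of
#' termini.
#'
#' @param peaks peak tibble.
#' @param frags deduplicated fragment tibble.
#' @return A tibble per peak: `peak_id`, `n_fragments`, `modal_start`,
#'   `modal_end`, `fraction_modal`, `is_discrete`. Peaks with no
#'   overlapping fragment get NA fields.
#' @export
call_discrete_ends <- function(peaks, frags) {
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    f <- frags %>%
      filter(.data$chrom == p$chrom, .data$strand == p$strand,
             .data$start < p$end, .data$end > p$start)
    if (nrow(f) == 0) {
      return(tibble(peak_id = p$peak_id, n_fragments = 0L,
                    modal_start = NA_integer_, modal_end = NA_integer_,
                    fraction_modal = NA_real_, is_discrete = NA))
    }
    ends <- f %>% count(.data$start, .data$end, sort = TRUE)
    tibble(peak_id = p$peak_id, n_fragments = nrow(f),
           modal_start = ends$start[1], modal_end = ends$end[1],
           fraction_modal = ends$n[1] / nrow(f),
           is_discrete = ends$n[1] / nrow(f) > 0.5)
  })
}
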