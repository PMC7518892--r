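#' Simulate a UMI-tagged cell-free fragment library
#'
#' Emits one sample's worth of deduplicatable fragment records over a
#' synthetic genome, emulating a TGIRT-seq plasma library after alignment and
#' projection to template coordinates. A `"dna"` (alkaline-hydrolysis
#' control) sample is uniform background coverage on both strands. An
#' `"rna"` (DNase-treated plasma) sample adds, on top of its background:
#' protein-protected fragments concentrated inside the planted peak intervals
#' on the feature strand; tandem-repeat fragments whose strand is drawn with
#' a per-locus (+)-strand probability sampled around the locus's
#' `theta_plus` (a Beta draw, giving the hierarchical structure the
#' Empirical Bayes strand-bias model assumes); and full-length excised-intron
#' fragments whose coordinates match the planted intron exactly, a fraction
#' of which carry short non-templated 3' tails.
#'
#' Each molecule gets a random unique molecular identifier (UMI). PCR
#' duplication re-emits molecules so that the expected record count is
#' `1 / (1 - dup_rate)` per molecule; a duplicate's UMI is resampled with a
#' single-base error at rate `umi_error_rate`.
#'
#' @param genome a `cf_genome` from [synth_genome()].
#' @param role `"rna"` or `"dna"` (baseline control).
#' @param n_background number of background molecules.
#' @param peak_frags molecules per planted peak (recycled over peaks).
#' @param repeat_frags molecules per repeat locus (recycled).
#' @param intron_frags exact full-length molecules per planted intron
#'   (recycled).
#' @param intron_tail_frac fraction of intron molecules given a 1-nt
#'   non-templated 3' tail (U as genomic T, or A).
#' @param frag_len_mean,frag_len_sd,frag_len_min fragment-length model (nt).
#' @param umi_len UMI length in nt; the library design uses 6 randomized
#'   nucleotides.
#' @param dup_rate PCR duplicate rate in [0, 1).
#' @param umi_error_rate per-duplicate probability of a 1-nt UMI error.
#' @param repeat_theta_conc concentration of the Beta draw around each repeat
#'   locus's `theta_plus`; larger means tighter.
#' @param mapq,nm MAPQ and mismatch count assigned to every record (defaults
#'   pass the high-quality filter); individual records can be degraded
#'   afterwards for filter tests.
#' @param sample_id sample label recorded on every record.
#' @param seed integer random seed.
#'
#' @return A tibble of fragment records with columns `chrom`, `start`, `end`
#'   (0-based half-open), `umi`, `mapq`, `strand`, `cigar`, `nm`, `clip3`
#'   (3'-soft-clipped bases, `""` if none), `sample_id`, and `origin`
#'   (which planted element the molecule came from, for truth checks). The
#'   number of distinct molecules per origin is attached as attribute
#'   `"molecules"`.
#' @export
#' @examples
#' g <- synth_genome(chrom_length = 20000, n_genes = 2, n_peaks = 3, seed = 1)
#' fr <- synth_fragments(g, role = "rna", n_background = 500, seed = 1)
#' dplyr::count(fr, origin)
synth_fragments <- function(genome,
                            role = c("rna", "dna"),
                            n_background = 2000L,
                            peak_frags = 30L,
                            repeat_frags = 100L,
                            intron_frags = 10L,
                            intron_tail_frac = 0.3,
                            frag_len_mean = 120,
                            frag_len_sd = 30,
                            frag_len_min = 30L,
                            umi_len = 6L,
                            dup_rate = 0,
                            umi_error_rate = 0.05,
                            repeat_theta_conc = 50,
                            mapq = 60L,
                            nm = 0L,
                            sample_id = "s1",
                            seed = 1L) {
  stopifnot(inherits(genome, "cf_genome"))
  role <- match.arg(role)
  if (sum(genome$chrom_lengths) == 0) abort("empty genome")
  if (n_background < 0 || dup_rate < 0 || dup_rate >= 1) {
    abort("n_background must be >= 0 and dup_rate in [0, 1)")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  chrom <- names(genome$chrom_lengths)[1]
  chrom_len <- genome$chrom_lengths[[1]]

  mol <- list(background_molecules(chrom, chrom_len, n_background,
                                   frag_len_mean, frag_len_sd, frag_len_min))

  if (role == "rna") {
    pk <- genome$peaks_truth
    if (nrow(pk) > 0 && any(peak_frags > 0)) {
      counts <- rep_len(as.integer(peak_frags), nrow(pk))
      mol <- c(mol, list(peak_molecules(pk, counts, frag_len_mean,
                                        frag_len_sd, frag_len_min)))
    }
    rp <- genome$repeats
    if (nrow(rp) > 0 && any(repeat_frags > 0)) {
      counts <- rep_len(as.integer(repeat_frags), nrow(rp))
      mol <- c(mol, list(repeat_molecules(rp, counts, repeat_theta_conc,
                                          frag_len_mean, frag_len_sd,
                                          frag_len_min, dna = FALSE)))
    }
    iv <- genome$introns
    if (nrow(iv) > 0 && any(intron_frags > 0)) {
      counts <- rep_len(as.integer(intron_frags), nrow(iv))
      mol <- c(mol, list(intron_molecules(iv, counts, intron_tail_frac)))
    }
  } else {
    # DNA control also covers repeat loci, strand-balanced
    rp <- genome$repeats
    if (nrow(rp) > 0 && any(repeat_frags > 0)) {
      counts <- rep_len(as.integer(repeat_frags), nrow(rp))
      mol <- c(mol, list(repeat_molecules(rp, counts, repeat_theta_conc,
                                          frag_len_mean, frag_len_sd,
                                          frag_len_min, dna = TRUE)))
    }
  }

  mol <- bind_rows(mol)
  mol$umi <- random_umis(nrow(mol), umi_len)
  mol$mapq <- as.integer(mapq)
  mol$nm <- as.integer(nm)
  mol$cigar <- paste0(mol$end - mol$start, "M")

  # PCR duplication: geometric number of extra records per molecule
  n_extra <- stats::rgeom(nrow(mol), prob = 1 - dup_rate)
  rec <- mol[rep(seq_len(nrow(mol)), 1L + n_extra), ]
  is_dup <- duplicated(rep(seq_len(nrow(mol)), 1L + n_extra))
  err <- is_dup & runif(nrow(rec)) < umi_error_rate
  rec$umi[err] <- vapply(rec$umi[err], mutate_umi_1nt, character(1))

  out <- rec %>%
    mutate(sample_id = sample_id) %>%
    select("chrom", "start", "end", "umi", "mapq", "strand", "cigar", "nm",
           "clip3", "sample_id", "origin") %>%
    as_tibble()
  attr(out, "molecules") <- mol %>% count(.data$origin, name = "n_molecules")
  out
}

background_molecules <- function(chrom, chrom_len, n, len_mean, len_sd,
                                 len_min) {
  if (n == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), clip3 = character(0),
                  origin = character(0)))
  }
  len <- pmin(draw_frag_lengths(n, len_mean, len_sd, len_min), chrom_len)
  start <- vapply(chrom_len - len, function(m) sample.int(m + 1L, 1L) - 1L,
                  integer(1))
  tibble(chrom = chrom, start = start, end = start + len,
         strand = sample(c("+", "-"), n, replace = TRUE),
         clip3 = "", origin = "background")
}

peak_molecules <- function(peaks, counts, len_mean, len_sd, len_min) {
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    n <- counts[i]
    if (n == 0) return(NULL)
    w <- p$end - p$start
    len <- pmin(draw_frag_lengths(n, len_mean, len_sd, len_min), w)
    start <- p$start +
      vapply(w - len, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    tibble(chrom = p$chrom, start = start, end = start + len,
           strand = p$strand, clip3 = "", origin = p$peak_id)
  })
}

repeat_molecules <- function(repeats, counts, conc, len_mean, len_sd,
                             len_min, dna) {
  purrr::map_dfr(seq_len(nrow(repeats)), function(i) {
    r <- repeats[i, ]
    n <- counts[i]
    if (n == 0) return(NULL)
    theta <- if (dna) 0.5 else draw_locus_theta(r$theta_plus, conc)
    w <- r$end - r$start
    len <- pmin(draw_frag_lengths(n, len_mean, len_sd, len_min), w)
    start <- r$start +
      vapply(w - len, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    tibble(chrom = r$chrom, start = start, end = start + len,
           strand = if_else(runif(n) < theta, "+", "-"),
           clip3 = "", origin = r$repeat_id)
  })
}

# locus-level (+)-strand probability: Beta centred on theta_plus; the
# degenerate ends 0 and 1 are kept exact
draw_locus_theta <- function(theta_plus, conc) {
  if (theta_plus <= 0 || theta_plus >= 1) return(theta_plus)
  rbeta(1, conc * theta_plus, conc * (1 - theta_plus))
}

intron_molecules <- function(introns, counts, tail_frac) {
  purrr::map_dfr(seq_len(nrow(introns)), function(i) {
    iv <- introns[i, ]
    n <- counts[i]
    if (n == 0) return(NULL)
    tails <- if_else(runif(n) < tail_frac,
                     sample(c("T", "A"), n, replace = TRUE), "")
    tibble(chrom = iv$chrom, start = iv$start, end = iv$end,
           strand = iv$strand, clip3 = tails,
           origin = iv$intron_id)
  })
}

mutate_umi_1nt <- function(umi) {
  pos <- sample.int(nchar(umi), 1L)
  cur <- substr(umi, pos, pos)
  substr(umi, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  umi
}

#' Write fragment records as a headerless BED-like TSV
#'
#' Column order: chrom, start, end, UMI (name), MAPQ (score), strand, CIGAR,
#' NM, 3'-clip, sample id. [read_fragments()] reads this layout back.
#'
#' @param frags fragment tibble from [synth_fragments()] or compatible.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  check_fragment_cols(frags, c("chrom", "start", "end", "umi", "mapq",
                               "strand", "cigar", "nm"))
  if (!"clip3" %in% names(frags)) frags$clip3 <- ""
  if (!"sample_id" %in% names(frags)) frags$sample_id <- "s1"
  out <- frags %>%
    mutate(clip3 = if_else(.data$clip3 == "" | is.na(.data$clip3),
                           ".", .data$clip3)) %>%
    select("chrom", "start", "end", "umi", "mapq", "strand", "cigar",
           "nm", "clip3", "sample_id")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
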