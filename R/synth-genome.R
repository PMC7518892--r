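#' Build a synthetic cell-free RNA study genome
#'
#' Constructs a toy genome with the structural features the cfRNA peak-calling
#' analysis assumes: multi-exon gene models, planted protein-protected peak
#' intervals inside gene bodies, planted RBP binding sites overlapping a
#' subset of those peaks, tandem-repeat loci with per-locus strand-bias
#' parameters, short GU..AG introns (the genomic sense strand reads GT..AG),
#' and a per-base conservation track. Every planted element is returned as a
#' tidy truth table so downstream recovery can be scored exactly.
#'
#' Layout is sequential and non-overlapping: genes, then repeat loci, are
#' placed left to right with random gaps, so no two planted elements collide
#' and all intervals lie within chromosome bounds. Planted introns are given
#' a stem-loop interior (a perfect inverted repeat around a short loop) so
#' that structure-aware classifiers have true positives to find.
#'
#' @param chrom_length length of the single synthetic chromosome in nt.
#' @param n_genes number of multi-exon genes to plant.
#' @param n_peaks number of protein-protected peak intervals, placed inside
#'   gene bodies (exonic space) on the gene strand.
#' @param peak_width_range inclusive range of planted peak widths (nt);
#'   defaults to 50--300 nt, the size range of protein-protected fragments.
#' @param n_rbp_peaks how many planted peaks also receive an overlapping RBP
#'   binding-site annotation (capped at `n_peaks`).
#' @param n_hairpin_peaks how many planted peaks get a stem-loop sequence
#'   written into the genome under them (for structure-enrichment tests).
#' @param repeat_units character vector of tandem-repeat unit sequences; one
#'   locus is planted per element.
#' @param repeat_copies tandem copy number per repeat locus (recycled).
#' @param repeat_theta_plus per-locus probability that an RNA fragment over
#'   the locus is on the (+) strand; recycled; each must lie in [0, 1].
#' @param intron_lengths lengths of planted introns (nt); each must lie in
#'   [73, 210], the size range of plasma full-length excised intron RNAs.
#' @param conservation_bin width (nt) of the conservation-track bins.
#' @param seed integer random seed; the same spec and seed give an identical
#'   genome.
#'
#' @return An object of class `cf_genome`: a list with elements `seq`
#'   (a [Biostrings::DNAStringSet]), `chrom_lengths`, and tibbles `genes`,
#'   `exons`, `introns`, `peaks_truth`, `rbp_sites`, `repeats`,
#'   `conservation`. All coordinates are 0-based half-open.
#' @export
#' @examples
#' g <- synth_genome(chrom_length = 20000, n_genes = 2, n_peaks = 3, seed = 1)
#' g$peaks_truth
synth_genome <- function(chrom_length = 100000L,
                         n_genes = 6L,
                         n_peaks = 20L,
                         peak_width_range = c(50L, 300L),
                         n_rbp_peaks = 10L,
                         n_hairpin_peaks = 0L,
                         repeat_units = c("CCG", "TTC", "CATTC", "TTAGGG"),
                         repeat_copies = 30L,
                         repeat_theta_plus = 0.5,
                         intron_lengths = c(90L, 120L, 150L, 200L),
                         conservation_bin = 50L,
                         seed = 1L) {
  stopifnot(chrom_length > 5000, n_genes >= 1, n_peaks >= 0)
  if (any(repeat_theta_plus < 0 | repeat_theta_plus > 1)) {
    abort("repeat_theta_plus values must lie in [0, 1]")
  }
  if (length(intron_lengths) > 0 &&
      any(intron_lengths < 73 | intron_lengths > 210)) {
    abort("planted intron lengths must lie in [73, 210] nt")
  }
  if (any(grepl("[^ACGT]", repeat_units))) {
    abort("repeat units must be over the alphabet {A,C,G,T}")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  chrom <- "chrS"
  base <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))

  n_repeats <- length(repeat_units)
  repeat_copies <- rep_len(as.integer(repeat_copies), n_repeats)
  repeat_theta_plus <- rep_len(repeat_theta_plus, n_repeats)
  intron_lengths <- as.integer(intron_lengths)

  # -- sequential layout: genes first, then repeat loci ----------------------
  repeat_span <- sum(nchar(repeat_units) * repeat_copies) + 200L * n_repeats
  gene_space <- chrom_length - repeat_span - 1000L
  gene_len <- (gene_space %/% n_genes) - 200L
  if (gene_len < 2000L) abort("chromosome too short for the requested layout")

  gene_strands <- rep_len(c("+", "-"), n_genes)
  genes <- tibble(
    gene_id = sprintf("gene%02d", seq_len(n_genes)),
    chrom = chrom,
    start = as.integer(500L + (seq_len(n_genes) - 1L) * (gene_len + 200L)),
    strand = gene_strands
  ) %>%
    mutate(end = .data$start + gene_len)

  # distribute introns over genes round-robin; exons fill the remainder
  intron_gene <- if (length(intron_lengths) > 0) {
    rep_len(seq_len(n_genes), length(intron_lengths))
  } else integer(0)

  empty_introns <- tibble(intron_id = character(0), gene_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          length = integer(0))
  introns <- purrr::map_dfr(seq_along(intron_lengths), function(i) {
    g <- genes[intron_gene[i], ]
    # spread introns along the gene body, away from gene ends
    k <- sum(intron_gene[seq_len(i)] == intron_gene[i])  # index within gene
    anchor <- g$start + as.integer(gene_len * k / 5) + 300L
    tibble(intron_id = sprintf("intron%02d", i),
           gene_id = g$gene_id, chrom = chrom,
           start = anchor, end = anchor + intron_lengths[i],
           strand = g$strand, length = intron_lengths[i])
  })
  if (nrow(introns) == 0) introns <- empty_introns
  if (nrow(introns) > 0 && any(introns$end > genes$end[intron_gene])) {
    abort("intron layout exceeds gene bounds; reduce intron count")
  }

  # exons: gene body minus introns
  exons <- purrr::map_dfr(seq_len(n_genes), function(gi) {
    g <- genes[gi, ]
    ints <- introns %>% filter(.data$gene_id == g$gene_id) %>%
      arrange(.data$start)
    bounds <- c(g$start, rbind(ints$start, ints$end), g$end)
    starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    tibble(gene_id = g$gene_id,
           exon_id = sprintf("%s.e%d", g$gene_id, seq_along(starts)),
           chrom = chrom, start = as.integer(starts), end = as.integer(ends),
           strand = g$strand)
  })

  # planted peaks: inside exons, non-overlapping, on the gene strand
  peaks_truth <- plant_peaks(exons, n_peaks, peak_width_range, introns)
  if (n_peaks > 0 && nrow(peaks_truth) < n_peaks) {
    abort("could not place all requested peaks without overlap; enlarge genome")
  }

  # RBP sites overlap the first n_rbp_peaks planted peaks (jittered edges)
  n_rbp_peaks <- min(n_rbp_peaks, nrow(peaks_truth))
  rbp_sites <- if (n_rbp_peaks > 0) {
    pk <- peaks_truth[seq_len(n_rbp_peaks), ]
    tibble(
      name = sprintf("RBP%02d", seq_len(n_rbp_peaks)),
      chrom = chrom,
      start = pmax(pk$start - sample(0:20, n_rbp_peaks, TRUE), 0L),
      end = pk$end + sample(0:20, n_rbp_peaks, TRUE),
      strand = pk$strand
    )
  } else {
    tibble(name = character(0), chrom = character(0),
           start = integer(0), end = integer(0), strand = character(0))
  }

  # repeat loci after the last gene
  empty_repeats <- tibble(repeat_id = character(0), unit = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          n_copies = integer(0), theta_plus = numeric(0))
  rep_cursor <- max(genes$end) + 500L
  repeats <- purrr::map_dfr(seq_len(n_repeats), function(ri) {
    w <- nchar(repeat_units[ri]) * repeat_copies[ri]
    locus <- tibble(repeat_id = sprintf("rep%02d", ri),
                    unit = repeat_units[ri], chrom = chrom,
                    start = rep_cursor, end = rep_cursor + w,
                    strand = "+", n_copies = repeat_copies[ri],
                    theta_plus = repeat_theta_plus[ri])
    rep_cursor <<- rep_cursor + w + 200L
    locus
  })
  if (nrow(repeats) == 0) repeats <- empty_repeats
  if (n_repeats > 0 && max(repeats$end) > chrom_length) {
    abort("repeat loci exceed chromosome bounds")
  }

  # -- write planted sequence content ---------------------------------------
  for (ri in seq_len(nrow(repeats))) {
    r <- repeats[ri, ]
    unit_chars <- strsplit(r$unit, "")[[1]]
    base[(r$start + 1):r$end] <- rep(unit_chars, r$n_copies)
  }
  for (ii in seq_len(nrow(introns))) {
    iv <- introns[ii, ]
    base[(iv$start + 1):iv$end] <-
      plant_intron_seq(iv$length, iv$strand)
  }
  n_hairpin_peaks <- min(n_hairpin_peaks, nrow(peaks_truth))
  hairpin_ids <- character(0)
  if (n_hairpin_peaks > 0) {
    for (pi in seq_len(n_hairpin_peaks)) {
      p <- peaks_truth[pi, ]
      base[(p$start + 1):p$end] <- hairpin_seq(p$end - p$start)
      hairpin_ids <- c(hairpin_ids, p$peak_id)
    }
  }
  peaks_truth$hairpin <- peaks_truth$peak_id %in% hairpin_ids

  seqs <- Biostrings::DNAStringSet(setNames(paste(base, collapse = ""), chrom))

  n_bins <- ceiling(chrom_length / conservation_bin)
  conservation <- tibble(
    chrom = chrom,
    start = as.integer((seq_len(n_bins) - 1L) * conservation_bin),
    score = round(runif(n_bins), 3)
  ) %>%
    mutate(end = pmin(.data$start + conservation_bin, chrom_length),
           .after = "start")

  structure(list(
    seq = seqs,
    chrom_lengths = setNames(as.integer(chrom_length), chrom),
    genes = genes %>% select("gene_id", "chrom", "start", "end", "strand"),
    exons = exons,
    introns = introns,
    peaks_truth = peaks_truth,
    rbp_sites = rbp_sites,
    repeats = repeats,
    conservation = conservation,
    seed = seed
  ), class = "cf_genome")
}

# place n non-overlapping peaks inside exons, avoiding planted introns
plant_peaks <- function(exons, n_peaks, width_range, introns) {
  out <- tibble(peak_id = character(0), chrom = character(0),
                start = integer(0), end = integer(0), strand = character(0))
  if (n_peaks == 0) return(out)
  ex <- exons %>% filter(.data$end - .data$start >= width_range[2] + 20L)
  placed_start <- integer(0); placed_end <- integer(0)
  tries <- 0L
  while (nrow(out) < n_peaks && tries < n_peaks * 200L) {
    tries <- tries + 1L
    e <- ex[sample.int(nrow(ex), 1), ]
    w <- sample(seq(width_range[1], width_range[2]), 1)
    if (e$end - e$start - w < 1) next
    s <- e$start + sample.int(e$end - e$start - w, 1)
    if (any(s < placed_end + 50L & s + w + 50L > placed_start)) next
    placed_start <- c(placed_start, s); placed_end <- c(placed_end, s + w)
    out <- bind_rows(out, tibble(
      peak_id = sprintf("truth_peak%02d", nrow(out) + 1L),
      chrom = e$chrom, start = as.integer(s), end = as.integer(s + w),
      strand = e$strand))
  }
  out
}

# genomic plus-strand sequence for a planted intron whose RNA-sense strand
# begins GU (genomic GT) and ends AG, with a stem-loop interior
plant_intron_seq <- function(len, strand) {
  interior <- hairpin_seq(len - 4L)
  sense <- c("G", "T", interior, "A", "G")
  if (strand == "-") {
    sense <- rev(c(A = "T", C = "G", G = "C", T = "A")[sense])
  }
  unname(sense)
}

# perfect inverted repeat around a 4-nt loop, padded to width `len`
hairpin_seq <- function(len) {
  arm_len <- (len - 4L) %/% 2L
  arm <- sample(c("A", "C", "G", "T"), arm_len, replace = TRUE)
  rc_arm <- rev(c(A = "T", C = "G", G = "C", T = "A")[arm])
  pad <- sample(c("A", "C", "G", "T"), len - 2L * arm_len - 4L, replace = TRUE)
  unname(c(arm, "T", "T", "C", "G", rc_arm, pad))
}

#' Write a synthetic genome to disk as standard text formats
#'
#' Writes the genome FASTA, gene models as GTF, RBP sites and repeats as
#' BED6, the conservation track as bedGraph, and the planted-truth tables as
#' TSV, so file-based entry points can be exercised end to end.
#'
#' @param genome a `cf_genome` from [synth_genome()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
synth_genome_write <- function(genome, dir) {
  stopifnot(inherits(genome, "cf_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gtf"),
    rbp = file.path(dir, "rbp_sites.bed"),
    repeats = file.path(dir, "repeats.bed"),
    conservation = file.path(dir, "conservation.bedGraph"),
    truth_peaks = file.path(dir, "truth_peaks.tsv"),
    truth_repeats = file.path(dir, "truth_repeats.tsv"),
    truth_introns = file.path(dir, "truth_introns.tsv")
  )
  Biostrings::writeXStringSet(genome$seq, paths[["fasta"]])

  gtf_feats <- bind_rows(
    genome$exons %>% mutate(type = "exon", feat_id = .data$exon_id),
    genome$introns %>% mutate(type = "intron", feat_id = .data$intron_id)
  )
  gtf <- sprintf(
    '%s\tcfpeakr\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1"; feature_id "%s";',
    gtf_feats$chrom, gtf_feats$type, gtf_feats$start + 1L, gtf_feats$end,
    gtf_feats$strand, gtf_feats$gene_id, gtf_feats$gene_id, gtf_feats$feat_id)
  writeLines(gtf, paths[["genes"]])

  write_bed6 <- function(x, path, name_col) {
    readr::write_tsv(
      tibble(x$chrom, x$start, x$end, x[[name_col]], 0L, x$strand),
      path, col_names = FALSE)
  }
  write_bed6(genome$rbp_sites, paths[["rbp"]], "name")
  write_bed6(genome$repeats, paths[["repeats"]], "unit")
  readr::write_tsv(genome$conservation, paths[["conservation"]],
                   col_names = FALSE)
  readr::write_tsv(genome$peaks_truth, paths[["truth_peaks"]])
  readr::write_tsv(genome$repeats, paths[["truth_repeats"]])
  readr::write_tsv(genome$introns, paths[["truth_introns"]])
  invisible(paths)
}
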