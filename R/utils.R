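#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of desc distinct count pull
#'   rename if_else slice first
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
#' @importFrom stats ppois p.adjust rbeta rbinom rnorm runif optim dbeta
#'   quantile median setNames
NULL

# All genomic intervals in this package are 0-based half-open (BED
# convention): a fragment [start, end) covers bases start .. end-1.

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

#' Reverse-complement a DNA string
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length UMI strings. Any position
# involving N counts as a mismatch (N matches nothing).
umi_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb)) {
    abort("UMIs of unequal length cannot be compared")
  }
  sum(va != vb | va == "N" | vb == "N")
}

check_fragment_cols <- function(frags, need = c("chrom", "start", "end", "strand")) {
  missing <- setdiff(need, names(frags))
  if (length(missing) > 0) {
    abort(paste0("fragment table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(frags)
}

# Draw fragment lengths: normal(mean, sd) rounded, floored at `min`.
draw_frag_lengths <- function(n, mean, sd, min) {
  pmax(as.integer(round(rnorm(n, mean, sd))), as.integer(min))
}

random_umis <- function(n, width = 6L) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1, paste0, collapse = "")
}
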