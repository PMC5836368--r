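#' @importFrom stats rbinom runif setNames pnorm
#' @importFrom utils head tail write.table read.table
NULL

.datatable.aware <- TRUE

# residue alphabet used throughout (stop "*" and ambiguous "X" handled separately)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the A/C/G/T/N alphabet.
#'
#' @param x single nucleotide string (uppercase A/C/G/T/N)
#' @return the reverse complement as a single string
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chars <- strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]
  paste(rev(chars), collapse = "")
}

# split a nucleotide string into consecutive codons
split_codons <- function(nt) {
  n <- nchar(nt)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate codons under the standard genetic code
#'
#' Codons containing characters other than A/C/G/T translate to "X".
#'
#' @param codons character vector of 3-nt codons
#' @return character vector of single-letter amino acids ("*" for stop)
#' @keywords internal
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# extract the translation-orientation sequence of genomic interval [g0, g1)
# (0-based half-open) from a contig string
extract_oriented <- function(contig_seq, strand, g0, g1) {
  s <- substr(contig_seq, g0 + 1L, g1)
  if (strand == "-") revcomp(s) else s
}

# run a block of code under a fixed RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# junction identity key shared by the annotation and digestion modules
junction_key <- function(contig, strand, donor_end, acceptor_start) {
  paste(contig, strand, donor_end, acceptor_start, sep = "|")
}
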