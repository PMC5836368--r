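#' Amino-acid composition at exon boundaries
#'
#' Counts boundary residues (the residue whose codon contains the donor exon's
#' final coding base) and compares them with the background amino-acid usage
#' over all protein residues of the annotation. Two counting bases are
#' offered: `"occurrence"` counts one boundary residue per (transcript,
#' junction) pair, mirroring composition-by-exon counting across redundant
#' isoforms; `"unique"` counts each deduplicated genomic junction once,
#' the basis used for K/R-junction fractions. Background usage is always
#' computed redundantly across isoforms. Transcripts containing ambiguous (X)
#' residues are excluded from both boundary and background counts, as are
#' stop-codon boundary residues.
#'
#' @param transcripts list of `coding_transcript` objects
#' @param junctions unique-junction table from [enumerate_junctions()]
#'   (required for `mode = "unique"`)
#' @param mode counting basis, `"occurrence"` or `"unique"`
#' @return object of class `composition_report`: `mode`, `boundary_counts`,
#'   `boundary_freq`, `background_freq`, `fold_change` (boundary freq /
#'   background freq, `NA` where the background is 0), `n_boundary`
#' @export
boundary_residue_composition <- function(transcripts, junctions = NULL,
                                         mode = c("occurrence", "unique")) {
  mode <- match.arg(mode)
  clean <- transcripts[!vapply(transcripts, function(ct) ct$has_ambiguous,
                               logical(1))]
  if (mode == "occurrence") {
    occ <- junction_occurrences(clean)
    res <- occ$boundary_residue
  } else {
    if (is.null(junctions)) stop("mode 'unique' requires a junction table")
    res <- junctions$boundary_residue
  }
  res <- res[res %in% AA20]
  boundary_counts <- table(factor(res, levels = AA20))
  n_boundary <- length(res)
  bg <- unlist(strsplit(vapply(clean, function(ct) ct$protein, character(1)),
                        "", fixed = TRUE), use.names = FALSE)
  bg_counts <- table(factor(bg[bg %in% AA20], levels = AA20))
  boundary_freq <- if (n_boundary > 0) boundary_counts / n_boundary else
    boundary_counts * NA_real_
  background_freq <- bg_counts / sum(bg_counts)
  fold <- ifelse(background_freq > 0,
                 as.numeric(boundary_freq) / as.numeric(background_freq),
                 NA_real_)
  structure(list(mode = mode,
                 boundary_counts = setNames(as.integer(boundary_counts), AA20),
                 boundary_freq = setNames(as.numeric(boundary_freq), AA20),
                 background_freq = setNames(as.numeric(background_freq), AA20),
                 fold_change = setNames(fold, AA20),
                 n_boundary = n_boundary),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Boundary residue composition (", x$mode, " mode), n = ",
      x$n_boundary, "\n", sep = "")
  df <- as.data.frame(x)
  print(df[order(-df$fold_change), ], digits = 3)
  invisible(x)
}

#' @export
as.data.frame.composition_report <- function(x, ...) {
  data.frame(residue = AA20,
             boundary_count = x$boundary_counts,
             boundary_freq = x$boundary_freq,
             background_freq = x$background_freq,
             fold_change = x$fold_change,
             row.names = NULL)
}

#' Write a composition report as TSV
#' @param report a `composition_report`
#' @param path output path
#' @return invisibly, the path
#' @export
write_composition_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Partition unique junctions into K/R and other
#'
#' A junction is a K/R junction iff its boundary residue is lysine or
#' arginine, i.e. a tryptic cleavage site sits at (phase 0) or within 1-2 nt
#' of (phase 2/1) the splice site.
#'
#' @param junctions unique-junction table from [enumerate_junctions()]
#' @return list with `n_total`, `n_kr`, `fraction_kr`, and the two partitions
#'   `kr` and `other` (data.frames)
#' @export
classify_kr_junctions <- function(junctions) {
  is_kr <- junctions$boundary_residue %in% c("K", "R")
  list(n_total = nrow(junctions),
       n_kr = sum(is_kr),
       fraction_kr = if (nrow(junctions)) mean(is_kr) else NA_real_,
       kr = junctions[is_kr, , drop = FALSE],
       other = junctions[!is_kr, , drop = FALSE])
}

#' Position frequency matrices at splice sites
#'
#' Extracts, strand-corrected to translation orientation, the exon-side and
#' intron-side flanks of every junction's donor and acceptor site and tallies
#' per-position nucleotide frequencies. For canonical junctions the donor
#' intron side begins GT and the acceptor intron side ends AG. Junctions whose
#' flank overruns a contig are skipped with a warning. No pseudocount is
#' applied; positions with zero coverage are NA.
#'
#' @param junctions unique-junction table from [enumerate_junctions()]
#' @param genome named contig sequence vector
#' @param exon_flank,intron_flank flank widths in nt (defaults 10)
#' @return object of class `splice_pfm_pair`: two `splice_pfm` matrices
#'   (`donor`, `acceptor`), each a 4 x (exon_flank + intron_flank) probability
#'   matrix with offset column names (negative = upstream of the site in
#'   translation orientation, no position 0)
#' @export
splice_site_pfm <- function(junctions, genome, exon_flank = 10L,
                            intron_flank = 10L) {
  if (nrow(junctions) == 0L) stop("empty junction set")
  w <- exon_flank + intron_flank
  donor <- character(nrow(junctions))
  accep <- character(nrow(junctions))
  skipped <- 0L
  for (i in seq_len(nrow(junctions))) {
    ctg <- genome[[junctions$contig[i]]]
    if (is.null(ctg)) { skipped <- skipped + 1L; next }
    len <- nchar(ctg)
    st <- junctions$strand[i]
    d <- junctions$donor_end[i]; a <- junctions$acceptor_start[i]
    if (st == "+") {
      dw <- c(d - exon_flank + 1L, d + 1L + intron_flank)
      aw <- c(a - intron_flank, a + exon_flank)
    } else {
      dw <- c(d - intron_flank, d + exon_flank)
      aw <- c(a - exon_flank + 1L, a + 1L + intron_flank)
    }
    if (dw[1] < 0L || aw[1] < 0L || dw[2] > len || aw[2] > len) {
      skipped <- skipped + 1L
      next
    }
    donor[i] <- extract_oriented(ctg, st, dw[1], dw[2])
    accep[i] <- extract_oriented(ctg, st, aw[1], aw[2])
  }
  if (skipped > 0L) {
    warning(skipped, " junction(s) skipped: flank outside contig bounds",
            call. = FALSE)
  }
  donor <- donor[nzchar(donor)]
  accep <- accep[nzchar(accep)]
  if (length(donor) == 0L) stop("no junction with complete flanks")
  offsets_d <- c(seq(-exon_flank, -1L), seq(1L, intron_flank))
  offsets_a <- c(seq(-intron_flank, -1L), seq(1L, exon_flank))
  structure(list(donor = build_pfm(donor, w, offsets_d, "donor_5prime"),
                 acceptor = build_pfm(accep, w, offsets_a, "acceptor_3prime")),
            class = "splice_pfm_pair")
}

build_pfm <- function(strings, width, offsets, site_kind) {
  m <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
              ncol = width, byrow = TRUE)
  freq <- vapply(seq_len(width), function(j) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    n <- length(col)
    if (n == 0L) return(rep(NA_real_, 4L))
    as.numeric(table(factor(col, levels = c("A", "C", "G", "T")))) / n
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  colnames(freq) <- as.character(offsets)
  structure(list(site_kind = site_kind, offsets = offsets, freq = freq,
                 n_sites = length(strings)),
            class = "splice_pfm")
}

#' Trim a splice-site PFM to a narrow window around the site
#'
#' @param pfm a `splice_pfm`
#' @param flank positions kept on each side of the site (default 4)
#' @return a `splice_pfm` restricted to offsets in `[-flank, flank]`
#' @export
pfm_trim <- function(pfm, flank = 4L) {
  keep <- abs(pfm$offsets) <= flank
  structure(list(site_kind = pfm$site_kind, offsets = pfm$offsets[keep],
                 freq = pfm$freq[, keep, drop = FALSE], n_sites = pfm$n_sites),
            class = "splice_pfm")
}

#' Write a PFM as a position x nucleotide TSV
#' @param pfm a `splice_pfm`
#' @param path output path
#' @return invisibly, the path
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(offset = pfm$offsets, t(pfm$freq), row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Frame-adjusted cleavage-scenario probabilities at splice junctions
#'
#' Over unique junctions, computes the reading-frame (phase) usage, the
#' probability that the boundary residue is in `residue_set` conditional on
#' phase, and the frame-usage-weighted probability that a protease cleaving
#' after those residues recognises the splice site. Scenario 1 (phase 0 with a
#' K/R boundary residue) puts the cleavage site exactly at the splice site and
#' yields type 1/3 peptides; scenario 2 (phase 2) puts it 1 nt into the
#' acceptor exon, yielding type 2/4 peptides. Phase-1 K/R junctions (cleavage
#' 2 nt into the acceptor) are reported separately.
#'
#' @param junctions unique-junction table from [enumerate_junctions()]
#' @param residue_set cleavage residues (default lysine and arginine)
#' @return object of class `cleavage_scenarios`: `phase_usage` (length-3),
#'   `p_kr_given_phase`, `p_kr_adjusted`, `p_scenario1`, `p_scenario2`,
#'   `p_phase1_kr`, `n_junctions`
#' @export
cleavage_scenario_stats <- function(junctions, residue_set = c("K", "R")) {
  n <- nrow(junctions)
  ph <- factor(junctions$phase, levels = 0:2)
  hit <- junctions$boundary_residue %in% residue_set
  usage <- as.numeric(table(ph)) / n
  p_given <- vapply(0:2, function(p) {
    sel <- junctions$phase == p
    if (!any(sel)) NA_real_ else mean(hit[sel])
  }, numeric(1))
  contrib <- ifelse(is.na(p_given), 0, usage * p_given)
  structure(list(phase_usage = setNames(usage, paste0("phase", 0:2)),
                 p_kr_given_phase = setNames(p_given, paste0("phase", 0:2)),
                 p_kr_adjusted = sum(contrib),
                 p_scenario1 = mean(junctions$phase == 0L & hit),
                 p_scenario2 = mean(junctions$phase == 2L & hit),
                 p_phase1_kr = mean(junctions$phase == 1L & hit),
                 n_junctions = n),
            class = "cleavage_scenarios")
}

#' @export
print.cleavage_scenarios <- function(x, ...) {
  cat("Cleavage scenarios over", x$n_junctions, "unique junctions\n")
  cat("  phase usage:       ",
      paste(sprintf("%s=%.3f", names(x$phase_usage), x$phase_usage),
            collapse = "  "), "\n")
  cat("  P(K/R | phase):    ",
      paste(sprintf("%s=%.3f", names(x$p_kr_given_phase), x$p_kr_given_phase),
            collapse = "  "), "\n")
  cat(sprintf("  frame-adjusted P(K/R at site): %.3f\n", x$p_kr_adjusted))
  cat(sprintf("  scenario 1 (phase 0, cleave at site):    %.3f\n",
              x$p_scenario1))
  cat(sprintf("  scenario 2 (phase 2, cleave 1 nt into acceptor): %.3f\n",
              x$p_scenario2))
  cat(sprintf("  phase 1 K/R (cleave 2 nt into acceptor): %.3f\n",
              x$p_phase1_kr))
  invisible(x)
}

#' Write scenario statistics as JSON
#' @param stats a `cleavage_scenarios` object
#' @param path output path
#' @return invisibly, the path
#' @export
write_scenario_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Expected rate of within-exon peptide termini coinciding with an exon
#' boundary
#'
#' Closed-form expectation `2 / (median exon length - median peptide length)`
#' (both in amino acids) for the fraction of peptides, placed within exons,
#' whose start or end touches an exon boundary; capped at 1.
#'
#' @param median_peptide_len_aa median peptide length, amino acids
#' @param median_exon_len_aa median exon length, amino acids
#' @return the expected fraction (not percent)
#' @export
expected_boundary_terminus_rate <- function(median_peptide_len_aa,
                                            median_exon_len_aa) {
  denom <- median_exon_len_aa - median_peptide_len_aa
  if (denom <= 0) stop("median exon length must exceed median peptide length")
  min(1, 2 / denom)
}
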