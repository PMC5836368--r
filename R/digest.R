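#' Define a protease cleavage rule
#'
#' @param name enzyme name
#' @param residues amino acids whose peptide bond is cleaved
#' @param side `"C"` (cleave C-terminal of `residues`) or `"N"` (N-terminal)
#' @param blocked residues that suppress cleavage when sitting immediately
#'   C-terminal of the cut (classically proline for trypsin)
#' @return object of class `enzyme`
#' @export
enzyme <- function(name, residues, side = c("C", "N"), blocked = character(0)) {
  side <- match.arg(side)
  if (length(residues) == 0L) stop("cleavage residue set must be non-empty")
  structure(list(name = name, residues = toupper(residues), side = side,
                 blocked = toupper(blocked)),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s-terminal of %s%s>\n", x$name, x$side,
              paste(x$residues, collapse = ","),
              if (length(x$blocked))
                paste0(", blocked before ", paste(x$blocked, collapse = ","))
              else ""))
  invisible(x)
}

#' Protease preset definitions
#'
#' Two preset families are shipped. The `"paper"` family mirrors the cleavage
#' rules as commonly tabulated for junction-coverage comparisons: trypsin
#' C-terminal of K/R blocked by proline; Lys-C C-terminal of K; Glu-C
#' C-terminal of D; chymotrypsin C-terminal of F/Y/L/W/M with no proline
#' block; Asp-N N-terminal of D; Arg-C C-terminal of R. The `"conventional"`
#' family swaps in the textbook specificities that differ: Glu-C C-terminal of
#' E (and D), chymotrypsin blocked by proline. Which family matches a given
#' historical digest is an empirical question; the family is therefore an
#' explicit, required choice.
#'
#' @param family `"paper"` or `"conventional"`
#' @return named list of [enzyme()] objects (Trypsin, Chymotrypsin, GluC,
#'   LysC, AspN, ArgC)
#' @export
enzyme_presets <- function(family = c("paper", "conventional")) {
  family <- match.arg(family)
  if (family == "paper") {
    list(
      Trypsin = enzyme("Trypsin", c("K", "R"), "C", "P"),
      Chymotrypsin = enzyme("Chymotrypsin", c("F", "Y", "L", "W", "M"), "C"),
      GluC = enzyme("GluC", "D", "C"),
      LysC = enzyme("LysC", "K", "C"),
      AspN = enzyme("AspN", "D", "N"),
      ArgC = enzyme("ArgC", "R", "C"))
  } else {
    list(
      Trypsin = enzyme("Trypsin", c("K", "R"), "C", "P"),
      Chymotrypsin = enzyme("Chymotrypsin", c("F", "Y", "L", "W", "M"), "C", "P"),
      GluC = enzyme("GluC", c("E", "D"), "C"),
      LysC = enzyme("LysC", "K", "C"),
      AspN = enzyme("AspN", "D", "N"),
      ArgC = enzyme("ArgC", "R", "C"))
  }
}

# cleavage boundary positions: cut after residue b (1-based), b in 1..L-1
cleavage_sites <- function(aa, enz) {
  L <- length(aa)
  if (L < 2L) return(integer(0))
  b <- seq_len(L - 1L)
  hit <- if (enz$side == "C") aa[b] %in% enz$residues else
    aa[b + 1L] %in% enz$residues
  if (length(enz$blocked)) hit <- hit & !(aa[b + 1L] %in% enz$blocked)
  which(hit)
}

#' Digest one protein with a protease rule
#'
#' Enumerates every cleavage product with 0..`max_missed` internal missed
#' cleavage sites. At `max_missed = 0` the products tile the protein exactly.
#' Unknown amino-acid letters (X) are treated as non-cleavable.
#'
#' @param protein amino-acid string
#' @param enz an [enzyme()]
#' @param max_missed maximum internal missed cleavages (default 0)
#' @return data.frame: `sequence`, `start_res`, `end_res` (0-based half-open
#'   residue indices), `missed_cleavages`
#' @export
digest <- function(protein, enz, max_missed = 0L) {
  stopifnot(inherits(enz, "enzyme"), max_missed >= 0L)
  if (nchar(protein) == 0L) stop("empty protein")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cuts <- cleavage_sites(aa, enz)
  s <- c(1L, cuts + 1L)
  e <- c(cuts, length(aa))
  nseg <- length(s)
  out <- vector("list", max_missed + 1L)
  for (mm in 0:max_missed) {
    if (nseg < mm + 1L) break
    i <- seq_len(nseg - mm)
    out[[mm + 1L]] <- data.frame(
      sequence = substring(protein, s[i], e[i + mm]),
      start_res = s[i] - 1L, end_res = e[i + mm],
      missed_cleavages = mm, stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Digest every protein of an annotation
#'
#' @param transcripts list of `coding_transcript` objects
#' @param enz an [enzyme()]
#' @param max_missed maximum missed cleavages
#' @return data.table of peptide records with `pep_id` and `tx_id` columns
#' @export
digest_proteome <- function(transcripts, enz, max_missed = 0L) {
  dfs <- lapply(transcripts, function(ct) {
    d <- digest(ct$protein, enz, max_missed)
    d$tx_id <- ct$model$tx_id
    d
  })
  dt <- data.table::rbindlist(dfs)
  dt[, "pep_id" := seq_len(nrow(dt))]
  dt[]
}

#' Filter peptides by length and missed cleavages
#'
#' Length bounds are inclusive on both sides.
#'
#' @param records peptide table from [digest()] or [digest_proteome()]
#' @param min_len,max_len amino-acid length bounds (inclusive)
#' @param max_missed maximum missed cleavages retained
#' @return the filtered table
#' @export
filter_peptides <- function(records, min_len = 8L, max_len = 25L,
                            max_missed = 0L) {
  if (min_len > max_len) stop("min_len exceeds max_len")
  len <- nchar(records$sequence)
  records[len >= min_len & len <= max_len &
            records$missed_cleavages <= max_missed, , drop = FALSE]
}

#' Project peptides onto genomic block coordinates
#'
#' Maps each peptide's residue span through its transcript's codon-resolved
#' genome map. Blocks are maximal runs of genomically contiguous coding
#' nucleotides, stored in genomic order; a peptide spans a junction iff it has
#' two or more blocks separated by an intron. Per spanned junction, donor- and
#' acceptor-side coverage count the peptide nucleotides upstream/downstream of
#' the junction in translation orientation.
#'
#' @param records peptide table with `tx_id`, `start_res`, `end_res`
#' @param transcripts named list of `coding_transcript` objects
#' @return list with `peptides` (input plus `contig`, `strand`, `n_blocks`,
#'   `spans_junction`, `signature`, and a `blocks` list-column of genomic
#'   interval matrices) and `junctions` (long table: `pep_id`, `key`,
#'   `donor_nt`, `acceptor_nt` per spanned junction)
#' @export
project_peptides <- function(records, transcripts) {
  dt <- data.table::as.data.table(records)
  if (!"pep_id" %in% names(dt)) dt[, "pep_id" := seq_len(nrow(dt))]
  n <- nrow(dt)
  blocks <- vector("list", n)
  contig <- character(n); strand <- character(n)
  n_blocks <- integer(n); signature <- character(n)
  jlist <- vector("list", n)
  for (i in seq_len(n)) {
    ct <- transcripts[[dt$tx_id[i]]]
    if (is.null(ct)) stop("unknown transcript: ", dt$tx_id[i])
    s <- dt$start_res[i]; e <- dt$end_res[i]
    if (s < 0L || e > nchar(ct$protein) + as.integer(ct$has_stop_codon) ||
        e <= s) {
      stop("residue span outside protein for peptide ", dt$pep_id[i])
    }
    pos <- ct$cds_pos[(3L * s + 1L):(3L * e)]
    st <- ct$model$strand
    bl <- positions_to_blocks(pos, st)
    blocks[[i]] <- bl
    contig[i] <- ct$model$contig
    strand[i] <- st
    n_blocks[i] <- nrow(bl)
    signature[i] <- paste(ct$model$contig, st,
                          paste(bl[, 1], bl[, 2], sep = ":", collapse = ","),
                          sep = "|")
    step <- if (st == "-") -1L else 1L
    br <- which(diff(pos) != step)
    if (length(br)) {
      jlist[[i]] <- data.frame(
        pep_id = dt$pep_id[i],
        key = junction_key(ct$model$contig, st, pos[br], pos[br + 1L]),
        donor_nt = br, acceptor_nt = length(pos) - br,
        stringsAsFactors = FALSE)
    }
  }
  dt[, c("contig", "strand", "n_blocks", "spans_junction", "signature") :=
       list(contig, strand, n_blocks, n_blocks > 1L, signature)]
  dt[, "blocks" := blocks]
  pj <- data.table::rbindlist(jlist)
  if (nrow(pj) == 0L) pj <- empty_pep_junctions()
  list(peptides = dt[], junctions = pj)
}

empty_pep_junctions <- function() {
  dt <- data.table::data.table(pep_id = integer(0), jkey = character(0),
                               donor_nt = integer(0), acceptor_nt = integer(0))
  data.table::setnames(dt, "jkey", "key")
  dt
}

#' Collapse peptides to unique genomic mappings
#'
#' Groups projected peptides by sequence. Occurrences sharing one identical
#' genomic block set (isoform-shared locations) merge; a sequence is
#' `unique_genomic` iff all its occurrences collapse to a single genomic
#' location. One representative row per sequence is flagged
#' (`is_representative`); downstream detectability uses representative rows
#' with `unique_genomic = TRUE` only.
#'
#' @param projected output of [project_peptides()] (the `peptides` element or
#'   the full list)
#' @return the peptide table with `unique_genomic` and `is_representative`
#'   columns added
#' @export
collapse_unique <- function(projected) {
  dt <- if (is.list(projected) && !data.table::is.data.table(projected)) {
    data.table::as.data.table(projected$peptides)
  } else data.table::as.data.table(projected)
  nsig <- NULL; sequence_ <- NULL  # appease R CMD check
  dt[, "unique_genomic" := length(unique(signature)) == 1L, by = "sequence"]
  dt[, "is_representative" := seq_len(.N) == 1L, by = "sequence"]
  dt[]
}

#' Write unique peptides as BED12
#'
#' One record per representative peptide; blocks encode the exonic segments of
#' the peptide's genomic projection. The BED name field carries the peptide
#' sequence; the score is the missed-cleavage count.
#'
#' @param peptides collapsed peptide table from [collapse_unique()]
#'   (representative, uniquely mapped rows are written)
#' @param path output path
#' @return invisibly, the path
#' @export
write_peptides_bed12 <- function(peptides, path) {
  dt <- data.table::as.data.table(peptides)
  if ("is_representative" %in% names(dt)) {
    dt <- dt[dt$is_representative & dt$unique_genomic]
  }
  gr <- peptides_to_granges(dt)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# build a GRanges with a `blocks` column from a projected peptide table
peptides_to_granges <- function(dt) {
  if (nrow(dt) == 0L) {
    return(GenomicRanges::GRanges(blocks = IRanges::IRangesList()))
  }
  start0 <- vapply(dt$blocks, function(b) min(b[, 1]), integer(1))
  end0 <- vapply(dt$blocks, function(b) max(b[, 2]), integer(1))
  gr <- GenomicRanges::GRanges(
    seqnames = dt$contig,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = dt$strand)
  names(gr) <- dt$sequence
  S4Vectors::mcols(gr)$name <- dt$sequence
  S4Vectors::mcols(gr)$score <- dt$missed_cleavages
  S4Vectors::mcols(gr)$thick <- IRanges::ranges(gr)
  # blocks are 1-based and relative to the record start for BED export
  S4Vectors::mcols(gr)$blocks <- IRanges::IRangesList(
    lapply(seq_len(nrow(dt)), function(i) {
      b <- dt$blocks[[i]]
      IRanges::IRanges(start = b[, 1] - start0[i] + 1L, end = b[, 2] - start0[i])
    }))
  gr
}

#' Read observed peptides from BED12
#'
#' Accepts one record per peptide with blocks encoding exonic segments (the
#' interchange format emulating genome-mapped peptide-spectrum matches).
#'
#' @param path BED12 path
#' @return data.frame: `name`, `contig`, `strand`, and a `blocks` list-column
#'   of 0-based half-open genomic interval matrices in genomic order
#' @export
read_peptides_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  n <- length(gr)
  bl <- if (!is.null(S4Vectors::mcols(gr)$blocks)) {
    lapply(seq_len(n), function(i) {
      b <- S4Vectors::mcols(gr)$blocks[[i]]
      abs0 <- GenomicRanges::start(gr)[i] - 1L
      cbind(start = abs0 + IRanges::start(b) - 1L,
            end = abs0 + IRanges::end(b))
    })
  } else {
    lapply(seq_len(n), function(i) {
      cbind(start = GenomicRanges::start(gr)[i] - 1L,
            end = GenomicRanges::end(gr)[i])
    })
  }
  data.frame(name = if (!is.null(S4Vectors::mcols(gr)$name))
               S4Vectors::mcols(gr)$name else as.character(seq_len(n)),
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             blocks = I(bl), stringsAsFactors = FALSE)
}

#' Locate BED12 peptides on coding transcripts
#'
#' Matches each BED record's genomic blocks against the codon maps of the
#' coding transcripts on the same contig and strand. A record matches a
#' transcript when its nucleotides form a codon-aligned contiguous run of that
#' transcript's coding positions. Unmatched or frame-incompatible records are
#' skipped with a warning.
#'
#' @param bed data.frame from [read_peptides_bed12()]
#' @param transcripts named list of `coding_transcript` objects
#' @return projected peptide structure as from [project_peptides()] (with
#'   `n_skipped` attribute on the peptide table)
#' @export
match_bed_to_transcripts <- function(bed, transcripts) {
  idx_by_loc <- split(seq_along(transcripts),
                      vapply(transcripts, function(ct)
                        paste(ct$model$contig, ct$model$strand), character(1)))
  rows <- vector("list", nrow(bed))
  skipped <- 0L
  for (i in seq_len(nrow(bed))) {
    b <- bed$blocks[[i]]
    strand <- bed$strand[i]
    pos <- sequence(nvec = b[, "end"] - b[, "start"], from = b[, "start"],
                    by = 1L)
    if (strand == "-") pos <- rev(pos)
    hit <- NULL
    for (ti in idx_by_loc[[paste(bed$contig[i], strand)]]) {
      ct <- transcripts[[ti]]
      k <- match(pos[1], ct$cds_pos)
      if (is.na(k) || (k - 1L) %% 3L != 0L) next
      if (length(pos) %% 3L != 0L) next
      if (k + length(pos) - 1L > length(ct$cds_pos)) next
      if (!all(ct$cds_pos[k:(k + length(pos) - 1L)] == pos)) next
      hit <- list(tx_id = ct$model$tx_id, start_res = (k - 1L) %/% 3L,
                  end_res = (k - 1L) %/% 3L + length(pos) %/% 3L)
      break
    }
    if (is.null(hit)) { skipped <- skipped + 1L; next }
    ct <- transcripts[[hit$tx_id]]
    seqaa <- substr(ct$protein, hit$start_res + 1L, hit$end_res)
    rows[[i]] <- data.frame(sequence = seqaa, start_res = hit$start_res,
                            end_res = hit$end_res, missed_cleavages = 0L,
                            tx_id = hit$tx_id, name = bed$name[i],
                            stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning(skipped, " BED record(s) did not match any coding transcript",
            call. = FALSE)
  }
  recs <- data.table::rbindlist(rows)
  if (nrow(recs) == 0L) {
    out <- list(peptides = recs, junctions = data.table::data.table())
    attr(out$peptides, "n_skipped") <- skipped
    return(out)
  }
  out <- project_peptides(recs, transcripts)
  attr(out$peptides, "n_skipped") <- skipped
  out
}

#' Write a peptide table as TSV
#'
#' @param peptides collapsed peptide table
#' @param path output path
#' @return invisibly, the path
#' @export
write_peptides_tsv <- function(peptides, path) {
  dt <- data.table::as.data.table(peptides)
  cols <- intersect(c("sequence", "tx_id", "start_res", "missed_cleavages",
                      "n_blocks", "spans_junction", "unique_genomic"),
                    names(dt))
  write.table(as.data.frame(dt)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
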