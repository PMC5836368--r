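#' Read a genome FASTA into a named vector of contig sequences
#'
#' Loads every record of a FASTA file, uppercases soft-masked bases and
#' validates the alphabet. Sequences are returned as plain character strings
#' keyed by contig name (the first whitespace-delimited token of each header).
#'
#' @param fasta_source path to a FASTA file
#' @return named character vector of uppercase contig sequences
#' @export
read_genome <- function(fasta_source) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_source)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  contigs <- toupper(as.character(seqs))
  names(contigs) <- nm
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig(s) with characters outside A/C/G/T/N: ",
         paste(nm[bad], collapse = ", "))
  }
  if (any(nchar(contigs) == 0L)) stop("empty contig sequence in FASTA")
  contigs
}

#' Construct a transcript model
#'
#' A transcript model holds the exon structure and CDS bounds of one coding
#' transcript. All coordinates are 0-based, half-open, in genomic orientation.
#'
#' @param tx_id transcript identifier
#' @param gene_id gene identifier
#' @param contig contig name
#' @param strand "+" or "-"
#' @param exon_start,exon_end integer vectors of exon bounds, sorted in genomic
#'   order, non-overlapping
#' @param cds_start,cds_end genomic span of the translated region
#' @return an object of class `transcript_model`
#' @export
transcript_model <- function(tx_id, gene_id, contig, strand,
                             exon_start, exon_end, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_start) == length(exon_end))
  exon_start <- as.integer(exon_start)
  exon_end <- as.integer(exon_end)
  o <- order(exon_start)
  exon_start <- exon_start[o]; exon_end <- exon_end[o]
  if (any(exon_end <= exon_start)) stop(tx_id, ": empty exon")
  if (length(exon_start) > 1L &&
      any(exon_start[-1L] < exon_end[-length(exon_end)])) {
    stop(tx_id, ": overlapping exons")
  }
  structure(list(tx_id = tx_id, gene_id = gene_id, contig = contig,
                 strand = strand, exon_start = exon_start, exon_end = exon_end,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "transcript_model")
}

# per-exon coding segment bounds (0-based half-open); empty segments dropped
coding_segments <- function(model) {
  s <- pmax(model$exon_start, model$cds_start)
  e <- pmin(model$exon_end, model$cds_end)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

# total coding length in nt
cds_length <- function(model) {
  seg <- coding_segments(model)
  sum(seg[, "end"] - seg[, "start"])
}

validate_model <- function(model, genome = NULL) {
  if (model$cds_start >= model$cds_end) return("no CDS")
  seg <- coding_segments(model)
  if (nrow(seg) == 0L) return("CDS outside exons")
  # CDS bounds must fall inside the exon union
  inside <- function(p) any(p >= model$exon_start & p <= model$exon_end)
  if (!inside(model$cds_start) || !inside(model$cds_end)) {
    return("CDS bounds outside exon union")
  }
  if (cds_length(model) %% 3L != 0L) return("CDS length not divisible by 3")
  if (!is.null(genome)) {
    if (!model$contig %in% names(genome)) return("unknown contig")
    if (max(model$exon_end) > nchar(genome[[model$contig]])) {
      return("exon outside contig bounds")
    }
  }
  NULL
}

#' Read coding gene models from genePred or GTF
#'
#' Non-coding transcripts (no CDS) are dropped silently; transcripts whose CDS
#' length is not a multiple of 3, or whose exons fall outside the supplied
#' genome's contigs, are dropped with a warning.
#'
#' @param annotation_source path to the annotation file
#' @param format "genePred" (UCSC, >= 10 tab-separated columns with
#'   comma-terminated exon lists) or "GTF" (exon + CDS features keyed by
#'   `transcript_id`)
#' @param genome optional genome (as from [read_genome()]) used to reject
#'   transcripts whose exons overrun contig bounds
#' @return list of [transcript_model()] objects
#' @export
read_gene_models <- function(annotation_source, format = c("genePred", "GTF"),
                             genome = NULL) {
  format <- match.arg(format)
  models <- switch(format,
                   genePred = read_genepred(annotation_source),
                   GTF = read_gtf_models(annotation_source))
  keep <- list()
  for (m in models) {
    if (m$cds_start >= m$cds_end) next   # non-coding: dropped silently
    msg <- validate_model(m, genome)
    if (!is.null(msg)) {
      warning("dropping transcript ", m$tx_id, ": ", msg, call. = FALSE)
      next
    }
    keep[[m$tx_id]] <- m
  }
  keep
}

# UCSC genePred: name chrom strand txStart txEnd cdsStart cdsEnd exonCount
# exonStarts exonEnds [score name2 cdsStartStat cdsEndStat exonFrames]
read_genepred <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) stop("genePred record with fewer than 10 columns")
    starts <- as.integer(strsplit(f[9], ",", fixed = TRUE)[[1]])
    ends <- as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]])
    gene <- if (length(f) >= 12L && nzchar(f[12])) f[12] else f[1]
    transcript_model(tx_id = f[1], gene_id = gene, contig = f[2],
                     strand = f[3], exon_start = starts, exon_end = ends,
                     cds_start = as.integer(f[6]), cds_end = as.integer(f[7]))
  })
}

read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (!"transcript_id" %in% names(df)) stop("GTF lacks transcript_id attribute")
  out <- list()
  for (tx in unique(df$transcript_id)) {
    d <- df[df$transcript_id == tx, , drop = FALSE]
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cds
    cs <- if (nrow(cds)) min(cds$start) - 1L else 0L
    ce <- if (nrow(cds)) max(cds$end) else 0L
    gene <- if ("gene_id" %in% names(d) && !is.na(d$gene_id[1])) d$gene_id[1] else tx
    out[[tx]] <- transcript_model(
      tx_id = tx, gene_id = gene, contig = as.character(ex$seqnames[1]),
      strand = as.character(ex$strand[1]),
      exon_start = ex$start - 1L, exon_end = ex$end,
      cds_start = cs, cds_end = ce)
  }
  out
}

#' Build a coding transcript with codon-resolved genome mapping
#'
#' Splices the coding segments of a transcript model out of the genome,
#' corrects for strand, translates under the standard code, and records the
#' genomic position of every coding nucleotide in translation order. That
#' position vector (`cds_pos`) is the projection every downstream stage
#' (junction enumeration, peptide-to-genome mapping) is built on.
#'
#' @param model a [transcript_model()]
#' @param genome named contig sequence vector from [read_genome()]
#' @return an object of class `coding_transcript` with elements `model`,
#'   `cds_nt`, `protein` (terminal stop removed), `cds_pos` (0-based genomic
#'   position of each coding nt, translation order), `has_stop_codon`,
#'   `has_ambiguous`; or `NULL` (with a warning) for transcripts carrying an
#'   in-frame internal stop
#' @export
build_coding_transcript <- function(model, genome) {
  msg <- validate_model(model, genome)
  if (!is.null(msg)) stop(model$tx_id, ": ", msg)
  seqarr <- genome[[model$contig]]
  seg <- coding_segments(model)
  n <- nrow(seg)
  if (model$strand == "+") {
    pieces <- substring(seqarr, seg[, "start"] + 1L, seg[, "end"])
    cds_pos <- sequence(nvec = seg[, "end"] - seg[, "start"],
                        from = seg[, "start"], by = 1L)
  } else {
    ord <- rev(seq_len(n))
    pieces <- vapply(ord, function(i) {
      revcomp(substr(seqarr, seg[i, "start"] + 1L, seg[i, "end"]))
    }, character(1))
    cds_pos <- sequence(nvec = (seg[, "end"] - seg[, "start"])[ord],
                        from = (seg[, "end"] - 1L)[ord], by = -1L)
  }
  cds_nt <- paste(pieces, collapse = "")
  codons <- split_codons(cds_nt)
  aa <- translate_codons(codons)
  n_cod <- length(aa)
  has_stop <- aa[n_cod] == "*"
  body <- if (has_stop) aa[-n_cod] else aa
  if (any(body == "*")) {
    warning("dropping transcript ", model$tx_id, ": in-frame internal stop",
            call. = FALSE)
    return(NULL)
  }
  structure(list(model = model, cds_nt = cds_nt,
                 protein = paste(body, collapse = ""),
                 cds_pos = as.integer(cds_pos),
                 has_stop_codon = has_stop,
                 has_ambiguous = any(body == "X")),
            class = "coding_transcript")
}

#' Build all coding transcripts of an annotation
#'
#' @param models list of transcript models
#' @param genome genome from [read_genome()]
#' @return named list of `coding_transcript` objects (rejected transcripts
#'   dropped with warnings)
#' @export
build_coding_transcripts <- function(models, genome) {
  out <- lapply(models, function(m) build_coding_transcript(m, genome))
  out[!vapply(out, is.null, logical(1))]
}

# genomic codon blocks of residue i (1-based) as a 2-column matrix of 0-based
# half-open intervals in genomic order
residue_blocks <- function(ct, i) {
  pos <- ct$cds_pos[(3L * (i - 1L) + 1L):(3L * i)]
  positions_to_blocks(pos, ct$model$strand)
}

# turn a translation-order genomic position vector into genomic-order blocks
positions_to_blocks <- function(pos, strand) {
  step <- if (strand == "-") -1L else 1L
  br <- which(diff(pos) != step)
  si <- c(1L, br + 1L)
  ei <- c(br, length(pos))
  if (strand == "+") {
    m <- cbind(start = pos[si], end = pos[ei] + 1L)
  } else {
    m <- cbind(start = pos[ei], end = pos[si] + 1L)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  m
}

#' Splice junctions of one coding transcript
#'
#' Junctions internal to the CDS, i.e. boundaries between consecutive coding
#' segments, in translation order. `cum_nt` is the number of coding
#' nucleotides upstream of the junction; `phase = cum_nt mod 3`. The boundary
#' residue is the amino acid whose codon contains the donor exon's final
#' coding base ("*" when that codon is the annotated stop).
#'
#' @param ct a `coding_transcript`
#' @return data.frame with one row per junction: `contig`, `strand`,
#'   `donor_end`, `acceptor_start` (0-based genomic coordinates of the last
#'   donor base and first acceptor base), `cum_nt`, `phase`,
#'   `boundary_residue`, `key`
#' @export
transcript_junctions <- function(ct) {
  pos <- ct$cds_pos
  step <- if (ct$model$strand == "-") -1L else 1L
  br <- which(diff(pos) != step)
  if (length(br) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      donor_end = integer(0), acceptor_start = integer(0),
                      cum_nt = integer(0), phase = integer(0),
                      boundary_residue = character(0), key = character(0),
                      stringsAsFactors = FALSE))
  }
  aa_all <- c(strsplit(ct$protein, "", fixed = TRUE)[[1]],
              if (ct$has_stop_codon) "*")
  ridx <- ((br - 1L) %/% 3L) + 1L
  data.frame(contig = ct$model$contig, strand = ct$model$strand,
             donor_end = pos[br], acceptor_start = pos[br + 1L],
             cum_nt = br, phase = br %% 3L,
             boundary_residue = aa_all[ridx],
             key = junction_key(ct$model$contig, ct$model$strand,
                                pos[br], pos[br + 1L]),
             stringsAsFactors = FALSE)
}

#' Enumerate unique coding splice junctions across transcripts
#'
#' Collapses junctions shared between isoforms onto their genomic identity key
#' (contig, strand, donor end, acceptor start). Phase and boundary residue are
#' taken from the first transcript carrying the junction; `n_transcripts`
#' counts isoform support. `is_kr` flags boundary residues in `{K, R}`.
#'
#' @param transcripts list of `coding_transcript` objects
#' @return data.frame of unique junctions (columns as
#'   [transcript_junctions()] plus `is_kr` and `n_transcripts`)
#' @export
enumerate_junctions <- function(transcripts) {
  occ <- junction_occurrences(transcripts)
  if (nrow(occ) == 0L) {
    out <- occ
    out$is_kr <- logical(0)
    out$n_transcripts <- integer(0)
    out$tx_id <- NULL
    return(out)
  }
  dt <- data.table::as.data.table(occ)
  uni <- dt[, c(.SD[1L], list(n_transcripts = .N)), by = "key",
            .SDcols = c("contig", "strand", "donor_end", "acceptor_start",
                        "cum_nt", "phase", "boundary_residue")]
  uni$is_kr <- uni$boundary_residue %in% c("K", "R")
  data.table::setcolorder(uni, c("contig", "strand", "donor_end",
                                 "acceptor_start", "cum_nt", "phase",
                                 "boundary_residue", "is_kr", "key",
                                 "n_transcripts"))
  as.data.frame(uni)
}

#' Per-transcript junction occurrences
#'
#' One row per (transcript, junction) pair, before deduplication. This is the
#' counting basis for occurrence-mode boundary composition.
#'
#' @param transcripts list of `coding_transcript` objects
#' @return data.frame of junction occurrences with a `tx_id` column
#' @export
junction_occurrences <- function(transcripts) {
  dfs <- lapply(transcripts, function(ct) {
    j <- transcript_junctions(ct)
    if (nrow(j)) j$tx_id <- ct$model$tx_id else j$tx_id <- character(0)
    j
  })
  out <- data.table::rbindlist(dfs)
  as.data.frame(out)
}

#' Write a junction table as TSV
#'
#' @param junctions data.frame from [enumerate_junctions()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_junction_tsv <- function(junctions, path) {
  cols <- c("contig", "strand", "donor_end", "acceptor_start", "phase",
            "boundary_residue", "is_kr")
  write.table(junctions[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write junction anchor intervals as BED
#'
#' Emits one 2-nt interval per junction anchoring the last donor base and the
#' first acceptor base (BED6; name = phase:boundary_residue).
#'
#' @param junctions data.frame from [enumerate_junctions()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_junction_bed <- function(junctions, path) {
  lo <- pmin(junctions$donor_end, junctions$acceptor_start)
  hi <- pmax(junctions$donor_end, junctions$acceptor_start)
  df <- data.frame(chrom = junctions$contig, start = lo, end = hi + 1L,
                   name = paste0("phase", junctions$phase, ":",
                                 junctions$boundary_residue),
                   score = 0L, strand = junctions$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write transcript models as UCSC genePred
#'
#' @param models list of [transcript_model()] objects
#' @param path output path
#' @return invisibly, the path
#' @export
write_genepred <- function(models, path) {
  lines <- vapply(models, function(m) {
    paste(m$tx_id, m$contig, m$strand,
          min(m$exon_start), max(m$exon_end),
          m$cds_start, m$cds_end, length(m$exon_start),
          paste0(paste(m$exon_start, collapse = ","), ","),
          paste0(paste(m$exon_end, collapse = ","), ","),
          0L, m$gene_id, "cmpl", "cmpl",
          paste0(paste(rep(-1L, length(m$exon_start)), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of contig sequences
#' @param path output path
#' @return invisibly, the path
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# compact fingerprint of an annotation, used to refuse cross-annotation
# enzyme comparisons
annotation_fingerprint <- function(transcripts, junctions) {
  total_nt <- sum(vapply(transcripts, function(ct) nchar(ct$cds_nt), numeric(1)))
  sprintf("tx:%d|cds_nt:%.0f|junc:%d", length(transcripts), total_nt,
          nrow(junctions))
}
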