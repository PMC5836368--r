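#' Configuration for the synthetic genome generator
#'
#' Defaults emulate compact vertebrate-like coding genes: 4-8 exons whose
#' lengths bracket the ~66-residue (~200 nt) median of human internal coding
#' exons, a human-like junction phase distribution (~0.47/0.30/0.23), a 25%
#' chance that a junction's boundary residue is lysine/arginine (the
#' frame-adjusted rate observed in human annotations), and near-universal
#' GT..AG introns.
#'
#' @param n_genes number of genes (one contig per gene)
#' @param exon_count_range inclusive range of exons per gene (min >= 2)
#' @param exon_len_range_nt inclusive range of exon coding lengths in nt
#'   (min >= 9 so planted boundary codons never collide)
#' @param intron_len_range_nt inclusive intron length range (min >= 4)
#' @param codon_usage optional named weight vector over the 64 codons
#'   (default uniform); stop codons are never used internally
#' @param p_boundary_kr probability a junction's boundary residue is K or R
#' @param phase_weights sampling weights for junction phases 0/1/2
#' @param p_canonical_intron probability an intron begins GT and ends AG
#' @param utr_len_range_nt range of untranslated extensions added to the
#'   first and last exon
#' @param flank_len_nt intergenic flank on each side of the transcript
#' @param p_minus_strand probability a gene is placed on the minus strand
#' @param isoform_share_prob per-gene probability of emitting a duplicate
#'   isoform sharing all junctions (exercises junction deduplication)
#' @param seed integer RNG seed; generation is fully reproducible from it
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_genes = 200L,
                             exon_count_range = c(4L, 8L),
                             exon_len_range_nt = c(90L, 300L),
                             intron_len_range_nt = c(60L, 200L),
                             codon_usage = NULL,
                             p_boundary_kr = 0.25,
                             phase_weights = c(0.47, 0.30, 0.23),
                             p_canonical_intron = 0.99,
                             utr_len_range_nt = c(0L, 30L),
                             flank_len_nt = 25L,
                             p_minus_strand = 0.5,
                             isoform_share_prob = 0,
                             seed = 1L) {
  if (is.null(codon_usage)) {
    codon_usage <- setNames(rep(1, 64), all_codons())
  }
  stopifnot(n_genes >= 1L,
            exon_count_range[1] >= 2L,
            exon_count_range[2] >= exon_count_range[1],
            intron_len_range_nt[1] >= 4L,
            p_boundary_kr >= 0, p_boundary_kr <= 1,
            length(phase_weights) == 3L, all(phase_weights >= 0),
            sum(phase_weights) > 0,
            p_canonical_intron >= 0, p_canonical_intron <= 1,
            all(names(codon_usage) %in% all_codons()),
            length(codon_usage) == 64L)
  if (exon_len_range_nt[1] < 9L || diff(exon_len_range_nt) < 3L) {
    stop("exon too short for planted codons: need min length >= 9 and a ",
         "range width >= 3 nt")
  }
  structure(list(n_genes = as.integer(n_genes),
                 exon_count_range = as.integer(exon_count_range),
                 exon_len_range_nt = as.integer(exon_len_range_nt),
                 intron_len_range_nt = as.integer(intron_len_range_nt),
                 codon_usage = codon_usage / sum(codon_usage),
                 p_boundary_kr = p_boundary_kr,
                 phase_weights = phase_weights / sum(phase_weights),
                 p_canonical_intron = p_canonical_intron,
                 utr_len_range_nt = as.integer(utr_len_range_nt),
                 flank_len_nt = as.integer(flank_len_nt),
                 p_minus_strand = p_minus_strand,
                 isoform_share_prob = isoform_share_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0))
}

KR_CODONS <- c("AAA", "AAG", "CGT", "CGC", "CGA", "CGG", "AGA", "AGG")

sample_codons <- function(n, usage, exclude_aa = character(0)) {
  codons <- names(usage)
  aa <- translate_codons(codons)
  keep <- aa != "*" & !(aa %in% exclude_aa)
  sample(codons[keep], n, replace = TRUE, prob = usage[keep])
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integer draw on [lo, hi], safe for degenerate ranges
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic genome, coding annotation, and truth table
#'
#' Builds multi-exon coding genes with controllable junction phase
#' distribution, boundary-residue K/R probability, and canonical GT..AG
#' introns. Each gene sits on its own contig with intergenic flanks; strands
#' are sampled. Boundary codons are planted per the junction's phase: at
#' phase 0 the codon is the donor exon's last triplet, at phase 2 it is split
#' 2+1 across the junction, at phase 1 split 1+2. Proteins start with M, end
#' with a stop codon, and contain no internal stops. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()]
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `annotation.genePred`, `truth_junctions.tsv`, `truth_proteins.tsv`, and
#'   `manifest.json` there
#' @return list: `genome` (named contig vector), `models` (list of
#'   [transcript_model()]), `truth` (list with `junctions` and `proteins`
#'   data.frames), `config`
#' @export
generate_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    genome <- character(config$n_genes)
    contig_names <- sprintf("ctg%04d", seq_len(config$n_genes))
    models <- list()
    jrows <- vector("list", config$n_genes)
    prows <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      gene <- generate_gene(config, sprintf("tx%04d", g),
                            sprintf("gene%04d", g), contig_names[g])
      genome[g] <- gene$contig_seq
      models[[gene$model$tx_id]] <- gene$model
      if (config$isoform_share_prob > 0 &&
          runif(1) < config$isoform_share_prob) {
        iso <- gene$model
        iso$tx_id <- paste0(gene$model$tx_id, "b")
        models[[iso$tx_id]] <- iso
      }
      jrows[[g]] <- gene$junctions
      prows[[g]] <- data.frame(tx_id = gene$model$tx_id,
                               gene_id = gene$model$gene_id,
                               protein = gene$protein,
                               stringsAsFactors = FALSE)
    }
    names(genome) <- contig_names
    truth <- list(junctions = as.data.frame(data.table::rbindlist(jrows)),
                  proteins = as.data.frame(data.table::rbindlist(prows)))
    out <- list(genome = genome, models = models, truth = truth,
                config = config)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_genome_fasta(genome, file.path(dir, "genome.fa"))
      write_genepred(models, file.path(dir, "annotation.genePred"))
      write.table(truth$junctions, file.path(dir, "truth_junctions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(truth$proteins, file.path(dir, "truth_proteins.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(generator = "juncpep::generate_genome",
             seed = config$seed, n_genes = config$n_genes,
             p_boundary_kr = config$p_boundary_kr,
             phase_weights = config$phase_weights,
             p_canonical_intron = config$p_canonical_intron,
             files = c("genome.fa", "annotation.genePred",
                       "truth_junctions.tsv", "truth_proteins.tsv")),
        file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      out$dir <- dir
    }
    out
  })
}

# one gene: returns contig sequence, transcript model (genomic coords),
# junction truth rows, and the protein
generate_gene <- function(config, tx_id, gene_id, contig) {
  n_ex <- sample_range(config$exon_count_range[1],
                       config$exon_count_range[2])
  n_j <- n_ex - 1L
  phases <- sample(0:2, n_j, replace = TRUE, prob = config$phase_weights)
  rng <- config$exon_len_range_nt
  # coding lengths per exon; cumulative length at junction j must be == phase
  # (mod 3)
  lens <- integer(n_ex)
  prev_phase <- 0L
  for (i in seq_len(n_j)) {
    want <- (phases[i] - prev_phase) %% 3L
    L <- sample_range(rng[1], rng[2])
    L <- L + ((want - L) %% 3L)
    if (L > rng[2]) L <- L - 3L
    lens[i] <- L
    prev_phase <- phases[i]
  }
  want <- (0L - prev_phase) %% 3L
  L <- sample_range(rng[1], rng[2])
  L <- L + ((want - L) %% 3L)
  if (L > rng[2]) L <- L - 3L
  lens[n_ex] <- L
  total <- sum(lens)
  n_cod <- total %/% 3L
  cums <- cumsum(lens)[seq_len(n_j)]
  # body codons, then plant start, stop, and boundary codons
  codons <- sample_codons(n_cod, config$codon_usage)
  codons[1L] <- "ATG"
  codons[n_cod] <- sample(STOP_CODONS, 1L)
  ridx <- ((cums - 1L) %/% 3L) + 1L
  if (any(ridx <= 1L) || any(ridx >= n_cod)) {
    stop("exon too short for planted codons (boundary codon collides with ",
         "start or stop)")
  }
  planted_kr <- runif(n_j) < config$p_boundary_kr
  for (j in seq_len(n_j)) {
    if (planted_kr[j]) {
      w <- config$codon_usage[KR_CODONS]
      if (sum(w) == 0) w <- rep(1, length(KR_CODONS))
      codons[ridx[j]] <- sample(KR_CODONS, 1L, prob = w)
    } else {
      codons[ridx[j]] <- sample_codons(1L, config$codon_usage,
                                       exclude_aa = c("K", "R"))
    }
  }
  cds <- paste(codons, collapse = "")
  protein <- paste(translate_codons(codons[-n_cod]), collapse = "")
  boundary_aa <- translate_codons(codons[ridx])
  # introns
  ilen <- sample_range(config$intron_len_range_nt[1],
                       config$intron_len_range_nt[2], n_j)
  introns <- vapply(seq_len(n_j), function(j) {
    s <- random_nt(ilen[j])
    if (runif(1) < config$p_canonical_intron) {
      substr(s, 1L, 2L) <- "GT"
      substr(s, ilen[j] - 1L, ilen[j]) <- "AG"
    }
    s
  }, character(1))
  # assemble in transcription orientation
  utr5 <- sample_range(config$utr_len_range_nt[1], config$utr_len_range_nt[2])
  utr3 <- sample_range(config$utr_len_range_nt[1], config$utr_len_range_nt[2])
  cds_pieces <- substring(cds, c(1L, cums + 1L), c(cums, total))
  exon_seqs <- cds_pieces
  exon_seqs[1L] <- paste0(random_nt(utr5), exon_seqs[1L])
  exon_seqs[n_ex] <- paste0(exon_seqs[n_ex], random_nt(utr3))
  flank <- config$flank_len_nt
  exon_len_tx <- nchar(exon_seqs)
  starts_t <- integer(n_ex)
  pos <- flank
  pieces <- character(2L * n_ex)
  pieces[1L] <- random_nt(flank)
  pi <- 2L
  for (i in seq_len(n_ex)) {
    starts_t[i] <- pos
    pieces[pi] <- exon_seqs[i]; pi <- pi + 1L
    pos <- pos + exon_len_tx[i]
    if (i < n_ex) {
      pieces[pi] <- introns[i]; pi <- pi + 1L
      pos <- pos + ilen[i]
    }
  }
  pieces[pi] <- random_nt(flank)
  seq_t <- paste(pieces[seq_len(pi)], collapse = "")
  Lc <- nchar(seq_t)
  ends_t <- starts_t + exon_len_tx
  cds_start_t <- starts_t[1L] + utr5
  cds_end_t <- ends_t[n_ex] - utr3
  minus <- runif(1) < config$p_minus_strand
  if (minus) {
    contig_seq <- revcomp(seq_t)
    exon_start <- Lc - ends_t
    exon_end <- Lc - starts_t
    cds_start <- Lc - cds_end_t
    cds_end <- Lc - cds_start_t
    strand <- "-"
    donor_end <- Lc - 1L - (ends_t[seq_len(n_j)] - 1L)
    acceptor_start <- Lc - 1L - starts_t[seq_len(n_j) + 1L]
  } else {
    contig_seq <- seq_t
    exon_start <- starts_t
    exon_end <- ends_t
    cds_start <- cds_start_t
    cds_end <- cds_end_t
    strand <- "+"
    donor_end <- ends_t[seq_len(n_j)] - 1L
    acceptor_start <- starts_t[seq_len(n_j) + 1L]
  }
  model <- transcript_model(tx_id, gene_id, contig, strand,
                            exon_start, exon_end, cds_start, cds_end)
  junctions <- data.frame(
    tx_id = tx_id, gene_id = gene_id, contig = contig, strand = strand,
    donor_end = donor_end, acceptor_start = acceptor_start,
    cum_nt = cums, phase = phases, boundary_residue = boundary_aa,
    planted_kr = planted_kr,
    key = junction_key(contig, strand, donor_end, acceptor_start),
    stringsAsFactors = FALSE)
  list(contig_seq = contig_seq, model = model, junctions = junctions,
       protein = protein)
}

#' Simulate an observed-peptide set from an enzymatic digest
#'
#' Digests every protein of the annotation, projects the products to the
#' genome, collapses to uniquely mapped sequences, and samples each unique
#' peptide independently with probability `detection_model(length)`. Stands
#' in for genome-mapped peptide identifications from a shotgun proteomics
#' experiment.
#'
#' @param transcripts named list of `coding_transcript` objects
#' @param enz an [enzyme()]
#' @param detection_model function mapping peptide length (aa) to a detection
#'   probability in `[0, 1]`; the default detects peptides of 8-25 residues
#'   with probability 1
#' @param max_missed maximum missed cleavages in the digest
#' @param seed optional RNG seed for the detection sampling
#' @param bed_path optional path; when given, the detected set is written as
#'   BED12
#' @return list as from [project_peptides()], restricted to detected,
#'   uniquely mapped representative peptides (plus `all_unique`, the
#'   pre-sampling unique set size)
#' @export
simulate_observed_peptides <- function(transcripts, enz,
                                       detection_model = function(len)
                                         as.numeric(len >= 8 & len <= 25),
                                       max_missed = 0L, seed = NULL,
                                       bed_path = NULL) {
  run <- function() {
    peps <- digest_proteome(transcripts, enz, max_missed)
    proj <- project_peptides(peps, transcripts)
    coll <- collapse_unique(proj)
    reps <- coll[coll$is_representative & coll$unique_genomic]
    p <- detection_model(nchar(reps$sequence))
    stopifnot(all(p >= 0 & p <= 1))
    keep <- runif(nrow(reps)) < p
    det <- reps[keep]
    pj <- proj$junctions[proj$junctions$pep_id %in% det$pep_id]
    if (!is.null(bed_path)) write_peptides_bed12(det, bed_path)
    list(peptides = det, junctions = pj, all_unique = nrow(reps))
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
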