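# Fixtures built in code and memoised across test files within one run.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Hand-built two-exon plus-strand gene: CDS "ATGAA" | "GTAA" (5 + 4 nt),
# protein "MK", junction phase 2 with the lysine codon AAG split 2+1.
hand_two_exon <- function() {
  exon1 <- "ATGAA"; intron <- "GTAAGTTTTTTCAG"; exon2 <- "GTAA"
  contig <- paste0("CCCCC", exon1, intron, exon2, "GGGGG")
  model <- transcript_model("tx_two", "gene_two", "chrT", "+",
                           exon_start = c(5L, 5L + 5L + nchar(intron)),
                           exon_end = c(10L, 5L + 5L + nchar(intron) + 4L),
                           cds_start = 5L,
                           cds_end = 5L + 5L + nchar(intron) + 4L)
  genome <- c(chrT = contig)
  list(genome = genome, model = model,
       ct = build_coding_transcript(model, genome))
}

# Default mid-size synthetic annotation shared by several test files.
default_synth <- function() {
  get_fixture("default_synth", function() {
    cfg <- synthetic_config(n_genes = 120L, seed = 101L)
    g <- generate_genome(cfg)
    tx <- build_coding_transcripts(g$models, g$genome)
    j <- enumerate_junctions(tx)
    list(cfg = cfg, g = g, tx = tx, j = j)
  })
}

# "Null" annotation: boundary residues drawn from the background codon usage
# (P(K/R) = 8/61 under uniform sense-codon usage) and fully random introns,
# so neither boundary composition nor splice-site consensus carries any bias.
null_synth <- function() {
  get_fixture("null_synth", function() {
    cfg <- synthetic_config(n_genes = 1750L, exon_count_range = c(6L, 8L),
                            p_boundary_kr = 8 / 61,
                            p_canonical_intron = 0, seed = 202L)
    g <- generate_genome(cfg)
    tx <- build_coding_transcripts(g$models, g$genome)
    j <- enumerate_junctions(tx)
    list(cfg = cfg, g = g, tx = tx, j = j)
  })
}

# All-phase-0, all-lysine-boundary annotation (scenario-1 geometry), no
# proline suppression possible downstream of the boundary by construction of
# tests that need it.
phase0_k_synth <- function() {
  get_fixture("phase0_k_synth", function() {
    usage <- stats::setNames(rep(1, 64), juncpep:::all_codons())
    cfg <- synthetic_config(n_genes = 40L, phase_weights = c(1, 0, 0),
                            p_boundary_kr = 1, codon_usage = usage,
                            seed = 303L)
    g <- generate_genome(cfg)
    tx <- build_coding_transcripts(g$models, g$genome)
    j <- enumerate_junctions(tx)
    list(cfg = cfg, g = g, tx = tx, j = j)
  })
}
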