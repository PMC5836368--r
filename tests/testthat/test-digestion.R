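test_that("preset digestion matches hand-derived products", {
  pre <- enzyme_presets("paper")
  expect_identical(digest("AKRPGKMEK", pre$Trypsin, 0)$sequence,
                   c("AK", "RPGK", "MEK"))
  expect_identical(digest("AFGWPLK", pre$Chymotrypsin, 0)$sequence,
                   c("AF", "GW", "PL", "K"))
  expect_identical(digest("MDAD", pre$AspN, 0)$sequence,
                   c("M", "DA", "D"))
  # conventional chymotrypsin gains the proline block, Glu-C gains E
  conv <- enzyme_presets("conventional")
  expect_identical(digest("AFGWPLK", conv$Chymotrypsin, 0)$sequence,
                   c("AF", "GWPL", "K"))
  expect_identical(digest("AEGD", conv$GluC, 0)$sequence, c("AE", "GD"))
  expect_identical(digest("AEGD", pre$GluC, 0)$sequence, c("AEGD"))
  expect_error(enzyme("broken", character(0)), "non-empty")
})

test_that("digestion agrees with the position-scan oracle on random proteins", {
  set.seed(5)
  pres <- enzyme_presets("paper")
  for (r in seq_len(60L)) {
    prot <- random_protein(sample(20:120, 1))
    enz <- pres[[sample(length(pres), 1)]]
    mm <- sample(0:2, 1)
    got <- sort(digest(prot, enz, mm)$sequence)
    want <- oracle_digest(prot, enz$residues, enz$side, enz$blocked, mm)
    expect_identical(got, want)
  }
})

test_that("zero-missed products tile the protein and closures hold", {
  set.seed(6)
  pres <- enzyme_presets("paper")
  for (enz in pres) {
    for (r in seq_len(20L)) {
      prot <- random_protein(sample(30:200, 1))
      d0 <- digest(prot, enz, 0)
      expect_identical(paste(d0$sequence, collapse = ""), prot)
      # every m-missed product is a concatenation of m+1 consecutive
      # zero-missed products
      d2 <- digest(prot, enz, 2)
      for (mm in 1:2) {
        sub <- d2[d2$missed_cleavages == mm, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
          k <- match(sub$start_res[i], d0$start_res)
          expect_false(is.na(k))
          expect_identical(
            paste(d0$sequence[k:(k + mm)], collapse = ""), sub$sequence[i])
        }
      }
    }
  }
})

test_that("length and missed-cleavage filters are inclusive on the bounds", {
  recs <- data.frame(sequence = c(strrep("A", 7), strrep("A", 8),
                                  strrep("A", 25), strrep("A", 26),
                                  strrep("A", 10)),
                     missed_cleavages = c(0L, 0L, 0L, 0L, 1L))
  kept <- filter_peptides(recs, 8, 25, 0)
  expect_identical(nchar(kept$sequence), c(8L, 25L))
  expect_error(filter_peptides(recs, 10, 8, 0), "exceeds")
})

test_that("peptides project to conserved genomic blocks", {
  fx <- hand_two_exon()
  tx <- list(tx_two = fx$ct)
  # "MK" spans the phase-2 junction; K's codon is split 2+1, so a peptide
  # ending at the boundary residue covers exactly 1 nt of the acceptor exon
  rec <- data.frame(sequence = "MK", start_res = 0L, end_res = 2L,
                    missed_cleavages = 0L, tx_id = "tx_two")
  proj <- project_peptides(rec, tx)
  p <- proj$peptides
  expect_true(p$spans_junction)
  expect_identical(proj$junctions$acceptor_nt, 1L)  # type-4 geometry
  expect_identical(proj$junctions$donor_nt, 5L)
  expect_identical(sum(p$blocks[[1]][, 2] - p$blocks[[1]][, 1]), 6L)

  # a peptide within one exon gets a single block of 3x its length
  genome <- c(chr1 = "ATGAAAGAAGTGTAA")
  m <- transcript_model("t1", "g", "chr1", "+", 0L, 15L, 0L, 15L)
  ct <- build_coding_transcript(m, genome)
  proj2 <- project_peptides(
    data.frame(sequence = "KEV", start_res = 1L, end_res = 4L,
               missed_cleavages = 0L, tx_id = "t1"), list(t1 = ct))
  expect_identical(proj2$peptides$n_blocks, 1L)
  expect_identical(nrow(proj2$junctions), 0L)
  expect_error(project_peptides(
    data.frame(sequence = "Z", start_res = 10L, end_res = 12L,
               missed_cleavages = 0L, tx_id = "t1"), list(t1 = ct)),
    "outside")
})

test_that("a phase-0 junction splits a 4-residue spanning peptide 6+6", {
  genome <- c(chr1 = paste0("ATGAAA", strrep("T", 10), "GAAGTGTAA"))
  m <- transcript_model("t", "g", "chr1", "+", c(0L, 16L), c(6L, 25L),
                        0L, 25L)
  ct <- build_coding_transcript(m, genome)
  proj <- project_peptides(
    data.frame(sequence = "MKEV", start_res = 0L, end_res = 4L,
               missed_cleavages = 0L, tx_id = "t"), list(t = ct))
  b <- proj$peptides$blocks[[1]]
  expect_identical(b[, 2] - b[, 1], c(6L, 6L))
  expect_identical(proj$junctions$acceptor_nt, 6L)
})

test_that("projection conserves block length sums on random synthetic peptides", {
  fx <- default_synth()
  set.seed(8)
  ids <- names(fx$tx)
  recs <- do.call(rbind, lapply(seq_len(400L), function(i) {
    tx_id <- sample(ids, 1)
    plen <- nchar(fx$tx[[tx_id]]$protein)
    len <- sample(5:30, 1)
    s <- sample.int(plen - len, 1) - 1L
    data.frame(sequence = substr(fx$tx[[tx_id]]$protein, s + 1, s + len),
               start_res = s, end_res = s + len, missed_cleavages = 0L,
               tx_id = tx_id)
  }))
  proj <- project_peptides(recs, fx$tx)
  widths <- vapply(proj$peptides$blocks,
                   function(b) sum(b[, 2] - b[, 1]), numeric(1))
  expect_identical(widths, 3 * nchar(proj$peptides$sequence))
  # per-junction coverages always sum to the peptide length in nt
  pj <- proj$junctions
  if (nrow(pj)) {
    lens <- 3L * nchar(proj$peptides$sequence)[match(pj$pep_id,
                                                     proj$peptides$pep_id)]
    expect_true(all(pj$donor_nt + pj$acceptor_nt == lens))
  }
})

test_that("uniqueness collapse merges isoform-shared hits and flags paralogs", {
  # same contig, two isoforms with identical structure -> unique
  genome <- c(chr1 = "ATGAAAGAAGTGTAA", chr2 = "ATGAAAGAAGTGTAA")
  mk <- function(id, ctg) transcript_model(id, id, ctg, "+", 0L, 15L, 0L, 15L)
  tx <- build_coding_transcripts(
    list(a1 = mk("a1", "chr1"), a2 = mk("a2", "chr1")), genome)
  recs <- digest_proteome(tx, enzyme_presets("paper")$Trypsin, 0)
  coll <- collapse_unique(project_peptides(recs, tx))
  expect_true(all(coll$unique_genomic))
  expect_identical(sum(coll$is_representative),
                   length(unique(coll$sequence)))

  # paralogous locus on another contig -> every shared sequence ambiguous
  tx2 <- build_coding_transcripts(
    list(a1 = mk("a1", "chr1"), b1 = mk("b1", "chr2")), genome)
  coll2 <- collapse_unique(project_peptides(
    digest_proteome(tx2, enzyme_presets("paper")$Trypsin, 0), tx2))
  expect_false(any(coll2$unique_genomic))
})

test_that("junction peptides with identical sequence but different acceptor exons are ambiguous", {
  # one donor exon feeding two acceptor exons with identical sequence
  donor <- "ATGGAAAAA"              # M E K
  acc <- "GAAGTGTAA"               # E V *
  intr1 <- strrep("T", 12); intr2 <- strrep("C", 12)
  genome <- c(chrP = paste0(donor, intr1, acc, intr2, acc))
  m1 <- transcript_model("p1", "g", "chrP", "+", c(0L, 21L), c(9L, 30L),
                         0L, 30L)
  m2 <- transcript_model("p2", "g", "chrP", "+", c(0L, 42L), c(9L, 51L),
                         0L, 51L)
  tx <- build_coding_transcripts(list(p1 = m1, p2 = m2), genome)
  expect_identical(tx$p1$protein, tx$p2$protein)
  proj <- project_peptides(
    data.frame(sequence = c("MEKEV", "MEKEV"), start_res = 0L, end_res = 5L,
               missed_cleavages = 0L, tx_id = c("p1", "p2")), tx)
  coll <- collapse_unique(proj)
  expect_false(any(coll$unique_genomic))
})

test_that("BED12 round trip preserves peptide projections and type calls", {
  fx <- default_synth()
  bed <- withr::local_tempfile(fileext = ".bed")
  obs <- simulate_observed_peptides(fx$tx, enzyme_presets("paper")$Trypsin,
                                    seed = 12L, bed_path = bed)
  rt <- read_peptides_bed12(bed)
  expect_identical(nrow(rt), nrow(obs$peptides))
  matched <- match_bed_to_transcripts(rt, fx$tx)
  expect_identical(nrow(matched$peptides), nrow(obs$peptides))
  expect_setequal(matched$peptides$sequence, obs$peptides$sequence)
  # spanning structure survives the round trip
  expect_identical(sum(matched$peptides$spans_junction),
                   sum(obs$peptides$spans_junction))
})
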