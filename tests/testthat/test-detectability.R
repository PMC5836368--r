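# shared digestion run on the default synthetic annotation
trypsin_run <- function() {
  get_fixture("trypsin_run", function() {
    fx <- default_synth()
    peps <- filter_peptides(
      digest_proteome(fx$tx, enzyme_presets("paper")$Trypsin, 0L), 8, 25, 0)
    proj <- project_peptides(peps, fx$tx)
    coll <- collapse_unique(proj)
    list(coll = coll, pj = proj$junctions)
  })
}

test_that("acceptor-coverage thresholds gate junction detectability", {
  # single gene whose only junction-spanning tryptic peptide ends 1 nt into
  # the acceptor exon (type-4 geometry): not detectable at the default
  # 3-nt acceptor threshold
  fx <- hand_two_exon()
  tx <- list(tx_two = fx$ct)
  j <- enumerate_junctions(tx)
  rec <- data.frame(sequence = "MK", start_res = 0L, end_res = 2L,
                    missed_cleavages = 0L, tx_id = "tx_two")
  proj <- project_peptides(rec, tx)
  coll <- collapse_unique(proj)
  rep1 <- coverage_report(coll, proj$junctions, j, tx, "Trypsin")
  expect_identical(rep1$n_detectable_junctions, 0L)
  # with a permissive threshold the same peptide verifies the junction
  rep2 <- coverage_report(coll, proj$junctions, j, tx, "Trypsin",
                          min_acceptor_nt = 1L)
  expect_identical(rep2$n_detectable_junctions, 1L)
  # empty peptide set -> zero coverages
  rep0 <- coverage_report(coll[0L], proj$junctions[0L], j, tx, "none")
  expect_identical(rep0$cds_coverage, 0)
  expect_identical(rep0$n_detectable_junctions, 0L)
})

test_that("coverage fractions equal a brute-force recount on the shipped toy annotation", {
  dirp <- system.file("extdata", "toy3", package = "juncpep")
  genome <- read_genome(file.path(dirp, "genome.fa"))
  models <- read_gene_models(file.path(dirp, "annotation.genePred"),
                             "genePred", genome)
  tx <- build_coding_transcripts(models, genome)
  j <- enumerate_junctions(tx)
  peps <- filter_peptides(
    digest_proteome(tx, enzyme_presets("paper")$Trypsin, 0L), 8, 25, 0)
  proj <- project_peptides(peps, tx)
  coll <- collapse_unique(proj)
  rep1 <- coverage_report(coll, proj$junctions, j, tx, "Trypsin")

  # brute force: enumerate every genomic CDS position of every transcript,
  # then mark positions covered by any unique peptide block
  cds_pos_all <- unique(unlist(lapply(tx, function(ct)
    paste(ct$model$contig, ct$cds_pos))))
  reps <- coll[coll$is_representative & coll$unique_genomic]
  cov_pos <- character(0)
  for (i in seq_len(nrow(reps))) {
    b <- reps$blocks[[i]]
    for (r in seq_len(nrow(b))) {
      cov_pos <- c(cov_pos, paste(reps$contig[i], b[r, 1]:(b[r, 2] - 1L)))
    }
  }
  cov_pos <- unique(cov_pos)
  expect_true(all(cov_pos %in% cds_pos_all))
  expect_equal(rep1$cds_coverage, length(cov_pos) / length(cds_pos_all))

  # brute-force junction recount from per-peptide junction coverages
  pj <- proj$junctions[proj$junctions$pep_id %in% reps$pep_id]
  det <- unique(pj$key[pj$acceptor_nt >= 3L & pj$donor_nt >= 1L])
  expect_identical(sort(rep1$detectable_keys), sort(intersect(det, j$key)))
  expect_equal(rep1$junction_coverage, length(det) / nrow(j))
})

test_that("enzyme comparisons reduce to exact set arithmetic", {
  fake <- function(name, keys, kr) {
    structure(list(enzyme = name, detectable_keys = keys,
                   detectable_kr_keys = kr, fingerprint = "fp"),
              class = "coverage_report")
  }
  a <- fake("A", paste0("j", 1:3), "j1")
  b <- fake("B", paste0("j", 4:7), character(0))
  cmp <- compare_enzymes(list(a, b))
  expect_identical(cmp$union_size, 7L)
  expect_identical(cmp$intersection_size, 0L)
  # identical sets: union = intersection
  cmp2 <- compare_enzymes(list(a, fake("A2", paste0("j", 1:3), "j1")))
  expect_identical(cmp2$union_size, cmp2$intersection_size)
  # engineered 3-way overlap vs exhaustive enumeration
  s1 <- paste0("j", 1:6); s2 <- paste0("j", 4:9); s3 <- paste0("j", c(1, 5, 9))
  cmp3 <- compare_enzymes(list(fake("E1", s1, character(0)),
                               fake("E2", s2, character(0)),
                               fake("E3", s3, character(0))))
  expect_identical(cmp3$union_size, length(unique(c(s1, s2, s3))))
  expect_identical(cmp3$intersection_size,
                   length(intersect(s1, intersect(s2, s3))))
  only_e1 <- setdiff(s1, union(s2, s3))
  rc <- cmp3$region_counts
  expect_identical(rc$count[rc$region == "E1"], length(only_e1))
  e2e3 <- setdiff(intersect(s2, s3), s1)
  expect_identical(rc$count[rc$region == "E2+E3"], length(e2e3))
  # mismatched annotations refuse to compare
  bad <- fake("C", "j1", character(0)); bad$fingerprint <- "other"
  expect_error(compare_enzymes(list(a, bad)), "different annotations")
})

test_that("detectable junction sets are monotone in the peptide filters", {
  fx <- default_synth()
  enz <- enzyme_presets("paper")$Trypsin
  peps_all <- digest_proteome(fx$tx, enz, 1L)
  sets <- list()
  for (par in list(list(25, 0), list(35, 0), list(35, 1))) {
    peps <- filter_peptides(peps_all, 8, par[[1]], par[[2]])
    proj <- project_peptides(peps, fx$tx)
    coll <- collapse_unique(proj)
    r <- coverage_report(coll, proj$junctions, fx$j, fx$tx, "T")
    sets <- c(sets, list(r$detectable_keys))
  }
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("peptide termini classify into types 1-4 at the defining offsets", {
  # scenario-1 walk: phase-0 K/R boundaries cleave exactly at the splice
  # site, so donor-side products are type 3 and acceptor-side products type 1
  fx <- phase0_k_synth()
  peps <- digest_proteome(fx$tx, enzyme_presets("paper")$Trypsin, 0L)
  proj <- project_peptides(peps, fx$tx)
  coll <- collapse_unique(proj)
  calls <- classify_peptide_type(coll, proj$junctions, fx$tx)
  expect_true(all(c(1L, 3L) %in% calls$type))
  # with every boundary phase 0 and cleavage at K/R, no junction-spanning
  # peptide survives unless proline suppressed the site
  reps <- coll[coll$is_representative & coll$unique_genomic]
  cums <- lapply(fx$tx, function(ct) transcript_junctions(ct)$cum_nt)
  for (i in which(calls$type == 1L)) {
    k <- match(calls$pep_id[i], reps$pep_id)
    expect_identical(
      (3L * reps$start_res[k]) %in% cums[[reps$tx_id[k]]], TRUE)
  }
  # type ratios are plain arithmetic over unique peptides
  rs <- type_ratio_summary(calls, sum(reps$is_representative))
  expect_equal(rs$summed_ratio, sum(rs$fractions))
  expect_identical(type_ratio_summary(calls[0, ], 20L)$summed_ratio, 0)
  toy <- data.frame(pep_id = 1:2, sequence = c("a", "b"), type = c(1L, 1L),
                    offset_nt = 0L)
  expect_equal(type_ratio_summary(toy, 20L)$fractions[["type1"]], 0.10)
})

test_that("type calls agree with the boundary-distance histogram cells", {
  run <- trypsin_run()
  fx <- default_synth()
  calls <- classify_peptide_type(run$coll, run$pj, fx$tx)
  hist <- boundary_distance_histogram(run$coll, run$pj, fx$tx)
  cell <- function(cat, off) {
    hist$count[hist$category == cat & hist$offset == off]
  }
  n_type <- function(t) length(unique(calls$pep_id[calls$type == t]))
  expect_identical(n_type(1L), cell("starts_vs_acceptor", 0L))
  expect_identical(n_type(2L), cell("starts_vs_acceptor", 1L))
  expect_identical(n_type(3L), cell("ends_vs_donor", 0L))
  expect_identical(n_type(4L), cell("junction_ends_vs_acceptor_start", 1L))
})

test_that("a degenerate all-boundary peptide set drives the offset-0 z to significance", {
  fx <- phase0_k_synth()
  # peptides starting exactly at acceptor starts of internal segments
  rows <- list()
  for (ct in fx$tx[1:20]) {
    cums <- transcript_junctions(ct)$cum_nt
    for (c0 in cums[-length(cums)]) {
      if (c0 %% 3L == 0L && c0 / 3L + 9L <= nchar(ct$protein)) {
        rows <- c(rows, list(data.frame(
          sequence = substr(ct$protein, c0 / 3 + 1, c0 / 3 + 9),
          start_res = c0 %/% 3L, end_res = c0 %/% 3L + 9L,
          missed_cleavages = 0L, tx_id = ct$model$tx_id)))
      }
    }
  }
  recs <- do.call(rbind, rows)
  proj <- project_peptides(recs, fx$tx)
  coll <- collapse_unique(proj)
  hist <- boundary_distance_histogram(coll, proj$junctions, fx$tx)
  h0 <- hist[hist$category == "starts_vs_acceptor" & hist$offset == 0L, ]
  expect_gt(h0$count, 0L)
  expect_lt(h0$p, 1e-6)
  expect_equal(h0$count, h0$n_category)   # all starts at offset 0
})
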