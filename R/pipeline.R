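#' Junction and composition analysis of an annotation
#'
#' Orchestrates the annotation and composition stages: builds coding
#' transcripts, enumerates unique junctions, computes occurrence- and
#' unique-mode boundary composition, the K/R-junction partition, splice-site
#' position frequency matrices, and frame-adjusted cleavage-scenario
#' statistics. When `out_dir` is given, writes the junction TSV, composition
#' TSVs, PFM TSVs, scenario JSON, and a run manifest.
#'
#' @param genome genome from [read_genome()] (or a path to a FASTA)
#' @param models list of transcript models from [read_gene_models()] (or a
#'   path to a genePred file)
#' @param out_dir optional output directory
#' @return list: `transcripts`, `junctions`, `composition_occurrence`,
#'   `composition_unique`, `kr`, `pfm`, `scenarios`, `fingerprint`
#' @export
run_junction_analysis <- function(genome, models, out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  if (is.character(models)) {
    models <- read_gene_models(models, "genePred", genome = genome)
  }
  transcripts <- build_coding_transcripts(models, genome)
  junctions <- enumerate_junctions(transcripts)
  comp_occ <- boundary_residue_composition(transcripts, mode = "occurrence")
  comp_uni <- boundary_residue_composition(transcripts, junctions,
                                           mode = "unique")
  kr <- classify_kr_junctions(junctions)
  pfm <- splice_site_pfm(junctions, genome)
  scen <- cleavage_scenario_stats(junctions)
  fp <- annotation_fingerprint(transcripts, junctions)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_junction_tsv(junctions, file.path(out_dir, "junctions.tsv"))
    write_composition_tsv(comp_occ,
                          file.path(out_dir, "composition_occurrence.tsv"))
    write_composition_tsv(comp_uni,
                          file.path(out_dir, "composition_unique.tsv"))
    write_pfm_tsv(pfm$donor, file.path(out_dir, "pfm_donor.tsv"))
    write_pfm_tsv(pfm$acceptor, file.path(out_dir, "pfm_acceptor.tsv"))
    write_scenario_json(scen, file.path(out_dir, "scenarios.json"))
    jsonlite::write_json(list(stage = "junctions", fingerprint = fp,
                              n_transcripts = length(transcripts),
                              n_junctions = nrow(junctions),
                              fraction_kr = kr$fraction_kr),
                         file.path(out_dir, "manifest_junctions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(transcripts = transcripts, junctions = junctions,
       composition_occurrence = comp_occ, composition_unique = comp_uni,
       kr = kr, pfm = pfm, scenarios = scen, fingerprint = fp)
}

#' Multi-enzyme in-silico digestion and detectability analysis
#'
#' Digests every protein with each enzyme, filters by length and missed
#' cleavages, projects peptides to the genome, collapses to uniquely mapped
#' sequences, and computes a per-enzyme coverage report. With two or more
#' enzymes, also emits detectable-junction set comparisons (all junctions and
#' the K/R subset).
#'
#' @param transcripts named list of `coding_transcript` objects
#' @param junctions unique-junction table
#' @param enzymes named list of [enzyme()] objects (e.g. [enzyme_presets()])
#' @param min_len,max_len peptide length bounds (aa, inclusive)
#' @param max_missed maximum missed cleavages
#' @param min_acceptor_nt,min_donor_nt junction detectability thresholds
#' @param out_dir optional output directory (per-enzyme peptide TSVs,
#'   coverage JSON, comparison JSON)
#' @return list: `reports` (per enzyme), `comparison`, `comparison_kr`
#'   (`NULL` for a single enzyme), and `peptides`/`pep_junctions` per enzyme
#' @export
run_digestion_analysis <- function(transcripts, junctions, enzymes,
                                   min_len = 8L, max_len = 25L,
                                   max_missed = 0L,
                                   min_acceptor_nt = 3L, min_donor_nt = 1L,
                                   out_dir = NULL) {
  if (inherits(enzymes, "enzyme")) enzymes <- setNames(list(enzymes),
                                                       enzymes$name)
  reports <- list(); peptides <- list(); pjs <- list()
  for (nm in names(enzymes)) {
    peps <- digest_proteome(transcripts, enzymes[[nm]], max_missed)
    peps <- filter_peptides(peps, min_len, max_len, max_missed)
    proj <- project_peptides(peps, transcripts)
    coll <- collapse_unique(proj)
    reports[[nm]] <- coverage_report(coll, proj$junctions, junctions,
                                     transcripts, enzyme_name = nm,
                                     min_acceptor_nt = min_acceptor_nt,
                                     min_donor_nt = min_donor_nt)
    peptides[[nm]] <- coll
    pjs[[nm]] <- proj$junctions
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_peptides_tsv(coll, file.path(out_dir,
                                         paste0("peptides_", nm, ".tsv")))
    }
  }
  comparison <- comparison_kr <- NULL
  if (length(enzymes) >= 2L) {
    comparison <- compare_enzymes(reports, "all")
    comparison_kr <- compare_enzymes(reports, "kr")
  }
  if (!is.null(out_dir)) {
    tab <- coverage_table(reports)
    write.table(tab, file.path(out_dir, "coverage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(coverage = tab,
           comparison = if (!is.null(comparison))
             comparison[c("enzymes", "union_size", "intersection_size")],
           comparison_kr = if (!is.null(comparison_kr))
             comparison_kr[c("enzymes", "union_size", "intersection_size")],
           thresholds = list(min_len = min_len, max_len = max_len,
                             max_missed = max_missed,
                             min_acceptor_nt = min_acceptor_nt,
                             min_donor_nt = min_donor_nt)),
      file.path(out_dir, "digestion_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = reports, comparison = comparison,
       comparison_kr = comparison_kr, peptides = peptides,
       pep_junctions = pjs)
}

#' Observed-peptide classification analysis
#'
#' Classifies observed peptides (a BED12 path, a data.frame from
#' [read_peptides_bed12()], or an in-memory projected set from
#' [simulate_observed_peptides()]) into types 1-4 relative to splice sites
#' and computes boundary-distance enrichment histograms.
#'
#' @param transcripts named list of `coding_transcript` objects
#' @param junctions unique-junction table
#' @param peptides observed peptides (see above)
#' @param out_dir optional output directory (type-call TSV, histogram TSV)
#' @return list: `calls`, `ratios`, `histogram`, `n_peptides`, `n_skipped`
#' @export
run_classification_analysis <- function(transcripts, junctions, peptides,
                                        out_dir = NULL) {
  n_skipped <- 0L
  if (is.character(peptides) && length(peptides) == 1L) {
    peptides <- read_peptides_bed12(peptides)
  }
  if (is.data.frame(peptides) && "blocks" %in% names(peptides) &&
      !"tx_id" %in% names(peptides)) {
    proj <- match_bed_to_transcripts(peptides, transcripts)
    n_skipped <- attr(proj$peptides, "n_skipped") %||% 0L
    if (nrow(proj$peptides)) {
      coll <- collapse_unique(proj)
    } else {
      coll <- proj$peptides
    }
    peps <- coll; pj <- proj$junctions
  } else {
    peps <- peptides$peptides
    pj <- peptides$junctions
  }
  if (is.null(nrow(peps)) || nrow(peps) == 0L) {
    empty <- data.frame(pep_id = integer(0), sequence = character(0),
                        type = integer(0), offset_nt = integer(0))
    return(list(calls = empty, ratios = type_ratio_summary(empty, 0L),
                histogram = boundary_distance_histogram(
                  data.table::data.table(
                    tx_id = character(0), start_res = integer(0),
                    end_res = integer(0), pep_id = integer(0),
                    sequence = character(0)),
                  empty_pep_junctions(),
                  transcripts),
                n_peptides = 0L, n_skipped = n_skipped))
  }
  dtp <- data.table::as.data.table(peps)
  if ("is_representative" %in% names(dtp)) {
    n_unique <- sum(dtp$is_representative & dtp$unique_genomic)
  } else {
    n_unique <- nrow(dtp)
  }
  calls <- classify_peptide_type(dtp, pj, transcripts)
  ratios <- type_ratio_summary(calls, n_unique)
  hist <- boundary_distance_histogram(dtp, pj, transcripts)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(calls, file.path(out_dir, "type_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_histogram_tsv(hist, file.path(out_dir, "boundary_histogram.tsv"))
    jsonlite::write_json(list(type_counts = as.list(ratios$counts),
                              type_fractions = as.list(ratios$fractions),
                              summed_ratio = ratios$summed_ratio,
                              n_peptides = n_unique, n_skipped = n_skipped),
                         file.path(out_dir, "type_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(calls = calls, ratios = ratios, histogram = hist,
       n_peptides = n_unique, n_skipped = n_skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
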