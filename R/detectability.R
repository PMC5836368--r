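#' Per-enzyme CDS, junction, and K/R-junction detectability
#'
#' A junction is detectable iff at least one uniquely mapped peptide spans it
#' with acceptor-side coverage >= `min_acceptor_nt` and donor-side coverage >=
#' `min_donor_nt`. The acceptor default of 3 nt excludes junction peptides
#' ending 1 nt (type 4) or 2 nt into the acceptor exon, whose single- or
#' two-nucleotide acceptor coverage makes the acceptor exon assignment
#' uncertain. CDS coverage is nucleotide-level over the union of genomic CDS
#' positions of all transcripts.
#'
#' @param peptides collapsed peptide table from [collapse_unique()] (already
#'   length/missed-cleavage filtered)
#' @param pep_junctions per-peptide junction table from [project_peptides()]
#' @param junctions unique-junction table from [enumerate_junctions()]
#' @param transcripts named list of `coding_transcript` objects
#' @param enzyme_name label for the report
#' @param min_acceptor_nt,min_donor_nt detectability thresholds (nt)
#' @return object of class `coverage_report`: `enzyme`, `cds_coverage`,
#'   `n_detectable_junctions`, `junction_coverage`, `n_detectable_kr`,
#'   `kr_coverage`, the detectable key sets, thresholds, `n_peptides`, and an
#'   annotation `fingerprint`
#' @export
coverage_report <- function(peptides, pep_junctions, junctions, transcripts,
                            enzyme_name = "enzyme",
                            min_acceptor_nt = 3L, min_donor_nt = 1L) {
  dt <- data.table::as.data.table(peptides)
  reps <- dt[dt$is_representative & dt$unique_genomic]
  # CDS universe and covered positions, per contig
  cds_by_contig <- cds_ranges_by_contig(transcripts)
  total_cds <- sum(vapply(cds_by_contig, function(r)
    sum(IRanges::width(IRanges::reduce(r))), numeric(1)))
  covered <- 0
  if (nrow(reps) > 0L) {
    bm <- do.call(rbind, reps$blocks)
    bl <- data.table::data.table(contig = rep(reps$contig, reps$n_blocks),
                                 start = bm[, 1], end = bm[, 2])
    for (ctg in unique(bl$contig)) {
      sub <- bl[bl$contig == ctg]
      ir <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L,
                                             end = sub$end))
      covered <- covered + sum(IRanges::width(ir))
    }
  }
  # detectable junctions
  pj <- data.table::as.data.table(pep_junctions)
  pj <- pj[pj$pep_id %in% reps$pep_id &
             pj$acceptor_nt >= min_acceptor_nt &
             pj$donor_nt >= min_donor_nt]
  det <- intersect(unique(pj$key), junctions$key)
  kr_keys <- junctions$key[junctions$is_kr]
  det_kr <- intersect(det, kr_keys)
  structure(list(enzyme = enzyme_name,
                 cds_coverage = if (total_cds > 0) covered / total_cds else NA_real_,
                 n_detectable_junctions = length(det),
                 junction_coverage = if (nrow(junctions))
                   length(det) / nrow(junctions) else NA_real_,
                 n_detectable_kr = length(det_kr),
                 kr_coverage = if (length(kr_keys))
                   length(det_kr) / length(kr_keys) else NA_real_,
                 detectable_keys = det, detectable_kr_keys = det_kr,
                 min_acceptor_nt = min_acceptor_nt,
                 min_donor_nt = min_donor_nt,
                 n_peptides = nrow(reps),
                 fingerprint = annotation_fingerprint(transcripts, junctions)),
            class = "coverage_report")
}

cds_ranges_by_contig <- function(transcripts) {
  dfs <- lapply(transcripts, function(ct) {
    seg <- coding_segments(ct$model)
    data.frame(contig = ct$model$contig, start = seg[, "start"],
               end = seg[, "end"])
  })
  all <- data.table::rbindlist(dfs)
  lapply(split(all, all$contig), function(d)
    IRanges::IRanges(start = d$start + 1L, end = d$end))
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("%s: CDS coverage %.1f%%; detectable junctions %d (%.1f%%); K/R %d (%.1f%%)\n",
              x$enzyme, 100 * x$cds_coverage, x$n_detectable_junctions,
              100 * x$junction_coverage, x$n_detectable_kr,
              100 * x$kr_coverage))
  invisible(x)
}

#' Summarise several coverage reports as a data.frame
#'
#' @param reports list of `coverage_report` objects
#' @return data.frame, one row per enzyme
#' @export
coverage_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(enzyme = r$enzyme, cds_coverage = r$cds_coverage,
               n_detectable_junctions = r$n_detectable_junctions,
               junction_coverage = r$junction_coverage,
               n_detectable_kr = r$n_detectable_kr,
               kr_coverage = r$kr_coverage, row.names = NULL)
  }))
}

#' Compare detectable-junction sets across enzymes
#'
#' Computes union and intersection sizes over the junction identity keys of
#' each enzyme's detectable set, the pairwise intersection matrix, and (for up
#' to three enzymes) exclusive Venn-region counts. Refuses to compare runs
#' made against different annotations.
#'
#' @param reports list of `coverage_report` objects (>= 2) from the same
#'   annotation
#' @param what `"all"` (all detectable junctions) or `"kr"` (K/R junctions)
#' @return list: `enzymes`, `union_size`, `intersection_size`,
#'   `pairwise_intersections` (matrix), and `region_counts` (exclusive
#'   membership-pattern counts, `NULL` for > 3 enzymes)
#' @export
compare_enzymes <- function(reports, what = c("all", "kr")) {
  what <- match.arg(what)
  if (length(reports) < 2L) stop("need at least two enzyme runs")
  fps <- vapply(reports, function(r) r$fingerprint, character(1))
  if (length(unique(fps)) != 1L) {
    stop("coverage reports come from different annotations")
  }
  sets <- lapply(reports, function(r)
    if (what == "kr") r$detectable_kr_keys else r$detectable_keys)
  names(sets) <- vapply(reports, function(r) r$enzyme, character(1))
  all_keys <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  pw <- matrix(NA_integer_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  inter <- Reduce(intersect, sets)
  region_counts <- NULL
  if (k <= 3L) {
    member <- vapply(sets, function(s) all_keys %in% s, logical(length(all_keys)))
    if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                                 dimnames = list(NULL, names(sets)))
    pattern <- apply(member, 1L, function(r)
      paste(names(sets)[r], collapse = "+"))
    region_counts <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
    names(region_counts) <- c("region", "count")
  }
  list(enzymes = names(sets), what = what,
       union_size = length(all_keys), intersection_size = length(inter),
       pairwise_intersections = pw, region_counts = region_counts)
}

# per-transcript segment scaffold used by type calls and distance histograms:
# cums = cumulative coding nt at each junction, in translation order
tx_cums <- function(transcripts) {
  lapply(transcripts, function(ct) transcript_junctions(ct)$cum_nt)
}

#' Classify peptide termini relative to splice sites (types 1-4)
#'
#' Works in spliced coding-sequence space (introns collapsed), in nt. Type 1:
#' the peptide's first base is the first base of an acceptor exon; type 2:
#' first base is the second base of an acceptor exon; type 3: last base is the
#' last base of a donor exon; type 4: junction-spanning peptide whose last
#' base is the first base of the acceptor exon (1-nt acceptor coverage). For
#' types 1-3 the terminus's coding segment must be internal (neither the
#' first nor the last coding exon), matching the exclusion used by the
#' boundary-distance histograms. A peptide can carry one start-type (1/2) and
#' one end-type (3/4) simultaneously; within a terminus the types are
#' mutually exclusive.
#'
#' @param peptides collapsed, uniquely mapped peptide table (representative
#'   rows are classified)
#' @param pep_junctions per-peptide junction table from [project_peptides()]
#' @param transcripts named list of `coding_transcript` objects
#' @return data.frame of calls: `pep_id`, `sequence`, `type` (1-4), and
#'   `offset_nt`, the signed distance used for the call
#' @export
classify_peptide_type <- function(peptides, pep_junctions, transcripts) {
  dt <- data.table::as.data.table(peptides)
  if ("is_representative" %in% names(dt)) {
    dt <- dt[dt$is_representative & dt$unique_genomic]
  }
  cums_all <- tx_cums(transcripts)
  pj <- data.table::as.data.table(pep_junctions)
  min_acc <- if (nrow(pj)) pj[, list(min_acc = min(acceptor_nt)),
                              by = "pep_id"] else NULL
  calls <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    cums <- cums_all[[dt$tx_id[i]]]
    res <- list()
    if (length(cums)) {
      nseg <- length(cums) + 1L
      pstart <- 3L * dt$start_res[i]
      pend <- 3L * dt$end_res[i] - 1L
      # start event: offset from the containing segment's acceptor start
      seg_s <- findInterval(pstart, cums) + 1L
      if (seg_s > 1L && seg_s < nseg) {
        off <- pstart - cums[seg_s - 1L]
        if (off == 0L) res <- c(res, list(c(1L, off)))
        if (off == 1L) res <- c(res, list(c(2L, off)))
      }
      # end event: offset back from the containing segment's donor end
      seg_e <- findInterval(pend, cums) + 1L
      if (seg_e > 1L && seg_e < nseg) {
        off <- (cums[seg_e] - 1L) - pend
        if (off == 0L) res <- c(res, list(c(3L, off)))
      }
      # type 4: junction-spanning, last base = acceptor's first base
      if (isTRUE(dt$spans_junction[i]) && !is.null(min_acc)) {
        k <- match(dt$pep_id[i], min_acc$pep_id)
        if (!is.na(k) && min_acc$min_acc[k] == 1L) {
          res <- c(res, list(c(4L, 1L)))
        }
      }
    }
    if (length(res)) {
      m <- do.call(rbind, res)
      calls[[i]] <- data.frame(pep_id = dt$pep_id[i],
                               sequence = dt$sequence[i],
                               type = m[, 1], offset_nt = m[, 2],
                               stringsAsFactors = FALSE)
    }
  }
  out <- data.table::rbindlist(calls)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(pep_id = integer(0), sequence = character(0),
                                  type = integer(0), offset_nt = integer(0))
  }
  as.data.frame(out)
}

#' Per-type fractions of uniquely mapped peptides
#'
#' @param calls data.frame from [classify_peptide_type()]
#' @param n_peptides total number of uniquely mapped peptide sequences
#' @return list: `fractions` (named, types 1-4), `counts`, `summed_ratio`
#'   (sum of the four fractions), `n_peptides`
#' @export
type_ratio_summary <- function(calls, n_peptides) {
  counts <- vapply(1:4, function(t)
    length(unique(calls$pep_id[calls$type == t])), integer(1))
  names(counts) <- paste0("type", 1:4)
  fr <- if (n_peptides > 0) counts / n_peptides else counts * NA_real_
  list(counts = counts, fractions = fr, summed_ratio = sum(fr),
       n_peptides = n_peptides)
}

#' Distance histograms between peptide termini and exon boundaries
#'
#' Counts uniquely mapped peptide sequences by the distance (nt, spliced
#' coding space) between a peptide terminus and the nearest relevant exon
#' boundary, in four categories: peptide starts vs acceptor exon starts
#' (offsets 0-10), peptide ends vs donor exon ends (0-10), junction-peptide
#' starts vs the donor exon end (1-10; the peptide's donor-side coverage of
#' its first spanned junction), and junction-peptide ends vs the acceptor
#' exon start (1-10; acceptor-side coverage of the last spanned junction).
#' For the first two categories the terminus's coding segment must be
#' internal. Each offset is tested one-sided against a uniform multinomial
#' null over the category's offset window (one-proportion z, sigma =
#' sqrt(N p0 (1 - p0)), no multiple-testing correction).
#'
#' @param peptides collapsed, uniquely mapped peptide table
#' @param pep_junctions per-peptide junction table
#' @param transcripts named list of `coding_transcript` objects
#' @param max_offset largest offset counted (default 10)
#' @return data.frame: `category`, `offset`, `count`, `n_category`,
#'   `expected`, `z`, `p`
#' @export
boundary_distance_histogram <- function(peptides, pep_junctions, transcripts,
                                        max_offset = 10L) {
  dt <- data.table::as.data.table(peptides)
  if ("is_representative" %in% names(dt)) {
    dt <- dt[dt$is_representative & dt$unique_genomic]
  }
  cums_all <- tx_cums(transcripts)
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(dt))) {
    cums <- cums_all[[dt$tx_id[i]]]
    if (!length(cums)) next
    nseg <- length(cums) + 1L
    pstart <- 3L * dt$start_res[i]
    pend <- 3L * dt$end_res[i] - 1L
    seg_s <- findInterval(pstart, cums) + 1L
    if (seg_s > 1L && seg_s < nseg) {
      off <- pstart - cums[seg_s - 1L]
      if (off <= max_offset) starts <- c(starts, off)
    }
    seg_e <- findInterval(pend, cums) + 1L
    if (seg_e > 1L && seg_e < nseg) {
      off <- (cums[seg_e] - 1L) - pend
      if (off >= 0L && off <= max_offset) ends <- c(ends, off)
    }
  }
  pj <- data.table::as.data.table(pep_junctions)
  pj <- pj[pj$pep_id %in% dt$pep_id]
  jstarts <- integer(0); jends <- integer(0)
  if (nrow(pj)) {
    firsts <- pj[, list(donor_nt = donor_nt[which.max(donor_nt)],
                        acceptor_nt = acceptor_nt[which.max(donor_nt)],
                        first_donor = donor_nt[which.min(donor_nt)],
                        last_acceptor = acceptor_nt[which.max(donor_nt)]),
                 by = "pep_id"]
    jstarts <- firsts$first_donor[firsts$first_donor <= max_offset]
    jends <- firsts$last_acceptor[firsts$last_acceptor <= max_offset]
  }
  rbind(
    histogram_block("starts_vs_acceptor", starts, 0L:max_offset),
    histogram_block("ends_vs_donor", ends, 0L:max_offset),
    histogram_block("junction_starts_vs_donor_end", jstarts, 1L:max_offset),
    histogram_block("junction_ends_vs_acceptor_start", jends, 1L:max_offset))
}

histogram_block <- function(category, offsets, window) {
  counts <- as.integer(table(factor(offsets, levels = window)))
  n <- sum(counts)
  p0 <- 1 / length(window)
  if (n > 0L) {
    expected <- n * p0
    z <- (counts - expected) / sqrt(n * p0 * (1 - p0))
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    expected <- rep(NA_real_, length(window))
    z <- rep(NA_real_, length(window))
    p <- rep(NA_real_, length(window))
  }
  data.frame(category = category, offset = window, count = counts,
             n_category = n, expected = expected, z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Write a boundary-distance histogram as TSV
#' @param hist data.frame from [boundary_distance_histogram()]
#' @param path output path
#' @return invisibly, the path
#' @export
write_histogram_tsv <- function(hist, path) {
  write.table(hist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
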