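# Independent oracles used to derive expected values. These deliberately take
# different computational routes from the package code they check.

# Position-scan digestion oracle: enumerate ALL residue substrings and keep
# those whose boundaries are cleavage boundaries (or protein termini) and
# whose internal cleavage-site count is within the missed-cleavage budget.
oracle_digest <- function(protein, residues, side, blocked, max_missed = 0L) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(aa)
  is_cut <- vapply(seq_len(max(L - 1L, 0L)), function(b) {
    hit <- if (side == "C") aa[b] %in% residues else aa[b + 1L] %in% residues
    hit && !(aa[b + 1L] %in% blocked)
  }, logical(1))
  cum <- c(0L, cumsum(as.integer(is_cut)))  # cum[b+1] = cuts in 1..b
  left_ok <- c(TRUE, is_cut)                # start i allowed
  right_ok <- c(is_cut, TRUE)               # end j allowed
  ij <- which(outer(seq_len(L), seq_len(L), "<=") &
                outer(left_ok, right_ok, "&") &
                outer(cum[seq_len(L)], cum[seq_len(L)],
                      function(a, b) b - a) <= max_missed,
              arr.ind = TRUE)
  sort(substring(protein, ij[, 1], ij[, 2]))
}

# Brute-force junction scan straight off the transcript models: walk exon
# adjacencies, keep those with coding sequence on both sides, and deduplicate
# on a string key. Independent of the cds_pos machinery.
oracle_junctions <- function(models) {
  keys <- character(0)
  for (m in models) {
    s <- pmax(m$exon_start, m$cds_start)
    e <- pmin(m$exon_end, m$cds_end)
    keep <- which(e > s)
    if (length(keep) < 2L) next
    for (t in seq_len(length(keep) - 1L)) {
      i <- keep[t]; k <- keep[t + 1L]
      if (m$strand == "+") {
        key <- paste(m$contig, "+", e[i] - 1L, s[k], sep = "|")
      } else {
        # translation order is descending genomic coordinate
        key <- paste(m$contig, "-", s[k], e[i] - 1L, sep = "|")
      }
      keys <- c(keys, key)
    }
  }
  unique(keys)
}

# Monte-Carlo oracle for the within-exon boundary-terminus rate: place
# fixed-length windows uniformly in a fixed-length exon and count windows
# touching either boundary.
oracle_boundary_rate_mc <- function(pep_len, exon_len, n_draws, seed = 1L) {
  set.seed(seed)
  starts <- sample.int(exon_len - pep_len + 1L, n_draws, replace = TRUE)
  mean(starts == 1L | (starts + pep_len - 1L) == exon_len)
}

# Random protein of given length over the 20-letter alphabet
random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
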