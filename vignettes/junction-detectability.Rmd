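---
title: "Protease choice and the detectability of splice-junction peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protease choice and the detectability of splice-junction peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Exon–exon junction-spanning peptides are the only direct protein-level
evidence that a particular splice isoform is translated. Whether such a
peptide can exist in a shotgun proteomics experiment is decided before the
mass spectrometer ever runs: the digestion protease fixes where peptides can
start and end. If a cleavage residue sits at or immediately next to a splice
site, the junction-spanning peptide is cut apart and the junction becomes
invisible (or nearly so) to that digest.

`juncpep` implements the full chain of reasoning needed to quantify this:

1. codon-resolved parsing of coding gene models against a genome;
2. enumeration of unique coding splice junctions with reading-frame phase
   and boundary residue;
3. amino-acid composition and enrichment at exon boundaries, splice-site
   nucleotide consensus matrices, and frame-adjusted cleavage-scenario
   probabilities;
4. multi-protease in-silico digestion, genomic projection, uniqueness
   handling, and per-enzyme junction detectability;
5. classification of observed peptide termini relative to splice sites
   (types 1–4) with positional enrichment tests;
6. a synthetic genome generator with plantable biases so that every stage is
   testable offline.

## Model and definitions

All coordinates are 0-based, half-open, and genomic internally; genePred
files are read natively and GTF is converted on input. All
transcript-relative quantities (phase, distances, boundary residues) are
computed in translation orientation; minus-strand blocks are stored in
genomic order with the strand as orientation flag.

For a junction between a 5′ donor exon and a 3′ acceptor exon, let $c$ be
the number of coding nucleotides upstream of the junction in the spliced
CDS. The **phase** is $c \bmod 3$: phase 0 junctions fall between codons,
phase 1/2 junctions split a codon after 1 or 2 donor nucleotides. The
**boundary residue** is the amino acid whose codon contains the donor exon's
final coding base — the exon-ending residue at phase 0, the
junction-crossing residue otherwise. A **K/R junction** has lysine or
arginine there, i.e. a tryptic cleavage site at (phase 0) or 1–2 nt past
(phase 2/1) the splice site. Junction identity is the tuple (contig, strand,
donor end, acceptor start); junctions shared between isoforms collapse to
one record, with isoform support counted.

Two cleavage scenarios follow from the phase. In scenario 1 (phase 0, K/R
boundary) the cleavage site coincides with the splice site, producing
peptides that *end at* the splice site (type 3) and peptides that *start
at* it (type 1). In scenario 2 (phase 2) cleavage lands 1 nt into the
acceptor exon, producing type 4 (junction peptide ending 1 nt into the
acceptor) and type 2 (peptide starting 1 nt past the site). Phase-1 K/R
junctions (cleavage 2 nt into the acceptor) are reported separately and not
folded into either scenario, since only offsets 0 and 1 show up as enriched
peptide-terminus positions. The frame-adjusted probability that a protease
cleaving after residue set $S$ recognises a splice site is
$\sum_{p} w_p \, P(\text{boundary} \in S \mid \text{phase}=p)$ with $w_p$
the phase usage — algebraically the overall fraction of junctions with a
boundary residue in $S$, decomposed so the per-frame table can be read off.

## Counting bases

Boundary composition is reported in two modes because the two downstream
uses differ: `"occurrence"` counts one boundary residue per (transcript,
junction) pair, the right basis for comparing against the redundant
background of all protein residues across isoforms; `"unique"` counts each
genomic junction once, the right basis for the K/R junction fraction.
Background usage is always computed redundantly over all coding transcripts.
Transcripts containing ambiguous residues (N in the CDS, translated as X)
are kept in the annotation but excluded from composition statistics so they
cannot skew either numerator or denominator; stop-codon boundary residues
(junctions inside the annotated stop) are likewise excluded from counts.

## Digestion and detectability

An enzyme is (residue set, terminus side, blocked set): cleavage happens
after (C-side) or before (N-side) a residue of the set, and is suppressed
when the residue immediately C-terminal of the cut is in the blocked set
(classically proline for trypsin). Two preset families are shipped. The
`"paper"` family matches the rules as tabulated in junction-coverage
comparisons — notably Glu-C cleaving after D, and chymotrypsin with no
proline block; the `"conventional"` family swaps in textbook specificities
(Glu-C after E/D, chymotrypsin with the proline block). Which family a given
historical digest used is an empirical question, so the family is an
explicit configuration choice rather than a default hidden in code. The
N-terminal methionine is not removed: the digestion input is the annotated
translation minus the stop, with no maturation rules applied.

Digestion products carry 0..`max_missed` internal missed cleavages; at zero
missed cleavages the products tile the protein exactly. The default filter
keeps fully cleaved peptides of 8–25 residues (inclusive), the length
window within which shotgun identification is routine.

Peptides are projected through the transcript's codon map to genomic blocks
(always summing to 3 nt per residue). A peptide sequence is **uniquely
mapped** iff all its occurrences across transcripts collapse to one genomic
block set; isoform-shared locations merge, paralogous locations make the
sequence ambiguous and exclude it downstream. A junction is **detectable**
iff some uniquely mapped peptide spans it with at least `min_acceptor_nt`
(default 3) nucleotides on the acceptor side and `min_donor_nt` (default 1)
on the donor side. The 3-nt acceptor default excludes both type-4 peptides
(1-nt acceptor coverage) and the 2-nt case, whose acceptor-exon assignment
is too constrained to verify a junction. The donor-side minimum is not
constrained by any published rule; 1 nt is the weakest symmetric choice and
both thresholds are recorded in the coverage report.

## Positional enrichment and its null

Peptide-terminus positions are compared with exon boundaries in spliced
coding space, in nucleotides, in four categories (starts vs acceptor
starts, ends vs donor ends, junction-peptide starts vs donor end,
junction-peptide ends vs acceptor start; windows 0–10 or 1–10). For the
first two categories the terminus's coding segment must be internal —
neither the first nor the last coding exon — and the same exclusion is
applied to type 1–3 calls so that type counts and histogram cells agree
exactly (type 1 = starts at offset 0, type 2 = starts at 1, type 3 = ends
at 0, type 4 = junction ends at 1). Counting is over distinct uniquely
mapped peptide sequences, not spectra.

Each offset is tested one-sided against a uniform multinomial null over the
category's window: $z = (k - Np_0)/\sqrt{Np_0(1-p_0)}$, $p_0$ = 1/window
size, with no multiple-testing correction — the simplest null consistent
with asking which positions carry more termini than chance.

One genuine limitation of that null is worth knowing. Peptide termini are
codon-aligned, so the offsets reachable from a given junction form a fixed
mod-3 class determined by its phase; with a skewed phase distribution
(human-like 0.47/0.30/0.23) offset 0 carries probability $w_0/4 \approx
0.118$ rather than $1/11 = 0.091$ even for peptides placed uniformly at
random. The uniform null is therefore anti-conservative at the boundary
offsets on phase-skewed annotations, independently of any protease effect.
The package's null-calibration test runs on phase-symmetric synthetic
genomes, where the class structure makes the boundary cells mildly
conservative, and checks that the type-defining offsets (starts 0/1, ends
0, junction-ends 1) are not flagged at $\alpha = 0.005$ in at least 95% of
200 replicates. Significance calls at other offsets on real, phase-skewed
annotations should be read with the mod-3 comb in mind.

## The synthetic generator

The generator emulates exactly the features the analysis consumes: genes of
4–8 exons (configurable), exon coding lengths of 90–300 nt bracketing the
~200-nt median of human internal coding exons, intron lengths 60–200 nt,
GT..AG introns with probability 0.99, one gene per contig with 25-nt
intergenic flanks and 0–30-nt UTR extensions on terminal exons, strands
sampled 50/50. Junction phases are drawn from configurable weights (default
0.47/0.30/0.23, the long-known human phase usage) and the boundary residue
is planted as K/R with configurable probability (default 0.25, the
frame-adjusted rate seen in human annotations): at phase 0 the planted
codon is the donor's last triplet, at phase 2 it is split 2+1 across the
junction, at phase 1 split 1+2. All other codons are drawn from a
configurable codon-usage table (default uniform over the 61 sense codons),
with ATG start and a sampled stop. Setting `p_boundary_kr = 8/61` under
uniform usage yields a bias-free annotation, which is how the fold-change
and consensus null tests compute their own background. Generation is fully
reproducible from the seed and leaves the caller's RNG state untouched.

What the generator does **not** emulate: real exon/intron length
distributions beyond uniform ranges, human codon usage, sequence
composition gradients around splice sites beyond the planted boundary
codons, selenocysteine or non-standard codes, alternative splicing beyond
optional duplicate isoforms, and any model of peptide abundance or spectral
detectability beyond a length-window detection probability. Passing tests
on synthetic data therefore demonstrate correctness of the computation and
direction of the enzyme effects, not numerical agreement with any
particular genome annotation; published human numbers additionally depend
on the specific annotation snapshot used.

## Numerical and degenerate-input choices

* Position frequency matrices use no pseudocount; zero-coverage positions
  are `NA`, and flanks overrunning a contig are skipped with a warning.
* Transcripts with non-multiple-of-3 CDS, exons outside contigs, or
  in-frame internal stops are dropped with warnings; non-coding transcripts
  are dropped silently.
* Junctions shared by isoforms with discordant upstream structure would in
  principle carry isoform-dependent phases; deduplication keeps the
  first-seen phase and boundary residue.
* Empty inputs return empty, well-formed results (zero coverages, `NA`
  fold changes); an empty junction set is an error only where a consensus
  matrix is meaningless.
* The closed-form expected rate of boundary-touching termini,
  $2/(L_\text{exon} - L_\text{pep})$ in amino acids, is capped at 1 and
  approximates the exact discrete rate $2/(L_\text{exon} - L_\text{pep} +
  1)$; the tests compare it against a Monte-Carlo placement oracle at that
  discretisation error.

## Problem sizes used by the test-suite

The packaged tests run entirely on generated data: annotations of 120–1,750
genes for module tests, three 20,000-junction annotations for parameter
recovery, 100 seeded replicates of ~45-gene genomes for the
trypsin-vs-chymotrypsin directional checks, and 200 replicates of 5,000
uniformly placed peptides for null calibration. These sizes make the
binomial error bars small enough for 3-SE recovery checks while keeping the
whole suite comfortably runnable on a laptop.

## Worked example

```{r, eval = FALSE}
library(juncpep)

cfg <- synthetic_config(n_genes = 300, seed = 20170101)
g <- generate_genome(cfg, dir = "results/data")

res <- run_junction_analysis(g$genome, g$models)
res$kr$fraction_kr                 # ~0.25: planted K/R junction rate
res$scenarios                      # phase usage and scenario probabilities

dig <- run_digestion_analysis(res$transcripts, res$junctions,
                              enzyme_presets("paper"))
coverage_table(dig$reports)        # per-enzyme CDS/junction/K-R coverage

obs <- simulate_observed_peptides(res$transcripts,
                                  enzyme_presets("paper")$Trypsin,
                                  seed = 20170102)
cls <- run_classification_analysis(res$transcripts, res$junctions, obs)
cls$ratios$summed_ratio            # fraction of type 1-4 peptides
```

The `analysis/` directory of the source repository runs this exact sequence
as four numbered scripts, writing all tables under `results/`.
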