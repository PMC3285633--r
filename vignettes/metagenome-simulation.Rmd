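---
title: "Simulating metagenomes and assessing their assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating metagenomes and assessing their assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagsim)
```

Benchmarking metagenomic software needs data where the truth is known:
which genome every read came from, where it came from, and which of its
bases are wrong. `metagsim` simulates shotgun metagenomes for three
sequencing platforms (Sanger, pyrosequencing, Illumina) with
platform-specific quality and error models, and provides the matching
assessment toolkit for scoring any assembly of the simulated data
against that recorded truth. This vignette describes the models, the
tunable parameters, and the design decisions behind them.

## Community model

A simulated community is a rank-abundance profile: relative organism
abundances in decreasing order. Three standard shapes are built in —
uniform, geometric (abundance of rank $r$ proportional to
$\rho^{r-1}$), and a deterministic lognormal quantile curve — plus
direct user-supplied abundance vectors. The lognormal curve uses
quantiles rather than random draws so that a given $(n, \sigma)$ always
produces the same community; randomness belongs to the sequencing
simulation, not the community definition.

Sequencing effort is divided among genomes with weights
$w_i = a_i \cdot L_i$ (abundance times genome length): abundances are
interpreted as *organism* (cell) abundances, so the DNA each organism
contributes to the sequencing pool — and hence its share of reads —
scales with its genome size. Fractional shares are rounded by the
largest-remainder method, which conserves the requested total exactly
and keeps every count within one read of its exact real-valued share.

Synthetic reference genomes are i.i.d. base sequences with a target GC
content. They stand in for real references when exercising the
pipeline; see *What the generator does not emulate* below.

## Quality models

Phred-scaled quality values are tied to error probabilities through the
odds form

$$Q = -10 \log_{10}\!\frac{P}{1-P}, \qquad P = \frac{1}{1+10^{Q/10}},$$

so $Q = 0$ means $P = 0.5$ and $Q = 20$ means $P = 1/101 \approx
0.0099$. This differs from the classical Phred rule $P = 10^{-Q/10}$ in
the low-quality regime (at high quality the two converge); both are
available through the `convention` argument, with the odds form as the
default the simulator is calibrated to.

Quality profiles are per-cycle descriptions of quality behaviour:

* **empirical** profiles are loaded from `.qual` files of real runs
  (one file per run); cycle $c$ keeps the full observed distribution of
  the $c$-th quality value, and sampling draws from it directly;
* **parametric** profiles store per-cycle `(mean, sd)` and sample from
  a rounded Normal truncated to $[0, 93]$, the encodable Sanger-FASTQ
  range.

Many runs of a common read length can be collapsed into a few
representative error models by k-means clustering of their per-cycle
mean-quality vectors (Euclidean distance); the cluster count is a free
parameter since real run collections differ. Parametric positional fits
(constant, linear decay, or two-piece linear with a grid-searched
breakpoint) are available to condense empirical profiles; the fit is a
least-squares fit of per-cycle mean quality against cycle index, and
the per-cycle empirical sd is retained for sampling.

When no empirical profiles are supplied, clearly-labelled parametric
defaults are used: Illumina 75 bp with mean quality decaying linearly
Q35 to Q25 (sd 3); Sanger with the classic capillary rise-plateau-fall
envelope over relative position (Q15 rising to a Q40 plateau in the
first 10 % of the read, falling to Q10 over the final 20 %, sd 5); and
pyrosequencing at constant Q28 (sd 2) with homopolymer errors handled
at injection time.

## Read simulation

Paired-end (Illumina) simulation samples inserts with
Normal(`insert_size`, `insert_sd`) sizes, rounded and clamped to
`[read_length, genome length]`, uniform start positions and fair-coin
strands. Read /1 is the first `read_length` bases of the insert on its
strand; read /2 is the reverse complement of the last `read_length`
bases (innie orientation). Single-end platforms draw per-read lengths:
fixed for Illumina; Normal(800, 100) truncated at 100 bp for Sanger and
Normal(255, 25) truncated at 50 bp for pyrosequencing, matching typical
platform read lengths. All coordinates are 0-based half-open and
minus-strand reads are stored as sequenced.

Error injection substitutes each base independently with probability
`phred_to_error_prob(Q)` of its sampled quality value, choosing the
substitute uniformly from the three alternatives. Illumina and Sanger
are substitution-only. Pyrosequencing adds the platform's signature
homopolymer-length errors: every run of two or more identical bases
suffers, with probability equal to the error probability of the run's
first base, a ±1 length change (fair coin); an inserted base duplicates
the run base and its quality value. This is a deliberately simple,
testable rule rather than a flowgram-level model.

Every read carries a truth record — source genome, coordinates, strand,
mate, and the exact positions and types of injected errors — written as
a TSV alongside the reads. The read ids additionally encode
`genome:start-end:strand` for human debugging, but the TSV is the
authoritative record. A single seeded generator drives the whole
simulation, so a config plus seed reproduces byte-identical outputs.

## Quality control

The Illumina QC pipeline applies three steps in order:

1. **5′ composition trim.** Per-cycle base frequencies are aggregated
   over all reads; a cycle is aberrant when some base's frequency
   deviates from its cross-cycle mean by more than 2 standard
   deviations *and* by more than `min_dev` (default 0.02) in absolute
   frequency. The leading prefix up to the last aberrant cycle within
   the first `window` (default 10) cycles is removed from every read.
   The statistic is population-level, so the trim is a single global
   offset; aberrant cycles beyond the window are reported but not
   trimmed, since a 5′ operation must remain a prefix operation. The
   `min_dev` floor exists because on artefact-free data the cross-cycle
   sd is pure sampling noise, and a bare 2-sd band would flag clean
   cycles at random (about 5 % per base and cycle); genuine artefacts
   deviate by tenths, sampling noise at realistic read counts by
   thousandths. Below roughly $10^4$ reads the floor no longer
   dominates the noise and occasional spurious single-cycle trims can
   occur.
2. **3′ quality trim.** Trailing bases are removed while the terminal
   base's quality is below `q_trim` (default Q20). Interior low-quality
   bases are kept.
3. **Read filter.** Reads shorter than 35 bases or with median quality
   below 20 are removed (length checked first). The median of an even
   number of quality values is the mean of the two central values — the
   standard convention.

The report accounts for reads and bases in/out and a histogram of
removal reasons. On reads simulated with a steeply decaying quality
model the fraction mappable to the source genomes within 2 mismatches
rises sharply after QC — the qualitative behaviour that motivates
aggressive quality control of short-read metagenomes.

## Assembly assessment

**Read-back mapping** is an exhaustive ungapped k-mismatch search (both
strands, all loci, default 2 mismatches) built on the pigeonhole
principle: a read cut into $k+1$ segments must match one segment
exactly wherever it aligns with at most $k$ mismatches, so exact
segment hits from an Aho-Corasick dictionary scan generate candidate
placements that are then verified by Hamming distance. This is
intended for desk-scale genome sets, not production alignment.
**Genome coverage** is the fraction of reference positions under at
least one alignment.

**Chimericity.** A contig is chimeric when it combines reads from more
than one source genome. Because short reads legitimately match several
genomes and assemblers may assign one read to several contigs, the
Illumina-mode definition restricts the test to uniquely-assigned reads;
the classic mode uses all reads. The *degree of chimericity* is the
fraction of a contig's reads not from its majority genome, with
majority ties broken by lexicographically smallest genome id for
determinism. Single-read contigs are never chimeric.

**Contig Score** measures how faithfully a contig represents its source
genome without reference to read provenance: the best local alignment
(HSP) of the contig against any reference is found by Smith-Waterman
with match +1, mismatch −2, gap open −5, gap extend −2 — parameters
suited to the high-identity contig-versus-source setting — and the
score is percent identity of that HSP times the percent of the contig
it covers, divided by 100, so a full-length perfect match scores
exactly 100. Identity counts matches over all alignment columns, gap
columns included. Alignments scoring below 20 are treated as no HSP
(score 0). Ties between genomes are broken by higher identity, then
lower genome id.

**Length statistics** use the standard cumulative-from-largest N50:
sort lengths in decreasing order, accumulate, and report the first
length at which the running sum reaches half the total. (Assembly
tables are sometimes captioned with the inverted "fragments of length
L &lt; N" wording; the conventional definition is implemented.)
Summaries are computed over contigs strictly longer than `min_len`
(default 500 bp), matching how assembly tables are usually presented,
and the Contig-Score percentile statistics are taken over that same
population. **Scaftigs** are the maximal N-free substrings of a
scaffold, in order; concatenating them with the removed N-runs
reconstructs the scaffold exactly.

## Functional profiles

Functional-category counts (e.g. COG assignments) are normalized to
probability distributions. The *expected* profile of a community
weights each genome's category counts by its sequencing share
$a_i L_i$ — the same weight that allocates reads — so the expectation
matches what unlimited, error-free sequencing of that community would
annotate. Profiles are compared by Jensen-Shannon divergence with
logarithms base 2 (maximum 1 bit) and the $0 \log 0 = 0$ convention,
after zero-filling each profile onto the union of categories; the
associated distance is $\sqrt{JSD}$, which is a metric. Ordination
uses classical PCoA (double-centre $-D^2/2$, eigendecompose, scale
eigenvectors by $\sqrt{\lambda}$); negative eigenvalues from
non-Euclidean distances are dropped and reported, not corrected. PCA
of the profile matrix (column-centred covariance eigenanalysis) and
Pearson correlation against the expected profile complete the toolkit.

## What the synthetic generator does and does not emulate

The package's fixture genomes are i.i.d. base sequences. They share
with real genomes only length and GC content — no repeats, no shared
homologous regions between community members, no codon structure, no
local GC skew. Consequences for interpreting passing tests:

* mapping and chimericity tests run in a clean room: reads almost never
  map across genomes by chance, so cross-genome assignment observed in
  tests is always constructed, never incidental. Real communities with
  conserved regions will show more multi-mapping and more ambiguous
  chimericity calls;
* the default quality models are parametric stand-ins with the right
  shape (linear decay, rise-plateau-fall, constant), not refits of any
  specific instrument's empirical profiles — supply your own `.qual`
  files for machine-realistic simulations;
* error injection is independent per base (plus the homopolymer rule
  for pyrosequencing); real instruments have correlated error bursts
  and sequence-context effects.

Passing tests therefore demonstrate the correctness of the machinery —
allocation arithmetic, coordinate bookkeeping, error accounting, metric
definitions — not that simulated data are indistinguishable from real
runs.

## Numerical choices and degenerate inputs

* Quality values are capped to $[0, 93]$ at encoding time (Phred+33);
  conversions themselves are exact and uncapped.
* Read-length and insert-size Normal draws are rounded, then clamped to
  platform floors (100 bp Sanger, 50 bp pyro) and to the genome length;
  at the default means these truncations are many standard deviations
  out and do not bias the means measurably.
* Abundances must be strictly positive; profiles renormalize to sum to
  1 within 1e-9.
* Empty reads may be produced by 3′ trimming and are removed by the
  length filter with reason `too_short`.
* An all-zero distance matrix yields a zero-axis ordination rather than
  an error; asymmetric or negative-diagonal matrices are rejected.
* k-means clustering uses 25 random starts; with `k` equal to the
  number of profiles the trivial singleton partition is returned
  directly.

## Problem sizes

The test-suite simulations are sized for quick, repeatable runs on one
core: communities of 2-10 synthetic genomes of 5-100 kb, read sets of
$10^2$ to $1.2\times10^5$ reads, and $10^4$ draws for distributional
checks against 3-standard-error bands. These sizes put Monte-Carlo
noise well below the tested tolerances while keeping the whole suite in
the minutes range.

## Known limitations

* No chimeric-fragment or PCR-duplicate simulation, no flowgram-level
  pyrosequencing model, no colour-space reads, no vector/linker
  contamination in Sanger reads.
* The k-mismatch mapper and the seed-free Smith-Waterman Contig Score
  are exhaustive by design and scale to desk-sized genome sets only.
* Scaffolding itself is out of scope; only scaftig extraction from
  given scaffolds is provided.
* The 5′ composition statistic is computed on the common prefix of the
  read set (cycles up to the shortest read).

## A minimal end-to-end run

```{r example, eval = FALSE}
genomes <- generate_synthetic_genomes(5, length = 5e4, seed = 1)
profile <- build_rank_abundance(5, "geometric", list(ratio = 0.6),
                                genome_ids = names(genomes))
sim <- simulate_metagenome(genomes, 20000, profile = profile,
                           platform = "illumina", seed = 1)
qc <- qc_pipeline(sim$reads)
aln <- map_reads_to_genomes(qc$reads, genomes)
length(unique(aln$read_id)) / nrow(qc$reads)   # mappable fraction
```
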