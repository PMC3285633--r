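#' Map reads back to reference genomes with at most k mismatches
#'
#' Exhaustive ungapped k-mismatch mapping of full-length reads against a
#' set of genomes, both strands, reporting *all* loci within the
#' mismatch budget. Uses the pigeonhole principle: each read is cut into
#' `max_mismatches + 1` segments, at least one of which must match
#' exactly at a true locus; exact segment hits are found with an
#' Aho-Corasick dictionary scan ([Biostrings::matchPDict()]) and every
#' candidate placement is then verified by Hamming distance. Intended
#' for desk-scale genome sets.
#'
#' @param reads Read-set data.frame or character vector of sequences
#'   (names become read ids).
#' @param genomes Named character vector of reference sequences.
#' @param max_mismatches Mismatch budget (default 2).
#' @return data.frame with columns `read_id`, `genome_id`, `start`
#'   (0-based), `end`, `strand`, `mismatches`; one row per reported
#'   alignment.
#' @export
map_reads_to_genomes <- function(reads, genomes, max_mismatches = 2L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else unname(reads)
  ids <- if (is.data.frame(reads)) reads$read_id
         else (names(reads) %||% paste0("read", seq_along(reads)))
  if (length(seqs) == 0L || length(genomes) == 0L) {
    stop("reads and genomes must be non-empty")
  }
  if (is.null(names(genomes))) stop("genomes must be named")
  k <- as.integer(max_mismatches)
  if (all(nchar(seqs) > max(nchar(genomes)))) {
    stop("every read is longer than every genome")
  }

  hits <- list()
  by_len <- split(seq_along(seqs), nchar(seqs))
  for (orient in c("+", "-")) {
    q_all <- if (orient == "+") seqs else revcomp(seqs)
    for (len_chr in names(by_len)) {
      L <- as.integer(len_chr)
      if (L == 0L) next
      idx <- by_len[[len_chr]]
      q <- q_all[idx]
      nseg <- min(k + 1L, L)
      w <- L %/% nseg
      seg_off <- (seq_len(nseg) - 1L) * w              # 0-based offsets
      seg_w <- c(rep(w, nseg - 1L), L - (nseg - 1L) * w)
      pdicts <- lapply(seq_len(nseg), function(j) {
        Biostrings::PDict(Biostrings::DNAStringSet(
          substr(q, seg_off[j] + 1L, seg_off[j] + seg_w[j])))
      })
      for (gid in names(genomes)) {
        gseq <- genomes[[gid]]
        glen <- nchar(gseq)
        if (L > glen) next
        subject <- Biostrings::DNAString(gseq)
        cand_read <- integer(0); cand_start <- integer(0)
        for (j in seq_len(nseg)) {
          mi <- Biostrings::matchPDict(pdicts[[j]], subject)
          st <- Biostrings::startIndex(mi)
          nh <- lengths(st)
          if (sum(nh) == 0L) next
          r <- rep.int(seq_along(q), nh)
          s <- unlist(st, use.names = FALSE) - seg_off[j]  # 1-based read start
          ok <- s >= 1L & s + L - 1L <= glen
          cand_read <- c(cand_read, r[ok])
          cand_start <- c(cand_start, s[ok])
        }
        if (!length(cand_read)) next
        dup <- duplicated(cand_read * (glen + 1) + cand_start)
        cand_read <- cand_read[!dup]; cand_start <- cand_start[!dup]
        ref <- substring(gseq, cand_start, cand_start + L - 1L)
        mm <- hamming(q[cand_read], ref)
        keep <- mm <= k
        if (!any(keep)) next
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = ids[idx[cand_read[keep]]],
          genome_id = gid,
          start = cand_start[keep] - 1L,
          end = cand_start[keep] - 1L + L,
          strand = orient,
          mismatches = mm[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(read_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Fraction of a genome covered by alignments
#'
#' @param alignments Alignment data.frame from [map_reads_to_genomes()]
#'   (0-based half-open `start`/`end`, `genome_id`).
#' @param genome A single named genome sequence, or a named length.
#' @return Fraction of genome positions covered by >= 1 alignment.
#' @export
genome_coverage <- function(alignments, genome) {
  gid <- names(genome)
  if (is.null(gid)) stop("genome must be named")
  glen <- unname(if (is.character(genome)) nchar(genome)
                 else as.numeric(genome))
  a <- alignments[alignments$genome_id == gid, , drop = FALSE]
  if (nrow(a) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L, end = a$end))
  sum(IRanges::width(ir)) / glen
}

#' Classify a contig as chimeric
#'
#' A chimeric contig combines reads originating from more than one
#' source genome. Two modes: `classic` considers all constituent reads
#' (the Sanger-era definition); `illumina` considers only
#' uniquely-mapping reads (reads assigned to exactly one contig), since
#' short reads can legitimately match several genomes and be assigned to
#' several contigs. A contig whose (relevant) reads all come from one
#' genome — in particular any single-read contig — is not chimeric.
#'
#' @param contig_reads data.frame with columns `source_genome` and, for
#'   illumina mode, `is_unique` (logical).
#' @param mode `"classic"` or `"illumina"`.
#' @return Logical flag.
#' @export
classify_chimeric <- function(contig_reads, mode = c("classic", "illumina")) {
  mode <- match.arg(mode)
  if (nrow(contig_reads) == 0L) stop("contig has no reads")
  src <- contig_reads$source_genome
  if (mode == "illumina") {
    if (is.null(contig_reads$is_unique)) {
      stop("illumina mode needs an is_unique column")
    }
    src <- src[contig_reads$is_unique]
  }
  length(unique(src)) > 1L
}

#' Degree of chimericity of a contig
#'
#' The fraction of a contig's reads that do not originate from its
#' majority source genome: `(n_reads - majority count) / n_reads`. Ties
#' for the majority genome are broken by the lexicographically smallest
#' genome id, for determinism.
#'
#' @param source_genomes Character vector: source genome of each
#'   constituent read (or a data.frame with a `source_genome` column).
#' @return List with `degree` (fraction in `[0, 1 - 1/n]`) and
#'   `majority_genome`.
#' @export
degree_of_chimericity <- function(source_genomes) {
  if (is.data.frame(source_genomes)) {
    source_genomes <- source_genomes$source_genome
  }
  n <- length(source_genomes)
  if (n == 0L) stop("contig has no reads")
  tab <- table(source_genomes)
  top <- names(tab)[tab == max(tab)]
  majority <- sort(top)[1]
  list(degree = (n - max(tab)) / n, majority_genome = majority)
}

#' Contig Score: identity-weighted coverage of the best HSP
#'
#' Locally aligns the contig against every reference genome
#' (seed-free Smith-Waterman via [Biostrings::pairwiseAlignment()];
#' match +1, mismatch -2, gap open -5, gap extend -2) and takes the
#' highest-scoring alignment (HSP); ties are broken by higher percent
#' identity, then lower genome id. The score is
#' `percent identity x percent of the contig covered by the HSP / 100`,
#' so a full-length perfect match scores exactly 100. Percent identity
#' counts matches over all alignment columns (gap columns included).
#' If no alignment reaches `min_score` the Contig Score is 0.
#'
#' @param contig Contig sequence (character scalar).
#' @param genomes Named character vector of reference genomes.
#' @param min_score Minimum alignment score to report an HSP
#'   (default 20).
#' @return List with `score` (0-100), `genome_id`, `percent_identity`,
#'   `percent_coverage`, `alignment_score`.
#' @export
contig_score <- function(contig, genomes, min_score = 20) {
  if (!is.character(contig) || length(contig) != 1L || !nzchar(contig)) {
    stop("contig must be a single non-empty sequence")
  }
  if (length(genomes) == 0L) stop("no genomes supplied")
  if (is.null(names(genomes))) stop("genomes must be named")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best <- NULL
  for (gid in sort(names(genomes))) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = contig, subject = genomes[[gid]], type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
    s <- Biostrings::score(aln)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    cols <- nchar(ap)
    matches <- sum(charToRaw(ap) == charToRaw(as_))
    pid <- 100 * matches / cols
    hsp_len <- Biostrings::width(Biostrings::pattern(aln))
    cov <- 100 * hsp_len / nchar(contig)
    cand <- list(alignment_score = s, percent_identity = pid,
                 percent_coverage = cov, genome_id = gid)
    if (is.null(best) ||
        s > best$alignment_score ||
        (s == best$alignment_score && pid > best$percent_identity)) {
      best <- cand
    }
  }
  if (best$alignment_score < min_score) {
    return(list(score = 0, genome_id = NA_character_,
                percent_identity = NA_real_, percent_coverage = NA_real_,
                alignment_score = best$alignment_score))
  }
  best$score <- best$percent_identity * best$percent_coverage / 100
  best[c("score", "genome_id", "percent_identity", "percent_coverage",
         "alignment_score")]
}

#' N50 of a set of fragment lengths
#'
#' The standard cumulative-from-largest convention: sort lengths in
#' decreasing order and accumulate; N50 is the first length at which the
#' cumulative sum reaches half the total assembled bases.
#'
#' @param lengths Positive numeric vector of fragment lengths (bp).
#' @return The N50 length (bp).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1]]
}

#' Assembly length summary
#'
#' Length statistics over contigs strictly longer than `min_len`
#' (matching the usual ">500 bp" presentation of assembly tables):
#' count, summed length, N50, longest and mean length.
#'
#' @param contigs Named character vector of contig sequences, or a
#'   numeric vector of contig lengths.
#' @param min_len Length cutoff in bp; only contigs with
#'   `length > min_len` enter the summary (default 500).
#' @return List with `n_contigs`, `sum_length`, `n50`, `longest`,
#'   `mean_length`, and `empty` (TRUE when no contig passes the cutoff;
#'   the statistics are then 0/NA).
#' @export
assembly_summary <- function(contigs, min_len = 500L) {
  if (length(contigs) == 0L) stop("empty contig set")
  len <- if (is.numeric(contigs)) contigs else nchar(contigs)
  keep <- len > min_len
  if (!any(keep)) {
    return(list(n_contigs = 0L, sum_length = 0, n50 = NA_real_,
                longest = NA_real_, mean_length = NA_real_, empty = TRUE))
  }
  lk <- len[keep]
  list(n_contigs = sum(keep), sum_length = sum(lk), n50 = n50(lk),
       longest = max(lk), mean_length = mean(lk), empty = FALSE)
}

#' Extract scaftigs from a scaffold
#'
#' Scaffolds link contigs with runs of unknown bases (N) in the gaps;
#' scaftigs are the maximal N-free contiguous subsequences, returned in
#' order. Any run of one or more Ns splits the scaffold.
#'
#' @param scaffold Scaffold sequence over A/C/G/T/N (character scalar).
#' @return Character vector of scaftig sequences (may be empty).
#' @export
extract_scaftigs <- function(scaffold) {
  stopifnot(is.character(scaffold), length(scaffold) == 1L)
  if (grepl("[^ACGTN]", scaffold)) {
    stop("scaffold must contain only A/C/G/T/N")
  }
  parts <- strsplit(scaffold, "N+")[[1]]
  parts[nzchar(parts)]
}

#' Read a read-to-contig assignment table
#'
#' Two-column TSV `read_id <tab> contig_id` (e.g. converted from a
#' short-read aligner's read-to-contig mapping). A read is
#' uniquely-mapping if it appears under exactly one contig.
#'
#' @param path TSV path (no header).
#' @return data.frame with `read_id`, `contig_id`, `is_unique`.
#' @export
read_contig_map <- function(path) {
  d <- read.delim(path, header = FALSE,
                  col.names = c("read_id", "contig_id"),
                  colClasses = "character")
  annotate_uniqueness(d)
}

# Mark reads assigned to exactly one contig.
annotate_uniqueness <- function(assignments) {
  n_contigs <- tapply(assignments$contig_id, assignments$read_id,
                      function(x) length(unique(x)))
  assignments$is_unique <- unname(n_contigs[assignments$read_id] == 1L)
  assignments
}

#' Assess every contig of an assembly against the simulation truth
#'
#' Joins a read-to-contig assignment with the simulator's truth table
#' and computes, per contig: read count, chimeric flag (in the requested
#' mode), degree of chimericity and majority source genome; optionally
#' the Contig Score when contig sequences and genomes are supplied.
#'
#' @param assignments data.frame with `read_id`, `contig_id` (an
#'   `is_unique` column is added if absent); e.g. from
#'   [read_contig_map()] or built from truth-based placement.
#' @param truth Truth table from [simulate_metagenome()] (needs
#'   `read_id`, `genome_id`).
#' @param mode Chimericity mode, `"classic"` or `"illumina"`.
#' @param contigs Optional named character vector of contig sequences
#'   (enables `length` and `contig_score` columns).
#' @param genomes Optional named character vector of reference genomes
#'   (required for contig scores).
#' @return data.frame, one row per contig: `contig_id`, `n_reads`,
#'   `chimeric`, `degree_of_chimericity`, `majority_genome`, plus
#'   `length` and `contig_score` when sequences are available.
#' @export
assess_contigs <- function(assignments, truth,
                           mode = c("classic", "illumina"),
                           contigs = NULL, genomes = NULL) {
  mode <- match.arg(mode)
  if (is.null(assignments$is_unique)) {
    assignments <- annotate_uniqueness(assignments)
  }
  src <- truth$genome_id[match(assignments$read_id, truth$read_id)]
  if (anyNA(src)) {
    stop("assignments contain read ids absent from the truth table")
  }
  assignments$source_genome <- src
  per <- split(assignments, assignments$contig_id)
  rows <- lapply(per, function(d) {
    doc <- degree_of_chimericity(d$source_genome)
    data.frame(contig_id = d$contig_id[1],
               n_reads = nrow(d),
               chimeric = classify_chimeric(d, mode),
               degree_of_chimericity = doc$degree,
               majority_genome = doc$majority_genome,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(contigs)) {
    out$length <- nchar(contigs[out$contig_id])
    if (!is.null(genomes)) {
      out$contig_score <- vapply(out$contig_id, function(cid) {
        contig_score(contigs[[cid]], genomes)$score
      }, numeric(1))
    }
  }
  out
}
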