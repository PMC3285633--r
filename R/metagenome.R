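#' Simulate a shotgun metagenome
#'
#' End-to-end simulation: allocate sequencing effort across the community
#' (abundance x genome length, largest-remainder rounding), sample
#' inserts/reads uniformly from each genome on both strands, draw quality
#' strings from the platform quality model, inject base-call errors at
#' the probability implied by each quality value, and emit reads plus a
#' ground-truth provenance table. Deterministic given `seed`.
#'
#' Illumina runs are paired-end by default (`n` counts inserts, each
#' yielding a /1 and /2 read); Sanger and pyrosequencing are single-end
#' with platform length distributions (see
#' [simulate_platform_read_length()]).
#'
#' @param genomes Named character vector of reference sequences (ACGT).
#' @param n Total number of inserts (paired) or reads (single-end).
#' @param profile A `community_profile`; default uniform over `genomes`.
#' @param platform `"illumina"`, `"sanger"` or `"pyro"`.
#' @param paired Paired-end? Default TRUE for Illumina, FALSE otherwise.
#' @param read_length Illumina read length (default 75).
#' @param insert_size,insert_sd Insert size model for paired mode
#'   (defaults 300 and 30 bp).
#' @param read_length_sd Read-length sd for variable-length platforms
#'   (default: platform default).
#' @param quality_model A `quality_profile`; default
#'   `default_quality_model(platform, read_length)`.
#' @param convention Phred convention (`"odds"` or `"standard"`).
#' @param seed Integer seed; the caller's RNG stream is preserved.
#' @param out_prefix If non-NULL, write outputs: `<prefix>.fastq`
#'   (Illumina, interleaved pairs) or `<prefix>.fasta` + `<prefix>.qual`
#'   (Sanger/pyro), plus `<prefix>.truth.tsv` and
#'   `<prefix>.summary.tsv`.
#' @return (Invisibly if writing) a list with elements `reads` (read-set
#'   data.frame: `read_id`, `sequence`, `quality`), `truth` (truth-table
#'   data.frame), `summary` (per-genome data.frame with read counts,
#'   bases and expected coverage), and `files` (paths written, or NULL).
#' @export
simulate_metagenome <- function(genomes, n,
                                profile = NULL,
                                platform = c("illumina", "sanger", "pyro"),
                                paired = NULL,
                                read_length = 75L,
                                insert_size = 300, insert_sd = 30,
                                read_length_sd = NULL,
                                quality_model = NULL,
                                convention = "odds",
                                seed = NULL,
                                out_prefix = NULL) {
  platform <- match.arg(platform)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be a named character vector")
  }
  if (any(grepl("[^ACGT]", genomes))) {
    stop("reference genomes must contain only A/C/G/T")
  }
  assert_count(n, "n")
  if (is.null(paired)) paired <- platform == "illumina"
  if (paired && platform != "illumina") {
    stop("paired-end simulation is only supported for illumina")
  }
  if (is.null(profile)) {
    profile <- build_rank_abundance(length(genomes), "uniform",
                                    genome_ids = names(genomes))
  }
  if (!all(profile$genome_id %in% names(genomes))) {
    stop("profile references genomes not supplied")
  }
  if (is.null(quality_model)) {
    quality_model <- default_quality_model(platform, read_length)
  }
  glen <- nchar(genomes)
  counts <- allocate_reads(profile, glen, n)

  result <- with_seed(seed, {
    all_reads <- vector("list", length(counts))
    all_truth <- vector("list", length(counts))
    serial0 <- 0L
    for (gi in seq_along(counts)) {
      gid <- names(counts)[gi]
      ni <- counts[[gi]]
      if (ni == 0L) next
      gseq <- genomes[[gid]]
      if (paired) {
        ins <- sample_insert(stats::setNames(gseq, gid), insert_size,
                             insert_sd, min_size = read_length, n = ni)
        pr <- extract_pairs_batch(gseq, ins$start, ins$end, ins$strand,
                                  read_length)
        raw <- c(pr$r1, pr$r2)
        qm <- sample_quality_matrix(quality_model, 2L * ni, read_length)
        quals <- lapply(seq_len(nrow(qm)), function(r) qm[r, ])
        inj <- inject_errors_batch(raw, quals, platform, convention)
        mate <- rep(1:2, each = ni)
        idx <- rep(seq_len(ni), 2L)
        ids <- sprintf("r%07d_%s:%d-%d:%s/%d", serial0 + idx, gid,
                       ins$start[idx], ins$end[idx], ins$strand[idx], mate)
        all_reads[[gi]] <- new_read_set(
          ids, inj$sequence,
          vapply(inj$quality, phred_encode, character(1)))
        all_truth[[gi]] <- truth_frame(ids, gid, ins$start[idx],
                                       ins$end[idx], ins$strand[idx], mate,
                                       inj$truth)
        serial0 <- serial0 + ni
      } else {
        rl <- simulate_platform_read_length(platform, ni, read_length,
                                            sd = read_length_sd)
        rl <- pmin(rl, nchar(gseq))
        start <- as.integer(floor(runif(ni) * (nchar(gseq) - rl + 1)))
        end <- start + rl
        strand <- ifelse(runif(ni) < 0.5, "+", "-")
        raw <- substring(gseq, start + 1L, end)
        neg <- strand == "-"
        if (any(neg)) raw[neg] <- revcomp(raw[neg])
        quals <- lapply(rl, function(L) {
          drop(sample_quality_matrix(quality_model, 1L, L))
        })
        inj <- inject_errors_batch(raw, quals, platform, convention)
        ids <- sprintf("r%07d_%s:%d-%d:%s", serial0 + seq_len(ni), gid,
                       start, end, strand)
        all_reads[[gi]] <- new_read_set(
          ids, inj$sequence,
          vapply(inj$quality, phred_encode, character(1)))
        all_truth[[gi]] <- truth_frame(ids, gid, start, end, strand,
                                       rep(0L, ni), inj$truth)
        serial0 <- serial0 + ni
      }
    }
    list(reads = do.call(rbind, all_reads), truth = do.call(rbind, all_truth))
  })

  reads <- result$reads
  truth <- result$truth
  rownames(reads) <- rownames(truth) <- NULL
  bases <- nchar(reads$sequence)
  per_genome <- data.frame(
    genome_id = names(counts),
    n_allocated = as.integer(counts),
    n_reads = as.integer(table(factor(truth$genome_id,
                                      levels = names(counts)))),
    bases = as.numeric(tapply(bases, factor(truth$genome_id,
                                            levels = names(counts)), sum,
                              default = 0)),
    genome_length = as.numeric(glen[names(counts)]),
    stringsAsFactors = FALSE)
  per_genome$expected_coverage <- per_genome$bases / per_genome$genome_length
  summary <- list(platform = platform, paired = paired, seed = seed,
                  n_reads = nrow(reads), total_bases = sum(bases),
                  mean_read_length = mean(bases), per_genome = per_genome)

  files <- NULL
  if (!is.null(out_prefix)) {
    files <- character(0)
    if (platform == "illumina") {
      fq <- paste0(out_prefix, ".fastq")
      ord <- if (paired) order(sub("/[12]$", "", reads$read_id),
                               reads$read_id) else seq_len(nrow(reads))
      write_fastq(reads[ord, ], fq)
      files <- c(files, reads = fq)
    } else {
      fa <- paste0(out_prefix, ".fasta"); qu <- paste0(out_prefix, ".qual")
      write_fasta_qual(reads, fa, qu)
      files <- c(files, fasta = fa, qual = qu)
    }
    tt <- paste0(out_prefix, ".truth.tsv")
    write_truth_table(truth, tt)
    st <- paste0(out_prefix, ".summary.tsv")
    write.table(per_genome, st, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, truth = tt, summary = st)
  }
  out <- list(reads = reads, truth = truth, summary = summary, files = files)
  if (is.null(out_prefix)) out else invisible(out)
}

truth_frame <- function(ids, gid, start, end, strand, mate, truth_list) {
  data.frame(
    read_id = ids, genome_id = gid,
    start = as.integer(start), end = as.integer(end), strand = strand,
    mate = as.integer(mate),
    n_sub = vapply(truth_list, function(t) t$n_sub, integer(1)),
    n_ins = vapply(truth_list, function(t) t$n_ins, integer(1)),
    n_del = vapply(truth_list, function(t) t$n_del, integer(1)),
    error_positions = vapply(truth_list, function(t) {
      paste(t$error_positions, collapse = ",")
    }, character(1)),
    error_types = vapply(truth_list, function(t) {
      paste(t$error_types, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Read / write simulated reads and truth tables
#'
#' FASTQ uses the Sanger Phred+33 encoding. The Sanger/pyro convention is
#' a FASTA file plus a matching `.qual` file of whitespace-separated
#' integer quality values. The truth table is TSV with columns `read_id`,
#' `genome_id`, `start`, `end`, `strand`, `mate`, `n_sub`, `n_ins`,
#' `n_del`, `error_positions`, `error_types`.
#'
#' @param reads A read-set data.frame (`read_id`, `sequence`, `quality`).
#' @param path,fasta_path,qual_path File paths.
#' @return Writers return the path(s) invisibly; readers return a
#'   read-set / truth data.frame.
#' @export
write_fastq <- function(reads, path) {
  validate_read_set(reads)
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), 4)] <- reads$sequence
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns on FASTQ input
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  new_read_set(names(x), as.character(x),
               as.character(methods::as(Biostrings::quality(x), "BStringSet")))
}

#' @rdname write_fastq
#' @export
write_fasta_qual <- function(reads, fasta_path, qual_path) {
  validate_read_set(reads)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    stats::setNames(reads$sequence, reads$read_id)), fasta_path, width = 80L)
  con <- file(qual_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(paste0(">", reads$read_id[i]), con)
    q <- phred_decode(reads$quality[i])
    # wrap at 20 values per line
    idx <- split(q, ceiling(seq_along(q) / 20))
    writeLines(vapply(idx, paste, character(1), collapse = " "), con)
  }
  invisible(c(fasta_path, qual_path))
}

#' @rdname write_fastq
#' @param truth A truth-table data.frame.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_truth_table <- function(path) {
  read.delim(path, colClasses = c(
    read_id = "character", genome_id = "character", strand = "character",
    error_positions = "character", error_types = "character"))
}
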