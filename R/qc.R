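#' 5' base-composition trim offset
#'
#' Early sequencing cycles often show distorted base composition
#' (priming/calibration artefacts). For each base b in A/C/G/T this
#' computes the per-cycle frequency f_b(c) across all reads, then the
#' mean and sd of f_b over cycles; a cycle is *aberrant* if any base's
#' frequency deviates from its mean by more than `n_sd` standard
#' deviations. The trim offset is the smallest t such that every cycle
#' beyond t (within the search window) is unremarkable — i.e. the last
#' aberrant cycle within the first `window` cycles. The same t leading
#' bases are then removed from every read.
#'
#' The statistic is population-level, so one global offset is returned
#' for the whole read set. Aberrant cycles beyond the window are not
#' trimmed (a prefix operation must stay a prefix) but are reported in
#' attribute `interior_outliers`. When no cycle has a real composition
#' artefact the cross-cycle sd reduces to sampling noise and the 2-sd
#' band would flag clean cycles at random, so a cycle must additionally
#' deviate by at least `min_dev` in absolute frequency — far below any
#' genuine artefact, far above counting noise at realistic read counts.
#'
#' @param reads Read-set data.frame or character vector of sequences,
#'   all aligned at cycle 1. Cycles beyond the shortest read are ignored.
#' @param n_sd Deviation threshold in standard deviations (default 2).
#' @param window Only the first `window` cycles are eligible for
#'   trimming (default 10).
#' @param min_dev Minimum absolute frequency deviation for a cycle to
#'   count as aberrant (default 0.02).
#' @return Integer trim offset (number of leading cycles to remove; 0 if
#'   none), with attribute `interior_outliers`.
#' @export
five_prime_composition_trim <- function(reads, n_sd = 2, window = 10L,
                                        min_dev = 0.02) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0L) stop("empty read set")
  w <- min(nchar(seqs))
  if (w == 0L) stop("reads of length zero")
  seqs_w <- substr(seqs, 1L, w)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs_w),
                                    as.prob = TRUE)
  f <- cm[DNA_BASES, , drop = FALSE]           # 4 x cycles frequencies
  mu <- rowMeans(f)
  sdev <- apply(f, 1, stats::sd)
  dev <- abs(f - mu)
  aberrant <- which(apply(dev > pmax(n_sd * sdev, min_dev) + 1e-12, 2, any))
  in_window <- aberrant[aberrant <= window]
  t <- if (length(in_window)) max(in_window) else 0L
  structure(as.integer(t),
            interior_outliers = as.integer(aberrant[aberrant > window]))
}

#' 3' quality trim
#'
#' Repeatedly removes the last base while its quality is below `q_min`;
#' stops at the first terminal base with quality >= `q_min`. Applied to a
#' whole read set at once. May produce empty reads (removed later by
#' [filter_read()]).
#'
#' @param reads Read-set data.frame.
#' @param q_min Quality threshold (default 20).
#' @return The read set with sequences and qualities truncated.
#' @export
three_prime_quality_trim <- function(reads, q_min = 20L) {
  validate_read_set(reads)
  keep_len <- vapply(reads$quality, function(s) {
    q <- phred_decode(s)
    ok <- which(q >= q_min)
    if (length(ok)) ok[length(ok)] else 0L
  }, integer(1), USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, 1L, keep_len)
  reads$quality <- substr(reads$quality, 1L, keep_len)
  reads
}

#' Read-level filter
#'
#' A trimmed read is discarded if it is shorter than `min_len` bases or
#' its median quality is below `min_median_q`. The median of an even
#' number of quality values is the mean of the two central values.
#'
#' @param reads Read-set data.frame (already trimmed).
#' @param min_len Minimum length in bp (default 35).
#' @param min_median_q Minimum median quality (default 20).
#' @return data.frame with columns `keep` (logical) and `reason`
#'   (`"kept"`, `"too_short"` or `"low_median_q"`; length is checked
#'   first).
#' @export
filter_read <- function(reads, min_len = 35L, min_median_q = 20L) {
  validate_read_set(reads)
  len <- nchar(reads$sequence)
  medq <- vapply(reads$quality, function(s) {
    q <- phred_decode(s)
    if (length(q) == 0L) return(NA_real_)
    median(q)
  }, numeric(1), USE.NAMES = FALSE)
  too_short <- len < min_len
  low_med <- !too_short & !is.na(medq) & medq < min_median_q
  reason <- rep("kept", nrow(reads))
  reason[low_med] <- "low_median_q"
  reason[too_short] <- "too_short"
  data.frame(keep = !(too_short | low_med), reason = reason,
             stringsAsFactors = FALSE)
}

#' Illumina read quality-control pipeline
#'
#' Applies, in order: (1) a global 5' composition trim
#' ([five_prime_composition_trim()]); (2) per-read 3' quality trimming
#' ([three_prime_quality_trim()]); (3) read filtering on minimum length
#' and median quality ([filter_read()]). Returns the retained reads and
#' a before/after accounting report.
#'
#' @param reads Read-set data.frame.
#' @param min_len,min_median_q Filter thresholds (defaults 35 bp, Q20).
#' @param q_trim 3' trimming threshold (default Q20).
#' @param n_sd,window,min_dev 5' composition-trim parameters.
#' @return List of class `qc_result` with `reads` (retained read set)
#'   and `report` (a `qc_report`: reads/bases in and out, the 5' offset,
#'   per-read trim lengths, and a histogram of removal reasons).
#' @export
qc_pipeline <- function(reads, min_len = 35L, min_median_q = 20L,
                        q_trim = 20L, n_sd = 2, window = 10L,
                        min_dev = 0.02) {
  validate_read_set(reads)
  if (nrow(reads) == 0L) stop("empty read set")
  reads_in <- nrow(reads)
  bases_in <- sum(nchar(reads$sequence))

  t5 <- five_prime_composition_trim(reads, n_sd = n_sd, window = window,
                                    min_dev = min_dev)
  trimmed <- reads
  if (t5 > 0L) {
    trimmed$sequence <- substr(trimmed$sequence, t5 + 1L,
                               nchar(trimmed$sequence))
    trimmed$quality <- substr(trimmed$quality, t5 + 1L,
                              nchar(trimmed$quality))
  }
  trimmed <- three_prime_quality_trim(trimmed, q_min = q_trim)
  verdict <- filter_read(trimmed, min_len = min_len,
                         min_median_q = min_median_q)
  kept <- trimmed[verdict$keep, , drop = FALSE]
  rownames(kept) <- NULL

  trim_len <- nchar(reads$sequence) - nchar(trimmed$sequence)
  reasons <- table(factor(verdict$reason[!verdict$keep],
                          levels = c("too_short", "low_median_q")))
  report <- structure(list(
    reads_in = reads_in, reads_out = nrow(kept),
    bases_in = bases_in, bases_out = sum(nchar(kept$sequence)),
    five_prime_trim = as.integer(t5),
    trim_lengths = trim_len,
    removal_reasons = reasons), class = "qc_report")
  structure(list(reads = kept, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  reads: %d -> %d (%.2f%% kept)\n", x$reads_in, x$reads_out,
              100 * x$reads_out / x$reads_in))
  cat(sprintf("  bases: %.0f -> %.0f (%.2f%% kept)\n", x$bases_in,
              x$bases_out, 100 * x$bases_out / x$bases_in))
  cat(sprintf("  5' composition trim: %d cycle(s)\n", x$five_prime_trim))
  cat(sprintf("  removed: %d too short, %d low median quality\n",
              x$removal_reasons[["too_short"]],
              x$removal_reasons[["low_median_q"]]))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  d <- data.frame(
    metric = c("reads_in", "reads_out", "bases_in", "bases_out",
               "five_prime_trim", "removed_too_short",
               "removed_low_median_q"),
    value = c(report$reads_in, report$reads_out, report$bases_in,
              report$bases_out, report$five_prime_trim,
              report$removal_reasons[["too_short"]],
              report$removal_reasons[["low_median_q"]]))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
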