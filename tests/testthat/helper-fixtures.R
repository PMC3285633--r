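# Shared fixture builders for the suite.

# A read set with explicit sequences and integer quality vectors.
make_reads <- function(seqs, quals) {
  stopifnot(length(seqs) == length(quals))
  data.frame(read_id = paste0("r", seq_along(seqs)),
             sequence = seqs,
             quality = vapply(quals, phred_encode, character(1)),
             stringsAsFactors = FALSE)
}

# n reads of length L with uniform base composition at every cycle and
# constant quality q. Composition is balanced exactly (each cycle is a
# random permutation of an equal split over A/C/G/T), so per-cycle base
# frequencies sit within any sensible deviation band by construction.
uniform_reads <- function(n, L, q = 30) {
  bases <- rep_len(c("A", "C", "G", "T"), n)
  cols <- replicate(L, sample(bases), simplify = FALSE)
  seqs <- do.call(paste0, cols)
  make_reads(seqs, replicate(n, rep(q, L), simplify = FALSE))
}

# Write a QUAL file with the given integer records.
write_qual_fixture <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">rec", i), con)
    writeLines(paste(records[[i]], collapse = " "), con)
  }
  path
}

# Independent brute-force N50: the largest length L in the set such that
# fragments of length >= L hold at least half of all bases.
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# A steeply decaying Illumina quality model (tail below Q20), as seen in
# real runs where 3' quality collapses.
steep_decay_model <- function(L = 75) {
  quality_profile("illumina", L,
                  cycles = data.frame(cycle = seq_len(L),
                                      mean = 34 + (8 - 34) * (seq_len(L) - 1) /
                                        (L - 1),
                                      sd = 3),
                  label = "steep decay")
}
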