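#' Sample a sequencing insert from a genome
#'
#' Insert size is drawn from `Normal(size_mean, size_sd)`, rounded and
#' clamped to `[min_size, genome length]`; the start position is uniform
#' over all valid placements and the strand is a fair coin. Coordinates
#' are 0-based half-open.
#'
#' @param genome A single genome sequence (character, optionally named).
#' @param size_mean,size_sd Insert size mean and sd (bp).
#' @param min_size Smallest permissible insert (bp); usually the read
#'   length. Default 1.
#' @param n Number of inserts to draw (default 1).
#' @return data.frame with columns `genome_id`, `start`, `end`, `strand`,
#'   `size`.
#' @export
sample_insert <- function(genome, size_mean, size_sd = 0, min_size = 1L,
                          n = 1L) {
  gid <- names(genome) %||% "genome"
  genome <- unname(genome)
  L <- nchar(genome)
  if (size_mean > L) stop("insert size mean exceeds genome length")
  if (min_size > L) stop("genome shorter than the minimum insert size")
  size <- round(rnorm(n, size_mean, size_sd))
  size <- pmin(pmax(size, min_size), L)
  start <- floor(runif(n) * (L - size + 1))   # 0-based
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  data.frame(genome_id = gid, start = as.integer(start),
             end = as.integer(start + size), strand = strand,
             size = as.integer(size), stringsAsFactors = FALSE)
}

#' Extract a paired read from an insert
#'
#' The insert is read from both ends, innie orientation: read /1 is the
#' first `read_length` bases of the insert on its strand; read /2 is the
#' reverse complement of the insert's last `read_length` bases (i.e. the
#' opposite strand read toward the centre).
#'
#' @param insert A one-row data.frame as produced by [sample_insert()]
#'   (or a list with `start`, `end`, `strand`).
#' @param genome The genome sequence the insert came from (character).
#' @param read_length Read length in bp; must not exceed the insert size.
#' @return Character vector `c(r1, r2)` of raw (error-free) read
#'   sequences as sequenced.
#' @export
extract_paired_reads <- function(insert, genome, read_length) {
  size <- insert$end - insert$start
  if (read_length > size) stop("read_length exceeds insert size")
  res <- extract_pairs_batch(unname(genome), insert$start, insert$end,
                             insert$strand, read_length)
  c(res$r1, res$r2)
}

# Vectorized pair extraction; start/end 0-based half-open.
extract_pairs_batch <- function(genome, start, end, strand, read_length) {
  fwd <- substring(genome, start + 1L, end)
  as_seq <- fwd
  neg <- strand == "-"
  if (any(neg)) as_seq[neg] <- revcomp(fwd[neg])
  size <- end - start
  r1 <- substr(as_seq, 1L, read_length)
  r2 <- revcomp(substring(as_seq, size - read_length + 1L, size))
  list(r1 = r1, r2 = r2)
}

#' Draw platform read lengths
#'
#' Illumina reads have a fixed configured length; Sanger and
#' pyrosequencing lengths are Normal draws (defaults: mean 800 sd 100,
#' and mean 255 sd 25) rounded and truncated below at a platform floor
#' (100 bp and 50 bp respectively).
#'
#' @param platform `"illumina"`, `"sanger"` or `"pyro"`.
#' @param n Number of draws.
#' @param read_length Fixed Illumina read length (default 75).
#' @param mean,sd Override the platform length distribution.
#' @return Integer vector of read lengths (bp).
#' @export
simulate_platform_read_length <- function(platform = c("illumina", "sanger",
                                                       "pyro"),
                                          n = 1L, read_length = 75L,
                                          mean = NULL, sd = NULL) {
  platform <- match.arg(platform)
  switch(platform,
    illumina = rep(as.integer(read_length), n),
    sanger = {
      m <- mean %||% 800; s <- sd %||% 100
      as.integer(pmax(round(rnorm(n, m, s)), 100L))
    },
    pyro = {
      m <- mean %||% 255; s <- sd %||% 25
      as.integer(pmax(round(rnorm(n, m, s)), 50L))
    })
}

#' Inject sequencing errors into a read
#'
#' Each base is substituted independently with probability
#' `phred_to_error_prob(Q)` of its quality value; the substitute base is
#' uniform over the three alternatives. For `platform = "pyro"`,
#' homopolymer-length errors are added: every homopolymer run (>= 2
#' identical bases) suffers, with probability equal to the error
#' probability of the run's first base, a length change of +1
#' (duplicated base, which also duplicates that base's quality value) or
#' -1 (deleted base), fair coin. All changes are logged.
#'
#' @param sequence Raw read sequence (character scalar, ACGT).
#' @param quality Integer vector of per-base quality values (or a
#'   Phred+33 string).
#' @param platform Sequencing platform (controls the indel model).
#' @param convention Phred convention for [phred_to_error_prob()].
#' @return List with `sequence`, `quality` (integer vector, possibly
#'   resized by indels) and `truth`: list of 0-based `error_positions`
#'   (in the output read), matching `error_types` (`sub`/`ins`/`del`;
#'   deletions are logged at the position following the removed base),
#'   and counts `n_sub`, `n_ins`, `n_del`.
#' @export
inject_errors <- function(sequence, quality, platform = "illumina",
                          convention = "odds") {
  if (is.character(quality)) quality <- phred_decode(quality)
  if (nchar(sequence) != length(quality)) {
    stop("sequence and quality lengths differ")
  }
  res <- inject_errors_batch(sequence, list(as.integer(quality)), platform,
                             convention)
  list(sequence = res$sequence[[1]], quality = res$quality[[1]],
       truth = res$truth[[1]])
}

# Batch error injection. seqs: character vector; quals: list of integer
# vectors (same lengths as seqs). Returns list(sequence=chr vector,
# quality=list of int vectors, truth=list of per-read truth lists).
inject_errors_batch <- function(seqs, quals, platform = "illumina",
                                convention = "odds") {
  n <- length(seqs)
  lens <- nchar(seqs)
  stopifnot(length(quals) == n, all(lengths(quals) == lens))
  flat_q <- unlist(quals, use.names = FALSE)
  if (length(flat_q)) {
    p <- phred_to_error_prob(flat_q, convention)
    hit <- which(runif(length(p)) < p)
  } else hit <- integer(0)
  read_of <- rep.int(seq_len(n), lens)
  offset0 <- cumsum(c(0L, lens[-n]))
  sub_read <- read_of[hit]
  sub_pos <- hit - offset0[sub_read]        # 1-based position within read
  # uniform over the 3 alternative bases via a cyclic shift of 1..3
  shift <- sample.int(3L, length(hit), replace = TRUE)

  out_seq <- seqs
  out_qual <- quals
  truth <- vector("list", n)
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

  sub_by_read <- split(seq_along(hit), factor(sub_read, levels = seq_len(n)))
  for (i in seq_len(n)) {
    idx <- sub_by_read[[i]]
    ch <- NULL
    sub_positions <- integer(0)
    if (length(idx)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sub_pos[idx]
      old <- base_code[ch[pos]]
      new <- ((old - 1L + shift[idx]) %% 4L) + 1L
      ch[pos] <- DNA_BASES[new]
      sub_positions <- sort(pos)
    }
    ins_positions <- integer(0); del_positions <- integer(0)
    if (platform == "pyro" && lens[i] > 1L) {
      if (is.null(ch)) ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      qv <- out_qual[[i]]
      r <- rle(ch)
      run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
      hp <- which(r$lengths >= 2L)
      if (length(hp)) {
        p_run <- phred_to_error_prob(qv[run_start[hp]], convention)
        do_err <- which(runif(length(hp)) < p_run)
        if (length(do_err)) {
          edit_s <- run_start[hp[do_err]]              # distinct, increasing
          edit_ins <- runif(length(do_err)) < 0.5
          # apply right-to-left so original-coordinate indices stay valid
          for (j in rev(seq_along(edit_s))) {
            s <- edit_s[j]
            if (edit_ins[j]) {
              ch <- append(ch, ch[s], after = s)
              qv <- append(qv, qv[s], after = s)
            } else {
              ch <- ch[-s]
              qv <- qv[-s]
            }
          }
          out_qual[[i]] <- qv
          # final-coordinate positions: each earlier edit shifts later
          # positions by +1 (ins) or -1 (del)
          shift_of <- function(p, strict) {
            vapply(p, function(x) {
              before <- if (strict) edit_s < x else edit_s <= x
              sum(ifelse(edit_ins, 1L, -1L)[before])
            }, integer(1))
          }
          # substitutions on a deleted base vanish from the read
          del_s <- edit_s[!edit_ins]
          sub_positions <- sub_positions[!(sub_positions %in% del_s)]
          sub_positions <- sub_positions + shift_of(sub_positions, TRUE)
          ins_positions <- edit_s[edit_ins] + 1L +
            shift_of(edit_s[edit_ins], TRUE)
          del_positions <- del_s + shift_of(del_s, TRUE)
        }
      }
    }
    if (!is.null(ch)) out_seq[i] <- paste(ch, collapse = "")
    pos0 <- c(sub_positions - 1L, ins_positions - 1L, del_positions - 1L)
    typ <- c(rep("sub", length(sub_positions)),
             rep("ins", length(ins_positions)),
             rep("del", length(del_positions)))
    o <- order(pos0, typ)
    truth[[i]] <- list(error_positions = pos0[o], error_types = typ[o],
                       n_sub = length(sub_positions),
                       n_ins = length(ins_positions),
                       n_del = length(del_positions))
  }
  list(sequence = out_seq, quality = out_qual, truth = truth)
}
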