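#' Build a rank-abundance community profile
#'
#' Constructs a normalized, rank-ordered vector of relative organism
#' abundances for a simulated community. Three standard ecological shapes
#' are available, plus direct user-supplied abundances:
#'
#' * `uniform`: every genome equally abundant.
#' * `geometric`: abundance of rank r proportional to `ratio^(r-1)`,
#'   `ratio` in (0, 1].
#' * `lognormal`: deterministic lognormal quantile profile — abundance of
#'   rank r proportional to `qlnorm((n - r + 0.5) / n, 0, sigma)`, so the
#'   same `n` and `sigma` always yield the same curve.
#' * `custom`: abundances taken from `params$abundances` (any positive
#'   vector; it is normalized and sorted).
#'
#' @param n_genomes Number of community members (>= 1).
#' @param model One of `"uniform"`, `"geometric"`, `"lognormal"`, `"custom"`.
#' @param params List of model parameters: `ratio` for geometric (default
#'   0.5), `sigma` for lognormal (default 1), `abundances` for custom.
#' @param genome_ids Optional character vector of genome identifiers
#'   (default `"g1" ... "gN"`, assigned in rank order).
#' @return A `community_profile`: data.frame with columns `genome_id` and
#'   `abundance`, sorted by decreasing abundance, abundances summing to 1.
#' @examples
#' build_rank_abundance(3, "geometric", list(ratio = 0.5))
#' @export
build_rank_abundance <- function(n_genomes,
                                 model = c("uniform", "geometric",
                                           "lognormal", "custom"),
                                 params = list(),
                                 genome_ids = NULL) {
  assert_count(n_genomes, "n_genomes")
  model <- match.arg(model)
  n <- as.integer(n_genomes)
  a <- switch(model,
    uniform = rep(1, n),
    geometric = {
      ratio <- params$ratio %||% 0.5
      if (!is.numeric(ratio) || ratio <= 0 || ratio > 1) {
        stop("geometric ratio must lie in (0, 1]")
      }
      ratio^(seq_len(n) - 1)
    },
    lognormal = {
      sigma <- params$sigma %||% 1
      if (!is.numeric(sigma) || sigma <= 0) {
        stop("lognormal sigma must be > 0")
      }
      stats::qlnorm((n - seq_len(n) + 0.5) / n, meanlog = 0, sdlog = sigma)
    },
    custom = {
      a <- params$abundances
      if (is.null(a) || !is.numeric(a) || length(a) != n || any(a <= 0)) {
        stop("custom model needs params$abundances: ", n,
             " strictly positive values")
      }
      sort(a, decreasing = TRUE)
    })
  a <- a / sum(a)
  if (is.null(genome_ids)) genome_ids <- paste0("g", seq_len(n))
  if (length(genome_ids) != n) stop("genome_ids must have length n_genomes")
  structure(
    data.frame(genome_id = as.character(genome_ids), abundance = a,
               stringsAsFactors = FALSE),
    class = c("community_profile", "data.frame")
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Allocate sequencing effort across genomes
#'
#' Splits a total number of reads (or inserts) among the genomes of a
#' community. Each genome's expected share is proportional to
#' `abundance x genome_length` (organism abundance weighted by genome
#' size, so sequencing share reflects the DNA each organism contributes
#' to the pool). Fractional shares are rounded with the largest-remainder
#' method, so the counts always sum to the requested total and each count
#' differs from its exact real-valued share by less than 1.
#'
#' @param profile A `community_profile` (see [build_rank_abundance()]).
#' @param genome_lengths Named numeric vector of genome lengths (bp);
#'   names must cover every `genome_id` in the profile.
#' @param total Total number of reads/inserts to allocate (>= 1).
#' @return A named integer vector of per-genome counts (in profile order)
#'   with attribute `total`.
#' @export
allocate_reads <- function(profile, genome_lengths, total) {
  stopifnot(is.data.frame(profile),
            all(c("genome_id", "abundance") %in% names(profile)))
  assert_count(total, "total")
  ids <- profile$genome_id
  if (!all(ids %in% names(genome_lengths))) {
    stop("genome_lengths missing entries for: ",
         paste(setdiff(ids, names(genome_lengths)), collapse = ", "))
  }
  w <- profile$abundance * as.numeric(genome_lengths[ids])
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
    stop("total allocation weight (abundance x length) must be positive")
  }
  share <- total * w / sum(w)
  counts <- floor(share)
  rem <- as.integer(round(total - sum(counts)))
  if (rem > 0) {
    extra <- order(share - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts <- as.integer(counts)
  names(counts) <- ids
  attr(counts, "total") <- as.integer(total)
  counts
}

#' Generate a synthetic genome sequence
#'
#' Draws an i.i.d. random DNA sequence with a target GC content —
#' a stand-in for a real reference genome when exercising the simulator
#' and assessment tools. G and C each get probability `gc_content / 2`,
#' A and T each `(1 - gc_content) / 2`. Deterministic given `seed`.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc_content Fraction of G+C bases, in [0, 1]. Default 0.5.
#' @param seed Integer seed (the caller's RNG stream is not disturbed);
#'   `NULL` uses the current RNG stream.
#' @param id Genome identifier (default `"synth"`).
#' @return A named character vector of length 1 (name = `id`).
#' @export
generate_synthetic_genome <- function(length, gc_content = 0.5, seed = NULL,
                                      id = "synth") {
  assert_count(length, "length")
  assert_fraction(gc_content, "gc_content")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  seq <- with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  names(seq) <- id
  seq
}

#' Generate a set of synthetic genomes
#'
#' Convenience wrapper over [generate_synthetic_genome()]: genome i uses
#' seed `seed + i` so the set is reproducible as a whole.
#'
#' @param n Number of genomes.
#' @param length Length of each genome (recycled).
#' @param gc_content GC content of each genome (recycled).
#' @param seed Base integer seed; `NULL` uses the current RNG stream.
#' @return Named character vector of genome sequences (`g1` ... `gN`).
#' @export
generate_synthetic_genomes <- function(n, length = 1e5, gc_content = 0.5,
                                       seed = NULL) {
  assert_count(n, "n")
  length <- rep_len(length, n)
  gc_content <- rep_len(gc_content, n)
  out <- vapply(seq_len(n), function(i) {
    generate_synthetic_genome(length[i], gc_content[i],
                              seed = if (is.null(seed)) NULL else seed + i)
  }, character(1))
  names(out) <- paste0("g", seq_len(n))
  out
}

#' Read reference genomes from a FASTA file
#'
#' @param path FASTA file. For simulation references, sequences containing
#'   IUPAC ambiguity codes (anything outside A/C/G/T) are rejected unless
#'   `strict = FALSE`.
#' @param strict Reject non-ACGT characters (default TRUE).
#' @return Named character vector of uppercase sequences.
#' @export
read_genomes_fasta <- function(path, strict = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (strict) {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stop("sequences contain non-ACGT characters (ambiguity codes): ",
           paste(names(seqs)[bad], collapse = ", "))
    }
  }
  seqs
}

#' Write genomes to a FASTA file (80-column wrapped)
#'
#' @param genomes Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  x <- Biostrings::DNAStringSet(genomes)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read / write a community profile as two-column TSV
#'
#' The format is `genome_id <tab> abundance`, no header. On read the
#' abundances are re-normalized to sum to 1 and sorted by rank.
#'
#' @param path TSV file path.
#' @return `read_community_profile`: a `community_profile` data.frame.
#' @export
read_community_profile <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("genome_id", "abundance"),
                  colClasses = c("character", "numeric"))
  if (any(d$abundance <= 0)) stop("abundances must be strictly positive")
  d <- d[order(d$abundance, decreasing = TRUE), , drop = FALSE]
  d$abundance <- d$abundance / sum(d$abundance)
  rownames(d) <- NULL
  structure(d, class = c("community_profile", "data.frame"))
}

#' @rdname read_community_profile
#' @param profile A `community_profile`.
#' @export
write_community_profile <- function(profile, path) {
  write.table(profile[, c("genome_id", "abundance")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
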