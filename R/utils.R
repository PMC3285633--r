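#' @importFrom methods as is
#' @importFrom stats kmeans lm coef rnorm runif sd median prcomp cmdscale cor
#' @importFrom utils read.delim write.table head
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Vectorized reverse complement of plain character sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between pairs of equal-length strings, vectorized.
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  if (any(nchar(a) != nchar(b))) stop("strings must be equal length pairwise")
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

assert_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(what, " must be a single number in [0, 1]")
  }
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    stop(what, " must be a single integer >= ", min)
  }
}

# A read set is a data.frame with columns read_id, sequence, quality
# (Phred+33 encoded, same length as sequence).
new_read_set <- function(read_id, sequence, quality) {
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality))
  data.frame(read_id = as.character(read_id),
             sequence = as.character(sequence),
             quality = as.character(quality),
             stringsAsFactors = FALSE)
}

validate_read_set <- function(reads) {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "sequence", "quality") %in% names(reads))) {
    stop("reads must be a data.frame with columns read_id, sequence, quality")
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence and quality lengths disagree for some reads")
  }
  invisible(reads)
}
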