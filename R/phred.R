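#' Convert a quality score to an error probability
#'
#' Uses the odds-based (Solexa-style) relationship
#' \eqn{Q = -10 \log_{10}(P / (1 - P))}, so that
#' \eqn{P = 1 / (1 + 10^{Q/10})}. This is the convention the simulator's
#' error models are defined in; set `convention = "standard"` for the
#' classical Phred relationship \eqn{P = 10^{-Q/10}}.
#'
#' @param q Numeric vector of quality scores (>= 0).
#' @param convention Either `"odds"` (default) or `"standard"`.
#' @return Numeric vector of error probabilities. Strictly decreasing in `q`.
#' @seealso [error_prob_to_phred()]
#' @examples
#' phred_to_error_prob(0)   # 0.5
#' phred_to_error_prob(20)  # 1/101
#' @export
phred_to_error_prob <- function(q, convention = c("odds", "standard")) {
  convention <- match.arg(convention)
  if (any(!is.finite(q)) || any(q < 0)) {
    stop("quality scores must be finite and >= 0")
  }
  if (convention == "odds") {
    1 / (1 + 10^(q / 10))
  } else {
    10^(-q / 10)
  }
}

#' Convert an error probability to a quality score
#'
#' Inverse of [phred_to_error_prob()]. Under the default odds convention
#' \eqn{Q = -10 \log_{10}(P / (1 - P))}; under the standard convention
#' \eqn{Q = -10 \log_{10} P}.
#'
#' @param p Numeric vector of error probabilities, each in (0, 1)
#'   (standard convention additionally allows p = 1).
#' @inheritParams phred_to_error_prob
#' @return Numeric vector of quality scores (not rounded, not capped;
#'   capping at 93 happens at FASTQ encoding time, see [phred_encode()]).
#' @export
error_prob_to_phred <- function(p, convention = c("odds", "standard")) {
  convention <- match.arg(convention)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("error probabilities must lie strictly within (0, 1)")
  }
  if (convention == "odds") {
    -10 * log10(p / (1 - p))
  } else {
    -10 * log10(p)
  }
}

#' Maximum encodable quality value (Sanger FASTQ, Phred+33)
#' @keywords internal
PHRED_MAX <- 93L

#' Encode integer quality values as a Phred+33 string
#'
#' Values are rounded to integers and capped to [0, 93], the printable
#' range of the Sanger FASTQ encoding.
#'
#' @param q Integer/numeric vector of per-base quality values.
#' @return A single character string, one ASCII character per base.
#' @export
phred_encode <- function(q) {
  if (length(q) == 0) return("")
  q <- as.integer(round(q))
  q[q < 0L] <- 0L
  q[q > PHRED_MAX] <- PHRED_MAX
  intToUtf8(q + 33L)
}

#' Decode a Phred+33 string to integer quality values
#'
#' @param s A single character string (one ASCII char per base).
#' @return Integer vector of quality values.
#' @export
phred_decode <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) return(integer(0))
  q <- utf8ToInt(s) - 33L
  if (any(q < 0L | q > PHRED_MAX)) {
    stop("quality string contains characters outside the Phred+33 range")
  }
  q
}

#' Decode many equal-length quality strings into a matrix
#'
#' @param s Character vector of quality strings, all the same length.
#' @return Integer matrix, one row per string, one column per cycle.
#' @keywords internal
phred_decode_matrix <- function(s) {
  n <- length(s)
  if (n == 0L) return(matrix(integer(0), 0, 0))
  w <- unique(nchar(s))
  if (length(w) != 1L) stop("quality strings must all have the same length")
  if (w == 0L) return(matrix(integer(0), n, 0))
  m <- matrix(utf8ToInt(paste(s, collapse = "")) - 33L,
              nrow = n, ncol = w, byrow = TRUE)
  if (any(m < 0L | m > PHRED_MAX)) {
    stop("quality string contains characters outside the Phred+33 range")
  }
  m
}
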