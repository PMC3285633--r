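#' Normalize category counts to an abundance profile
#'
#' Functional-category counts (e.g. COG assignments of a metagenome's
#' genes) are normalized to a probability distribution.
#'
#' @param counts Named non-negative numeric vector of category counts,
#'   at least one positive.
#' @return Named numeric vector of probabilities summing to 1
#'   (class `abundance_profile`).
#' @export
normalize_abundance <- function(counts) {
  if (length(counts) == 0L || any(counts < 0) || sum(counts) <= 0) {
    stop("counts must be non-negative with a positive total")
  }
  structure(counts / sum(counts), class = "abundance_profile")
}

#' Expected functional profile of a community
#'
#' The category abundances expected from the input genomes alone:
#' each genome's category counts are weighted by its sequencing share
#' (`abundance x genome length`, the same weight used to allocate
#' reads), summed across genomes and normalized.
#'
#' @param genome_counts Named list: per genome, a named numeric vector
#'   of category counts.
#' @param profile A `community_profile`.
#' @param genome_lengths Named numeric vector of genome lengths.
#' @return An `abundance_profile` over the union of categories.
#' @export
expected_profile <- function(genome_counts, profile, genome_lengths) {
  ids <- profile$genome_id
  if (!all(ids %in% names(genome_counts))) {
    stop("missing category counts for: ",
         paste(setdiff(ids, names(genome_counts)), collapse = ", "))
  }
  if (!all(ids %in% names(genome_lengths))) {
    stop("missing genome lengths for: ",
         paste(setdiff(ids, names(genome_lengths)), collapse = ", "))
  }
  w <- profile$abundance * as.numeric(genome_lengths[ids])
  cats <- sort(unique(unlist(lapply(genome_counts[ids], names))))
  total <- stats::setNames(numeric(length(cats)), cats)
  for (i in seq_along(ids)) {
    ci <- genome_counts[[ids[i]]]
    total[names(ci)] <- total[names(ci)] + w[i] * ci
  }
  normalize_abundance(total)
}

# Align two (or more) named probability vectors on the union of their
# categories, filling absent categories with zero.
align_profiles <- function(...) {
  ps <- list(...)
  cats <- sort(unique(unlist(lapply(ps, names))))
  lapply(ps, function(p) {
    out <- stats::setNames(numeric(length(cats)), cats)
    out[names(p)] <- p
    out
  })
}

#' Jensen-Shannon divergence between two abundance profiles
#'
#' \eqn{JSD(P,Q) = KL(P||M)/2 + KL(Q||M)/2} with \eqn{M = (P+Q)/2},
#' logarithms base 2 (so the maximum is 1 bit) and the convention
#' \eqn{0 \log 0 = 0}. Profiles with different category universes are
#' aligned by zero-filling first. The associated distance is
#' \eqn{\sqrt{JSD}}, which is a metric.
#'
#' @param p,q Named probability vectors (e.g. `abundance_profile`s).
#' @return The divergence in bits, in `[0, 1]`.
#' @seealso [jsd_distance()], [jsd_distance_matrix()]
#' @export
jensen_shannon_divergence <- function(p, q) {
  al <- align_profiles(p, q)
  p <- al[[1]]; q <- al[[2]]
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  max(0, (kl(p, m) + kl(q, m)) / 2)
}

#' @rdname jensen_shannon_divergence
#' @export
jsd_distance <- function(p, q) sqrt(jensen_shannon_divergence(p, q))

#' Pairwise square-root-JSD distance matrix
#'
#' @param profiles Named list of probability vectors.
#' @return Symmetric matrix of \eqn{\sqrt{JSD}} distances, zero
#'   diagonal.
#' @export
jsd_distance_matrix <- function(profiles) {
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- jsd_distance(profiles[[i]], profiles[[j]])
    }
  }
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical multidimensional scaling: double-centre \eqn{-D^2/2},
#' eigendecompose, keep the positive-eigenvalue axes and scale
#' eigenvectors by \eqn{\sqrt{\lambda}}. Negative eigenvalues (from
#' non-Euclidean distances) are dropped, not corrected; their magnitudes
#' are reported for diagnostics.
#'
#' @param d Square symmetric non-negative distance matrix with zero
#'   diagonal.
#' @return List of class `ordination` with `coordinates` (samples x
#'   axes; zero columns when the matrix is all-zero), `explained`
#'   (per-axis fraction of the positive eigenvalue mass) and
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-9 & e$values > 1e-12
  coords <- if (any(pos)) {
    e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos))
  } else matrix(numeric(0), n, 0)
  rownames(coords) <- rownames(d)
  if (ncol(coords)) colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    explained = if (any(pos)) e$values[pos] / sum(e$values[pos]) else numeric(0),
    negative_eigenvalues = e$values[e$values < 0]), class = "ordination")
}

#' Principal component analysis of a profile matrix
#'
#' Column mean-centred PCA (covariance eigendecomposition) of a
#' samples x categories abundance matrix.
#'
#' @param x Numeric matrix, one row per sample (>= 2 rows).
#' @return `ordination` list with `coordinates` (sample scores) and
#'   `explained` (per-axis variance fractions).
#' @export
pca_profiles <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(coordinates = p$x,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 negative_eigenvalues = numeric(0)), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$explained)) {
    cat("  explained:",
        paste(sprintf("%.1f%%", 100 * head(x$explained, 5)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Pearson correlation between expected and observed profiles
#'
#' Profiles are aligned on the union of their categories (zero-filled)
#' and the standard Pearson r over paired category probabilities is
#' returned.
#'
#' @param expected,observed Named probability vectors.
#' @return Pearson r in `[-1, 1]`.
#' @export
profile_correlation <- function(expected, observed) {
  al <- align_profiles(expected, observed)
  if (length(al[[1]]) < 2) stop("need at least 2 categories")
  if (stats::sd(al[[1]]) == 0 || stats::sd(al[[2]]) == 0) {
    stop("zero variance in a profile")
  }
  cor(al[[1]], al[[2]], method = "pearson")
}

#' Read / write abundance profiles as TSV
#'
#' Format: `category_id <tab> value` (counts or probabilities), no
#' header. On read, values are normalized to probabilities.
#'
#' @param path TSV path.
#' @return `read_abundance_profile`: an `abundance_profile`.
#' @export
read_abundance_profile <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("category", "value"),
                  colClasses = c("character", "numeric"))
  normalize_abundance(stats::setNames(d$value, d$category))
}

#' @rdname read_abundance_profile
#' @param profile Named numeric vector.
#' @export
write_abundance_profile <- function(profile, path) {
  write.table(data.frame(names(profile), as.numeric(profile)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
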