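#' Quality-value profiles
#'
#' A `quality_profile` describes, for one sequencing platform, how base
#' quality varies along the read. Two flavours exist:
#'
#' * **empirical** — built from observed per-read quality values (e.g.
#'   loaded from `.qual` files of a real run); cycle c keeps the full
#'   distribution of the c-th quality value across reads.
#' * **parametric** — a per-cycle `(mean, sd)` table for fixed-length
#'   platforms, or a positional *shape* (constant / linear decay /
#'   rise-plateau-fall evaluated over relative position) for
#'   variable-length platforms.
#'
#' Quality values always live in `[0, 93]` (Sanger FASTQ range).
#'
#' @param platform `"illumina"`, `"sanger"` or `"pyro"`.
#' @param read_length Fixed read length in cycles, or `NA` for
#'   variable-length platforms.
#' @param cycles data.frame with columns `cycle`, `mean`, `sd` (fixed
#'   length models), or `NULL`.
#' @param values Integer matrix (reads x cycles) of observed quality
#'   values for empirical profiles, or `NULL`.
#' @param shape Positional shape spec for variable-length parametric
#'   models: a list with element `kind` (`"constant"`, `"linear"`,
#'   `"rise_plateau_fall"`) and its parameters; or `NULL`.
#' @param label Free-text label (e.g. run name).
#' @return An object of class `quality_profile`.
#' @export
quality_profile <- function(platform, read_length = NA, cycles = NULL,
                            values = NULL, shape = NULL, label = "") {
  platform <- match.arg(platform, c("illumina", "sanger", "pyro"))
  if (!is.null(values)) values <- as.matrix(values)
  if (!is.null(cycles)) {
    stopifnot(all(c("cycle", "mean", "sd") %in% names(cycles)))
    if (any(cycles$mean < 0 | cycles$mean > PHRED_MAX)) {
      stop("per-cycle mean quality must lie in [0, 93]")
    }
  }
  if (is.null(cycles) && is.null(shape)) {
    stop("a quality profile needs either a per-cycle table or a shape")
  }
  if (!is.na(read_length) && !is.null(cycles) &&
      nrow(cycles) != read_length) {
    stop("per-cycle table length must equal read_length")
  }
  structure(list(platform = platform,
                 read_length = if (is.na(read_length)) NA_integer_
                               else as.integer(read_length),
                 type = if (is.null(values)) "parametric" else "empirical",
                 cycles = cycles, values = values, shape = shape,
                 label = label),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  len <- if (is.na(x$read_length)) "variable" else paste0(x$read_length, " bp")
  cat(sprintf("<quality_profile> %s, %s, %s%s\n", x$platform, len, x$type,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  if (!is.null(x$cycles)) {
    cat(sprintf("  mean Q: %.1f (cycle 1) .. %.1f (cycle %d)\n",
                x$cycles$mean[1], x$cycles$mean[nrow(x$cycles)],
                nrow(x$cycles)))
  } else if (!is.null(x$shape)) {
    cat("  shape:", x$shape$kind, "\n")
  }
  invisible(x)
}

# Mean quality at (1-based) positions `pos` of a read of total length `len`
# under a positional shape spec.
shape_mean <- function(shape, pos, len) {
  switch(shape$kind,
    constant = rep(shape$q, length(pos)),
    linear = {
      # linear from q_start at cycle 1 to q_end at cycle len
      if (len == 1) rep(shape$q_start, length(pos))
      else shape$q_start + (shape$q_end - shape$q_start) * (pos - 1) / (len - 1)
    },
    rise_plateau_fall = {
      # rise over the first rise_frac of the read, plateau, then fall over
      # the final fall_frac; breakpoints in relative coordinates
      r <- (pos - 0.5) / len
      q <- rep(shape$q_plateau, length(pos))
      rise <- r < shape$rise_frac
      fall <- r > 1 - shape$fall_frac
      q[rise] <- shape$q_start +
        (shape$q_plateau - shape$q_start) * r[rise] / shape$rise_frac
      q[fall] <- shape$q_plateau +
        (shape$q_end - shape$q_plateau) *
        (r[fall] - (1 - shape$fall_frac)) / shape$fall_frac
      q
    },
    stop("unknown shape kind: ", shape$kind))
}

#' Built-in default quality models
#'
#' Parametric stand-in models used when no empirical `.qual` profiles are
#' supplied:
#'
#' * `illumina`: linear decay of the per-cycle mean from Q35 (cycle 1) to
#'   Q25 (last cycle), sd 3 — the familiar gentle 3' quality decline of a
#'   short-read run.
#' * `sanger`: rise-plateau-fall over relative read position (Q15 rising
#'   to a Q40 plateau over the first 10%, falling to Q10 over the final
#'   20%), sd 5 — the classic capillary-trace quality envelope.
#' * `pyro`: constant Q28, sd 2; homopolymer-length errors are added
#'   separately at error-injection time (see [inject_errors()]).
#'
#' @param platform `"illumina"`, `"sanger"` or `"pyro"`.
#' @param read_length Read length for fixed-length platforms (default 75).
#' @return A `quality_profile`.
#' @export
default_quality_model <- function(platform = c("illumina", "sanger", "pyro"),
                                  read_length = 75L) {
  platform <- match.arg(platform)
  switch(platform,
    illumina = {
      L <- as.integer(read_length)
      mu <- if (L == 1) 35 else 35 + (25 - 35) * (seq_len(L) - 1) / (L - 1)
      quality_profile("illumina", L,
                      cycles = data.frame(cycle = seq_len(L), mean = mu,
                                          sd = rep(3, L)),
                      label = "default illumina linear-decay Q35->Q25")
    },
    sanger = quality_profile("sanger", NA,
      shape = list(kind = "rise_plateau_fall", q_start = 15, q_plateau = 40,
                   q_end = 10, rise_frac = 0.10, fall_frac = 0.20, sd = 5),
      label = "default sanger rise-plateau-fall"),
    pyro = quality_profile("pyro", NA,
      shape = list(kind = "constant", q = 28, sd = 2),
      label = "default pyro constant Q28"))
}

#' Load empirical quality profiles from QUAL files
#'
#' QUAL format: FASTA-like `>` headers followed by whitespace-separated
#' integer quality values (Sanger-scale Phred). Each file is one
#' sequencing run and yields one empirical per-cycle profile; the
#' distribution at cycle c pools the c-th value of every record.
#'
#' @param paths Character vector of QUAL file paths.
#' @param platform Platform tag for the resulting profiles (default
#'   `"illumina"`). Fixed-length platforms (`illumina`) require all
#'   records within a file to have the same length.
#' @return List of `quality_profile` objects, one per file, in input
#'   order; labels are the file base names.
#' @export
load_qual_profiles <- function(paths, platform = "illumina") {
  lapply(paths, function(p) {
    recs <- parse_qual_file(p)
    if (length(recs) == 0L) stop("no records in QUAL file: ", p)
    lens <- lengths(recs)
    if (platform == "illumina" && length(unique(lens)) != 1L) {
      stop("inconsistent read lengths in fixed-length run: ", p,
           " (", paste(sort(unique(lens)), collapse = ", "), ")")
    }
    L <- max(lens)
    m <- matrix(NA_integer_, nrow = length(recs), ncol = L)
    for (i in seq_along(recs)) m[i, seq_len(lens[i])] <- recs[[i]]
    if (any(m < 0L | m > PHRED_MAX, na.rm = TRUE)) {
      stop("quality value outside [0, 93] in ", p)
    }
    cyc <- data.frame(
      cycle = seq_len(L),
      mean = colMeans(m, na.rm = TRUE),
      sd = apply(m, 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1) stats::sd(v) else 0
      }))
    quality_profile(platform,
                    read_length = if (platform == "illumina") L else NA,
                    cycles = cyc, values = m,
                    label = sub("\\.[^.]*$", "", basename(p)))
  })
}

parse_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a QUAL file (no '>' headers): ", path)
  if (!hdr[1]) stop("QUAL file must start with a '>' header: ", path)
  rec <- cumsum(hdr)
  body <- split(lines[!hdr], rec[!hdr])
  lapply(body, function(x) {
    v <- suppressWarnings(as.integer(scan(text = paste(x, collapse = " "),
                                          what = "", quiet = TRUE)))
    if (any(is.na(v))) stop("non-integer quality value in ", path)
    v
  })
}

#' Cluster sequencing runs by their quality profiles
#'
#' Groups runs with similar quality behaviour by k-means on the per-cycle
#' mean-quality vectors (Euclidean distance), the natural way to collapse
#' many runs of the same read length into a few representative error
#' models. All profiles must share one read length.
#'
#' @param profiles List of `quality_profile`s with per-cycle tables.
#' @param k Number of clusters, `1 <= k <= length(profiles)`.
#' @return List with `assignment` (integer cluster id per profile) and
#'   `centroids` (one consensus parametric `quality_profile` per cluster;
#'   centroid sd at each cycle is the mean of member sds).
#' @export
cluster_profiles <- function(profiles, k) {
  if (!length(profiles)) stop("no profiles supplied")
  assert_count(k, "k")
  if (k > length(profiles)) stop("k must not exceed the number of profiles")
  lens <- vapply(profiles, function(p) {
    if (is.null(p$cycles)) stop("profiles must carry per-cycle tables")
    nrow(p$cycles)
  }, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("profiles have mixed read lengths: ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  mu <- t(vapply(profiles, function(p) p$cycles$mean, numeric(lens[1])))
  sdm <- t(vapply(profiles, function(p) p$cycles$sd, numeric(lens[1])))
  if (k == length(profiles)) {
    assignment <- seq_along(profiles)
    centers <- mu
  } else if (k == 1L) {
    assignment <- rep(1L, length(profiles))
    centers <- matrix(colMeans(mu), nrow = 1)
  } else {
    km <- kmeans(mu, centers = k, nstart = 25)
    assignment <- km$cluster
    centers <- km$centers
  }
  platform <- profiles[[1]]$platform
  centroids <- lapply(seq_len(nrow(centers)), function(j) {
    members <- which(assignment == j)
    quality_profile(platform,
                    read_length = profiles[[1]]$read_length,
                    cycles = data.frame(
                      cycle = seq_len(ncol(centers)),
                      mean = as.numeric(centers[j, ]),
                      sd = colMeans(sdm[members, , drop = FALSE])),
                    label = paste0("cluster", j))
  })
  list(assignment = assignment, centroids = centroids)
}

#' Fit a parametric positional quality model to a profile
#'
#' Least-squares fit of per-cycle mean quality against cycle index.
#' Families: `constant` (grand mean), `linear_decay` (straight line,
#' parameterized as `q(c) = intercept + slope * (c - 1)` so the intercept
#' is the cycle-1 quality), `piecewise` (two straight lines joined at the
#' breakpoint minimizing the residual sum of squares, found by grid
#' search). The per-cycle empirical sd of the input profile is retained
#' for sampling.
#'
#' @param profile A `quality_profile` with a per-cycle table.
#' @param family `"constant"`, `"linear_decay"` or `"piecewise"`.
#' @return A parametric `quality_profile` whose per-cycle means are the
#'   fitted values; the fit parameters and residuals are in attribute
#'   `fit` (`$coefficients`, `$residuals`, and `$breakpoint` for
#'   piecewise).
#' @export
fit_positional_quality_model <- function(profile,
                                         family = c("constant",
                                                    "linear_decay",
                                                    "piecewise")) {
  family <- match.arg(family)
  if (is.null(profile$cycles) || nrow(profile$cycles) < 1) {
    stop("profile has no per-cycle table")
  }
  cyc <- profile$cycles
  n <- nrow(cyc)
  x <- cyc$cycle - cyc$cycle[1]
  y <- cyc$mean
  fit <- switch(family,
    constant = {
      mu <- mean(y)
      list(coefficients = c(intercept = mu), fitted = rep(mu, n))
    },
    linear_decay = {
      if (n < 2) stop("linear_decay needs at least 2 cycles")
      m <- lm(y ~ x)
      list(coefficients = c(intercept = unname(coef(m)[1]),
                            slope = unname(coef(m)[2])),
           fitted = unname(stats::fitted(m)))
    },
    piecewise = {
      if (n < 4) stop("piecewise needs at least 4 cycles")
      best <- NULL
      for (b in 2:(n - 2)) {
        i1 <- seq_len(b); i2 <- (b + 1):n
        m1 <- lm(y[i1] ~ x[i1]); m2 <- lm(y[i2] ~ x[i2])
        sse <- sum(stats::resid(m1)^2) + sum(stats::resid(m2)^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(sse = sse, breakpoint = cyc$cycle[b],
                       fitted = c(unname(stats::fitted(m1)),
                                  unname(stats::fitted(m2))),
                       coefficients = c(
                         intercept1 = unname(coef(m1)[1]),
                         slope1 = unname(coef(m1)[2]),
                         intercept2 = unname(coef(m2)[1]),
                         slope2 = unname(coef(m2)[2])))
        }
      }
      best
    })
  fitted_mu <- pmin(pmax(fit$fitted, 0), PHRED_MAX)
  out <- quality_profile(profile$platform, profile$read_length,
                         cycles = data.frame(cycle = cyc$cycle,
                                             mean = fitted_mu, sd = cyc$sd),
                         label = paste0(profile$label, " [", family, " fit]"))
  attr(out, "fit") <- c(fit[setdiff(names(fit), "fitted")],
                        list(residuals = y - fit$fitted, family = family))
  out
}

#' Sample a quality string from a profile
#'
#' Draws one quality value per base: from the empirical per-cycle
#' distribution for empirical profiles, or from
#' `Normal(mean_c, sd_c)` rounded and truncated to `[0, 93]` for
#' parametric ones. Variable-length shape models evaluate the positional
#' mean for the requested read length.
#'
#' @param model A `quality_profile`.
#' @param length Number of bases (0 allowed; must not exceed the model's
#'   read length for fixed-length profiles).
#' @return Integer vector of quality values (length `length`).
#' @export
sample_quality_string <- function(model, length) {
  assert_count(length, "length", min = 0L)
  drop(sample_quality_matrix(model, 1L, length))
}

# n quality vectors of a common length, as an n x length integer matrix.
sample_quality_matrix <- function(model, n, length) {
  if (!inherits(model, "quality_profile")) stop("model must be a quality_profile")
  length <- as.integer(length)
  if (length == 0L) return(matrix(integer(0), n, 0))
  if (!is.na(model$read_length) && length > model$read_length) {
    stop("requested length ", length, " exceeds model read length ",
         model$read_length)
  }
  if (model$type == "empirical") {
    cols <- lapply(seq_len(length), function(c) {
      v <- model$values[, c]
      v <- v[!is.na(v)]
      v[sample.int(length(v), n, replace = TRUE)]
    })
    q <- matrix(unlist(cols), nrow = n, ncol = length)
  } else {
    if (!is.null(model$cycles)) {
      mu <- model$cycles$mean[seq_len(length)]
      sdv <- model$cycles$sd[seq_len(length)]
    } else {
      mu <- shape_mean(model$shape, seq_len(length), length)
      sdv <- rep(model$shape$sd %||% 0, length)
    }
    q <- matrix(rnorm(n * length, mean = rep(mu, each = n),
                      sd = rep(sdv, each = n)), nrow = n, ncol = length)
    q <- round(q)
  }
  q[q < 0] <- 0L
  q[q > PHRED_MAX] <- PHRED_MAX
  storage.mode(q) <- "integer"
  q
}

#' Serialize / load a parametric quality model as TSV
#'
#' Parametric per-cycle models are written as `cycle <tab> mean <tab> sd`
#' with a one-line `#` header carrying platform and read length;
#' empirical models are written as their per-cycle summary (mean, sd) in
#' the same format.
#'
#' @param model A `quality_profile` with a per-cycle table.
#' @param path Output path.
#' @return `path` (write) / a parametric `quality_profile` (read).
#' @export
write_quality_model <- function(model, path) {
  if (is.null(model$cycles)) stop("only per-cycle models can be serialized")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#platform=%s\tread_length=%s\tlabel=%s",
                     model$platform,
                     ifelse(is.na(model$read_length), "variable",
                            model$read_length),
                     model$label), con)
  write.table(model$cycles[, c("cycle", "mean", "sd")], con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_quality_model
#' @export
read_quality_model <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^#platform=", hdr)) stop("missing model header line")
  fields <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  kv <- do.call(rbind, strsplit(fields, "=", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  col.names = c("cycle", "mean", "sd"))
  rl <- if (identical(meta[["read_length"]], "variable")) NA
        else as.integer(meta[["read_length"]])
  quality_profile(meta[["platform"]], rl, cycles = d,
                  label = meta[["label"]] %||% "")
}
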