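test_that("insert sampling respects size model, bounds and uniformity", {
  g <- generate_synthetic_genome(10000, seed = 31, id = "gen")

  set.seed(1)
  fixed <- sample_insert(g, 300, 0, n = 1000)
  expect_true(all(fixed$size == 300))
  expect_true(all(fixed$start >= 0 & fixed$end <= 10000))
  expect_true(all(fixed$end - fixed$start == fixed$size))
  expect_true(all(fixed$strand %in% c("+", "-")))

  set.seed(2)
  norm <- sample_insert(g, 300, 30, n = 1e5)
  expect_lt(abs(mean(norm$size) - 300), 3 * 30 / sqrt(1e5) + 0.5)

  # start positions uniform: chi-square over 20 bins at alpha = 0.001
  set.seed(3)
  u <- sample_insert(g, 100, 0, n = 1e5)
  bins <- cut(u$start, breaks = seq(0, 10000 - 100 + 1, length.out = 21),
              include.lowest = TRUE)
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)

  expect_error(sample_insert(g, 20000, 0), "exceeds genome length")
})

test_that("paired reads come from opposite insert ends, innie-oriented", {
  g <- c(gen = "ACGTACGT")
  ins <- data.frame(genome_id = "gen", start = 0L, end = 8L, strand = "+",
                    size = 8L)
  pr <- extract_paired_reads(ins, g, 4)
  expect_identical(pr, c("ACGT", "ACGT"))  # revcomp("ACGT") == "ACGT"

  # read_length == insert size: mates are exact reverse complements
  set.seed(9)
  g2 <- generate_synthetic_genome(500, seed = 12, id = "gen")
  ins2 <- sample_insert(g2, 100, 0, n = 20)
  for (i in seq_len(20)) {
    pr <- extract_paired_reads(ins2[i, ], g2, 100)
    expect_identical(pr[2],
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(pr[1]))))
  }

  # minus-strand /1 is the revcomp of the plus-strand /1 region read
  # from the other end
  ins_p <- data.frame(start = 10L, end = 60L, strand = "+")
  ins_m <- data.frame(start = 10L, end = 60L, strand = "-")
  r_p <- extract_paired_reads(ins_p, g2, 20)
  r_m <- extract_paired_reads(ins_m, g2, 20)
  expect_identical(r_m[1], r_p[2])
  expect_identical(r_m[2], r_p[1])

  expect_error(extract_paired_reads(ins_p, g2, 60), "exceeds insert size")
})

test_that("error injection matches quality-implied rates and logs every change", {
  set.seed(21)
  ref100 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  hi <- inject_errors(ref100, rep(93L, 100))
  expect_equal(hi$truth$n_sub, metagsim:::hamming(hi$sequence, ref100))

  # Q=0 means P=0.5: substitution fraction within 3 binomial SEs
  set.seed(22)
  n <- 1e5
  refs <- vapply(seq_len(n %/% 100), function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  }, character(1))
  out <- metagsim:::inject_errors_batch(
    refs, replicate(length(refs), rep(0L, 100), simplify = FALSE), "illumina")
  nsub <- sum(vapply(out$truth, function(t) t$n_sub, integer(1)))
  expect_lt(abs(nsub / n - 0.5), 3 * sqrt(0.25 / n))

  # logged positions equal the positionwise diff, for every read
  set.seed(23)
  for (i in 1:50) {
    ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    res <- inject_errors(ref, rep(3L, 60))
    diffpos <- which(charToRaw(res$sequence) != charToRaw(ref)) - 1L
    expect_identical(res$truth$error_positions, diffpos)
    expect_true(all(res$truth$error_types == "sub"))
    expect_true(all(diff(res$truth$error_positions) > 0))
  }
})

test_that("pyro homopolymer errors are logged consistently with edit distance", {
  set.seed(31)
  total_indels <- 0
  for (i in 1:200) {
    # homopolymer-rich reference
    ref <- paste(rep(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                     times = sample(1:4, 15, replace = TRUE)), collapse = "")
    res <- inject_errors(ref, rep(10L, nchar(ref)), platform = "pyro")
    n_err <- with(res$truth, n_sub + n_ins + n_del)
    total_indels <- total_indels + res$truth$n_ins + res$truth$n_del
    expect_equal(nchar(res$sequence),
                 nchar(ref) + res$truth$n_ins - res$truth$n_del)
    expect_length(res$quality, nchar(res$sequence))
    # independent oracle: Levenshtein distance never exceeds the log
    expect_lte(adist(res$sequence, ref)[1, 1], n_err)
    pos <- res$truth$error_positions
    if (length(pos)) {
      expect_true(all(pos >= 0 & pos < nchar(res$sequence)))
      expect_true(all(diff(pos) >= 0))
    }
  }
  expect_gt(total_indels, 0)  # the indel channel actually fires at Q10
})

test_that("platform read lengths match their configured distributions", {
  expect_identical(simulate_platform_read_length("illumina", 10), rep(75L, 10))
  expect_identical(simulate_platform_read_length("illumina", 2,
                                                 read_length = 44), rep(44L, 2))
  set.seed(41)
  sg <- simulate_platform_read_length("sanger", 1e4)
  expect_lt(abs(mean(sg) - 800), 3 * 100 / sqrt(1e4) + 0.5)
  expect_true(all(sg >= 100))
  py <- simulate_platform_read_length("pyro", 1e4)
  expect_lt(abs(mean(py) - 255), 3 * 25 / sqrt(1e4) + 0.5)
  expect_true(all(py >= 50))
})

test_that("simulated metagenomes have exact totals, coverage and determinism", {
  g <- generate_synthetic_genomes(10, length = 2e4, seed = 51)
  sim <- simulate_metagenome(g, 10000, platform = "illumina", seed = 8)
  expect_equal(nrow(sim$reads), 20000)
  expect_equal(sim$summary$total_bases, 20000 * 75)
  expect_equal(sum(sim$summary$per_genome$n_allocated), 10000)

  # byte-identical outputs for the same config + seed
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  s1 <- simulate_metagenome(g, 200, platform = "illumina", seed = 99,
                            out_prefix = file.path(d1, "mg"))
  s2 <- simulate_metagenome(g, 200, platform = "illumina", seed = 99,
                            out_prefix = file.path(d2, "mg"))
  for (f in c("mg.fastq", "mg.truth.tsv", "mg.summary.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # 1 genome of 100 kb, 1000 single-end 100 bp reads -> coverage 1.0x
  g1 <- generate_synthetic_genome(1e5, seed = 52, id = "solo")
  cov <- simulate_metagenome(g1, 1000, platform = "illumina", paired = FALSE,
                             read_length = 100, seed = 1)
  expect_equal(cov$summary$per_genome$expected_coverage, 1.0)
})

test_that("every read's truth record re-extracts its reference origin", {
  g <- generate_synthetic_genomes(3, length = 5000, seed = 61)
  for (platform in c("illumina", "sanger")) {
    sim <- simulate_metagenome(g, 150, platform = platform, paired = FALSE,
                               seed = 13)
    tr <- sim$truth
    ref <- substring(g[tr$genome_id], tr$start + 1L, tr$end)
    neg <- tr$strand == "-"
    ref[neg] <- metagsim:::revcomp(ref[neg])
    expect_identical(metagsim:::hamming(sim$reads$sequence, ref), tr$n_sub)
    expect_true(all(tr$n_ins == 0 & tr$n_del == 0))
  }
  # paired mode: reconstruct each mate from the insert coordinates
  sim <- simulate_metagenome(g, 100, platform = "illumina", seed = 14)
  tr <- sim$truth
  ins <- substring(g[tr$genome_id], tr$start + 1L, tr$end)
  neg <- tr$strand == "-"
  ins[neg] <- metagsim:::revcomp(ins[neg])
  exp_read <- ifelse(tr$mate == 1L, substr(ins, 1, 75),
                     metagsim:::revcomp(substring(ins, nchar(ins) - 74,
                                                  nchar(ins))))
  expect_identical(metagsim:::hamming(sim$reads$sequence, exp_read), tr$n_sub)
})

test_that("realized per-genome base counts track abundance x length shares", {
  g <- generate_synthetic_genomes(5, length = c(2e4, 4e4, 1e4, 3e4, 2e4),
                                  seed = 71)
  prof <- build_rank_abundance(5, "geometric", list(ratio = 0.6),
                               genome_ids = names(g))
  n <- 120000
  sim <- simulate_metagenome(g, n, profile = prof, platform = "illumina",
                             paired = FALSE, seed = 17)
  w <- prof$abundance * nchar(g)[prof$genome_id]
  share <- w / sum(w)
  obs <- table(factor(sim$truth$genome_id, levels = prof$genome_id)) / n
  se <- sqrt(share * (1 - share) / n)
  # largest-remainder allocation is deterministic, so this is far inside
  # 3 binomial SEs by construction
  expect_true(all(abs(as.numeric(obs) - share) <= 3 * se + 1 / n))
})

test_that("FASTQ and FASTA+QUAL round trips preserve reads", {
  g <- generate_synthetic_genomes(2, length = 3000, seed = 81)
  sim <- simulate_metagenome(g, 50, platform = "illumina", paired = FALSE,
                             seed = 21)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, sim$reads$sequence)
  expect_equal(back$quality, sim$reads$quality)

  sim2 <- simulate_metagenome(g, 20, platform = "pyro", seed = 22)
  fa <- tempfile(fileext = ".fasta"); qu <- tempfile(fileext = ".qual")
  write_fasta_qual(sim2$reads, fa, qu)
  seqs <- read_genomes_fasta(fa)
  expect_equal(unname(seqs), sim2$reads$sequence)
  quals <- load_qual_profiles(qu, platform = "pyro")[[1]]
  expect_equal(nrow(quals$values), nrow(sim2$reads))

  tt <- tempfile(fileext = ".tsv")
  write_truth_table(sim2$truth, tt)
  expect_equal(read_truth_table(tt)$read_id, sim2$truth$read_id)
})
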