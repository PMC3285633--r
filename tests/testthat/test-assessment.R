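test_that("k-mismatch mapping reports exactly the loci within budget", {
  g <- generate_synthetic_genomes(2, length = 8000, seed = 91)
  sim <- simulate_metagenome(g, 100, platform = "illumina", paired = FALSE,
                             seed = 31,
                             quality_model = quality_profile(
                               "illumina", 75,
                               cycles = data.frame(cycle = 1:75, mean = 93,
                                                   sd = 0)))
  # error-free reads map at their truth locus with 0 mismatches
  aln <- map_reads_to_genomes(sim$reads, g)
  key <- paste(aln$read_id, aln$genome_id, aln$start, aln$strand)
  tr <- sim$truth
  truth_key <- paste(tr$read_id, tr$genome_id, tr$start, tr$strand)
  expect_true(all(truth_key %in% key))
  expect_true(all(aln$mismatches[match(truth_key, key)] == 0))

  # a read with 3 substitutions is unmapped at max 2 mismatches
  ref <- substr(g[[1]], 101, 175)
  mutated <- ref
  for (p in c(10, 40, 70)) {
    old <- substr(mutated, p, p)
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  m3 <- map_reads_to_genomes(c(mut = mutated), g, max_mismatches = 2)
  expect_equal(nrow(m3), 0)
  m3b <- map_reads_to_genomes(c(mut = mutated), g, max_mismatches = 3)
  expect_gte(nrow(m3b), 1)
  expect_equal(m3b$start[1], 100)

  # a duplicated segment is reported at both loci
  dup <- paste0(substr(g[[1]], 1, 2000), substr(g[[1]], 501, 540),
                substr(g[[2]], 1, 2000))
  gd <- c(dup = dup)
  probe <- substr(g[[1]], 501, 540)
  md <- map_reads_to_genomes(c(p1 = probe), c(g[1], gd))
  md_plus <- md[md$strand == "+", ]
  expect_setequal(paste(md_plus$genome_id, md_plus$start),
                  c("g1 500", "dup 500", "dup 2000"))
})

test_that("genome coverage is the covered fraction of positions", {
  g <- generate_synthetic_genome(1000, seed = 101, id = "gen")
  tile <- data.frame(genome_id = "gen",
                     start = seq(0, 900, by = 100),
                     end = seq(100, 1000, by = 100))
  expect_equal(genome_coverage(tile, g), 1.0)

  one <- data.frame(genome_id = "gen", start = 100L, end = 175L)
  expect_equal(genome_coverage(one, g), 0.075)

  none <- one[0, ]
  expect_equal(genome_coverage(none, g), 0.0)

  # overlapping alignments are not double counted
  over <- data.frame(genome_id = "gen", start = c(0L, 50L), end = c(100L, 150L))
  expect_equal(genome_coverage(over, g), 0.15)
})

test_that("chimeric classification follows the classic and illumina rules", {
  both <- data.frame(source_genome = c("A", "A", "B"),
                     is_unique = c(TRUE, TRUE, TRUE))
  expect_true(classify_chimeric(both, "classic"))
  expect_true(classify_chimeric(both, "illumina"))

  multi <- data.frame(source_genome = c("A", "A", "B", "B"),
                      is_unique = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(classify_chimeric(multi, "classic"))
  expect_false(classify_chimeric(multi, "illumina"))

  single <- data.frame(source_genome = "A", is_unique = TRUE)
  expect_false(classify_chimeric(single, "classic"))
  expect_false(classify_chimeric(single, "illumina"))

  expect_error(classify_chimeric(single[0, ], "classic"), "no reads")

  # on unique-only inputs the two definitions coincide
  set.seed(41)
  for (i in 1:50) {
    d <- data.frame(source_genome = sample(LETTERS[1:3], sample(1:6, 1),
                                           replace = TRUE),
                    is_unique = TRUE)
    expect_identical(classify_chimeric(d, "classic"),
                     classify_chimeric(d, "illumina"))
  }
})

test_that("degree of chimericity is the non-majority read fraction", {
  expect_equal(degree_of_chimericity(c(rep("A", 7), rep("B", 3)))$degree, 0.3)
  expect_equal(degree_of_chimericity(rep("X", 5))$degree, 0)
  tie <- degree_of_chimericity(c(rep("B", 5), rep("A", 5)))
  expect_equal(tie$degree, 0.5)
  expect_equal(tie$majority_genome, "A")  # lexicographic tie-break

  # hand-count oracle on 1000 random compositions
  set.seed(42)
  for (i in 1:1000) {
    src <- sample(paste0("g", 1:4), sample(1:12, 1), replace = TRUE)
    res <- degree_of_chimericity(src)
    maxn <- max(sapply(unique(src), function(s) sum(src == s)))
    expect_equal(res$degree, (length(src) - maxn) / length(src))
    expect_true(res$degree >= 0 && res$degree <= 1 - 1 / length(src))
    expect_identical(res$degree == 0, length(unique(src)) == 1L)
  }
})

test_that("contig scores combine best-HSP identity and coverage", {
  g <- generate_synthetic_genomes(2, length = 6000, seed = 111)

  exact <- contig_score(substr(g[[1]], 1001, 2000), g)
  expect_equal(exact$score, 100)
  expect_equal(exact$genome_id, "g1")
  expect_equal(exact$percent_identity, 100)
  expect_equal(exact$percent_coverage, 100)

  # interior mismatches, full-length HSP: score = pid since coverage 100
  contig <- substr(g[[1]], 1001, 1500)
  for (p in seq(50, 450, by = 40)) {
    old <- substr(contig, p, p)
    substr(contig, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  res <- contig_score(contig, g)
  expect_equal(res$percent_coverage, 100)
  expect_equal(res$percent_identity, 100 * (500 - 11) / 500)
  expect_equal(res$score, res$percent_identity)

  # score recomputed independently from the alignment definition on
  # random partially-matching contigs
  set.seed(43)
  for (i in 1:20) {
    core <- substr(g[[2]], 2000, 2000 + sample(200:400, 1))
    junk <- generate_synthetic_genome(sample(100:300, 1), seed = 1000 + i)
    ctg <- paste0(core, junk)
    res <- contig_score(ctg, g["g2"])
    aln <- Biostrings::pairwiseAlignment(
      ctg, g[["g2"]], type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    pid <- 100 * sum(charToRaw(ap) == charToRaw(as_)) / nchar(ap)
    cov <- 100 * Biostrings::width(Biostrings::pattern(aln)) / nchar(ctg)
    expect_equal(res$score, pid * cov / 100, tolerance = 1e-9)
  }

  # nothing alignable above the reporting threshold scores 0
  poly <- strrep("AC", 50)
  tt <- c(t = strrep("T", 500))
  expect_equal(contig_score(poly, tt)$score, 0)

  expect_error(contig_score("ACGT", character(0)), "no genomes")
})

test_that("N50 follows the cumulative-from-largest convention", {
  expect_equal(n50(c(1000, 500, 500)), 1000)
  expect_equal(n50(42), 42)
  expect_equal(n50(rep(500, 4)), 500)
  expect_error(n50(numeric(0)), "empty")

  # brute-force agreement on all length multisets of size <= 8 from
  # {100, ..., 1000 step 100}
  vals <- seq(100, 1000, by = 100)
  for (k in 1:8) {
    sets <- utils::combn(length(vals) + k - 1, k)
    for (j in seq_len(ncol(sets))) {
      lens <- vals[sets[, j] - seq_len(k) + 1]  # multisets via stars-and-bars
      expect_identical(n50(lens), n50_oracle(lens))
    }
  }
})

test_that("assembly summaries restrict to contigs above the length cutoff", {
  s <- assembly_summary(c(600, 400, 501))
  expect_equal(s$n_contigs, 2L)
  expect_equal(s$sum_length, 1101)
  expect_equal(s$longest, 600)

  s2 <- assembly_summary(c(100, 500))  # 500 is not > 500
  expect_true(s2$empty)
  expect_equal(s2$n_contigs, 0L)

  s3 <- assembly_summary(c(22725, 300, 600, 700))
  expect_equal(s3$longest, 22725)
  expect_equal(s3$n50, 22725)
})

test_that("scaftig extraction splits on N runs and reconstructs scaffolds", {
  expect_equal(extract_scaftigs("ACGTNNNACGT"), c("ACGT", "ACGT"))
  expect_equal(extract_scaftigs("ACGTACGT"), "ACGTACGT")
  expect_equal(extract_scaftigs("NNNN"), character(0))
  expect_equal(extract_scaftigs("NACGTN"), "ACGT")
  expect_error(extract_scaftigs("ACGTX"), "A/C/G/T/N")

  set.seed(44)
  for (i in 1:50) {
    parts <- replicate(sample(1:5, 1), paste(
      sample(c("A", "C", "G", "T"), sample(1:20, 1), replace = TRUE),
      collapse = ""))
    gaps <- replicate(length(parts) - 1, strrep("N", sample(1:10, 1)))
    scaffold <- paste0(paste0(parts[-length(parts)], gaps, collapse = ""),
                       parts[length(parts)])
    tigs <- extract_scaftigs(scaffold)
    expect_identical(tigs, parts[nzchar(parts)])
    # removing the Ns from the scaffold reconstructs the concatenation
    expect_identical(paste(tigs, collapse = ""), gsub("N", "", scaffold))
  }
})

test_that("contig assessment joins assignments with truth end to end", {
  g <- generate_synthetic_genomes(2, length = 5000, seed = 121)
  sim <- simulate_metagenome(g, 200, platform = "illumina", paired = FALSE,
                             seed = 51)
  tr <- sim$truth
  ids_a <- tr$read_id[tr$genome_id == "g1"][1:20]
  ids_b <- tr$read_id[tr$genome_id == "g2"][1:10]

  # pure contig: all reads one genome -> degree 0, not chimeric
  pure <- data.frame(read_id = ids_a, contig_id = "c_pure")
  res <- assess_contigs(pure, tr, mode = "classic")
  expect_equal(res$degree_of_chimericity, 0)
  expect_false(res$chimeric)

  # splicing in reads from a second genome makes the degree the spliced
  # fraction exactly
  spliced <- data.frame(read_id = c(ids_a, ids_b),
                        contig_id = "c_mix")
  res2 <- assess_contigs(spliced, tr, mode = "classic")
  expect_true(res2$chimeric)
  expect_equal(res2$degree_of_chimericity, 10 / 30)
  expect_equal(res2$majority_genome, "g1")

  # multi-contig assignment: shared reads lose uniqueness, illumina mode
  # ignores them
  shared <- rbind(
    data.frame(read_id = ids_a, contig_id = "c1"),
    data.frame(read_id = ids_b, contig_id = c(rep("c1", 5), rep("c2", 5))),
    data.frame(read_id = ids_b[1:5], contig_id = "c2"))
  res3 <- assess_contigs(shared, tr, mode = "illumina")
  c1 <- res3[res3$contig_id == "c1", ]
  # c1 = 20 unique g1 reads + 5 g2 reads shared with c2: the unique
  # reads are single-source, so illumina mode does not call it chimeric
  expect_false(c1$chimeric)
  expect_true(res3[res3$contig_id == "c1", "degree_of_chimericity"] > 0)

  # TSV round trip for assignments
  path <- tempfile(fileext = ".tsv")
  write.table(spliced, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  m <- read_contig_map(path)
  expect_true(all(m$is_unique))
})
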