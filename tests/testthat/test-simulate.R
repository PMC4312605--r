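test_that("reference building is deterministic and seed-sensitive", {
  cfg <- small_config(seed = 5)
  a <- build_references(cfg)
  b <- build_references(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$references, b$references)

  c <- build_references(small_config(seed = 6))
  expect_false(identical(a$genome, c$genome))
})

test_that("the truth manifest satisfies its construction invariants", {
  refs <- small_refs()
  m <- refs$manifest
  genome <- refs$genome[["chr_sim"]]
  expect_equal(nrow(m), 16)
  # mature occurs verbatim in its precursor arm and at its genome locus
  for (i in seq_len(nrow(m))) {
    expect_true(grepl(m$mature_sequence[i], m$precursor_sequence[i],
                      fixed = TRUE))
    genomic <- substr(genome, m$mature_start[i] + 1, m$mature_end[i])
    expected <- if (m$strand[i] == "+") m$mature_sequence[i] else
      revcomp(m$mature_sequence[i])
    expect_identical(genomic, expected)
  }
  # loci are 0-based half-open within the genome
  expect_true(all(m$prec_start >= 0 & m$prec_end <= nchar(genome)))
  expect_true(all(m$mature_start >= m$prec_start &
                    m$mature_end <= m$prec_end))
  # pattern categories partition the planted miRNAs
  expect_true(all(m$pattern %in% c("up_both", "down_both", "opposite",
                                   "genotype1_only", "genotype2_only",
                                   "null")))
  # planted precursors pass the annotation criteria by construction
  passes <- purrr::map_lgl(seq_len(nrow(m)), function(i) {
    evaluate_hairpin(m$precursor_sequence[i], m$mature_offset[i],
                     nchar(m$mature_sequence[i]))$pass
  })
  expect_true(all(passes))
})

test_that("a too-short genome raises a sizing error", {
  cfg <- small_config()
  cfg$genome_length <- 500L
  expect_error(build_references(cfg), "too short")
})

test_that("simulated count means respect the planted fold changes", {
  refs <- small_refs()
  cfg <- small_config()
  m <- refs$manifest
  # Monte-Carlo over replicate draws: mean stress/control ratio within 5%
  draws <- purrr::map(1:1500, ~simulate_counts(m, cfg,
                                              stream = paste0("mc", .x)))
  t1 <- rowMeans(do.call(cbind, purrr::map(draws, "t1")))
  c1 <- rowMeans(do.call(cbind, purrr::map(draws, "c1")))
  up <- which(m$pattern == "up_both")
  expect_true(all(abs(t1[up] / c1[up] - m$fold[up]) / m$fold[up] < 0.05))
  # null-category miRNAs share means: log2 ratio of averaged counts near 0
  null <- which(m$pattern == "null")
  expect_true(all(abs(log2(t1[null] / c1[null])) < 0.15))
  # opposite category: planted log2 ratios have opposite signs
  opp <- m$pattern == "opposite"
  expect_true(all(log2(m$mean_t1 / m$mean_c1)[opp] < 0))
  expect_true(all(log2(m$mean_t2 / m$mean_c2)[opp] > 0))
})

test_that("synthesized libraries conserve read totals and ground truth", {
  cfg <- small_config()
  cfg$error_rate <- 0
  refs <- build_references(cfg)
  counts <- simulate_counts(refs$manifest, cfg)
  reads <- synthesize_reads(counts, refs, cfg)
  expect_named(reads, c("c1", "t1", "c2", "t2"))
  for (lib in names(reads)) {
    expect_equal(nrow(reads[[lib]]), cfg$n_reads_per_library)
  }
  # with error_rate = 0 every planted miRNA yields exactly its count of
  # reads whose trimmed insert equals the mature sequence
  mature_of <- setNames(refs$manifest$mature_sequence,
                        refs$manifest$mirna_id)
  ins <- trim_adapter(reads$c1$read, cfg$adapter_sequence)
  for (id in sample(names(mature_of), 5)) {
    expect_equal(sum(ins == mature_of[[id]], na.rm = TRUE),
                 counts$c1[counts$mirna_id == id])
  }
})

test_that("a degenerate length distribution yields only 24-nt inserts", {
  cfg <- small_config()
  ld <- setNames(rep(0, 15), 16:30)
  ld["24"] <- 1
  cfg$length_distribution <- ld
  refs <- small_refs()
  counts <- simulate_counts(refs$manifest, cfg)
  counts[c("c1", "t1", "c2", "t2")] <- 0L  # background only
  reads <- synthesize_reads(counts, refs, cfg)
  ins <- trim_adapter(reads$c1$read, cfg$adapter_sequence)
  expect_true(all(nchar(ins[!is.na(ins)]) == 24))
})

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(length_distribution = c(`24` = 0.5)), "sum to 1")
  expect_error(sim_config(category_fractions = c(rRNA = 1)), "named")
  ld <- setNames(rep(1 / 15, 15), 16:30)
  names(ld)[1] <- "12"
  expect_error(sim_config(length_distribution = ld), "16..30")
})

test_that("study writer produces byte-identical outputs for a fixed seed", {
  cfg <- sim_config(seed = 11, n_reads_per_library = 2000,
                    n_conserved_mirnas = 5, n_novel_precursors = 2,
                    genome_length = 10000, n_transcripts = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_srna_study(cfg, d1)
  s2 <- simulate_srna_study(cfg, d2)
  for (f in c("C1.fastq", "T2.fastq", "genome.fa", "mature_mirna.fa")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
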