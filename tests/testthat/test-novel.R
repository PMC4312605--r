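test_that("exact mapping finds both strands and rejects mismatches", {
  set.seed(3)
  tag <- random_seq(22)
  genome <- c(chrA = paste0(random_seq(100), tag, random_seq(100)))
  hits <- map_exact(tag, genome)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 100)
  expect_equal(hits$end, 122)
  expect_equal(hits$strand, "+")

  # the reverse complement maps to the same interval on the minus strand
  rc <- map_exact(revcomp(tag), genome)
  expect_equal(rc$start, 100)
  expect_equal(rc$end, 122)
  expect_equal(rc$strand, "-")

  # one substitution breaks the perfect-match contract
  mut <- tag
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tag, 11, 11))[1]
  expect_equal(nrow(map_exact(mut, genome)), 0)
})

test_that("exact mapping agrees with a naive string scan", {
  set.seed(4)
  genome <- c(g = random_seq(3000))
  tags <- c(vapply(1:10, function(i) {
    s <- sample(2900, 1)
    substr(genome[["g"]], s, s + 19)
  }, ""), random_seq(20))
  hits <- map_exact(tags, genome)
  for (tg in tags) {
    naive <- gregexpr(tg, genome[["g"]], fixed = TRUE)[[1]]
    naive <- naive[naive > 0]
    got <- hits$start[hits$sequence == tg & hits$strand == "+"]
    expect_setequal(got, naive - 1)
  }
})

test_that("candidate excision respects window arithmetic and orientation", {
  set.seed(5)
  genome <- c(chrA = random_seq(2000))
  locus <- tibble::tibble(chrom = "chrA", start = 1000, end = 1022,
                          strand = "+")
  w <- excise_candidates(locus, genome)
  expect_equal(nchar(w$sequence), c(20 + 22 + 200, 200 + 22 + 20))
  expect_equal(w$mature_offset, c(20, 200))
  # the mature is at the stated offset inside each window
  mat <- substr(genome[["chrA"]], 1001, 1022)
  for (i in 1:2) {
    expect_equal(substr(w$sequence[i], w$mature_offset[i] + 1,
                        w$mature_offset[i] + 22), mat)
  }

  # clipping at the contig start
  locus0 <- tibble::tibble(chrom = "chrA", start = 5, end = 27,
                           strand = "+")
  w0 <- excise_candidates(locus0, genome)
  expect_equal(w0$win_start[1], 0)
  expect_equal(w0$mature_offset[1], 5)

  # minus-strand windows are reverse-complemented, mature still recovered
  locus_m <- tibble::tibble(chrom = "chrA", start = 1000, end = 1022,
                            strand = "-")
  wm <- excise_candidates(locus_m, genome)
  for (i in 1:2) {
    expect_equal(substr(wm$sequence[i], wm$mature_offset[i] + 1,
                        wm$mature_offset[i] + 22), revcomp(mat))
  }
})

test_that("the folder reproduces hand-checkable structures", {
  f0 <- fold_rna("AAAAAA")
  expect_equal(f0$n_pairs, 0)
  expect_equal(f0$dot_bracket, "......")

  f1 <- fold_rna("GGGAAAACCC")
  expect_equal(f1$n_pairs, 3)
  expect_equal(f1$score, 9)
  expect_equal(f1$dot_bracket, "(((....)))")

  expect_error(fold_rna("ACG"), "too short")
})

test_that("folding optimum equals exhaustive enumeration on short RNAs", {
  set.seed(6)
  for (i in 1:60) {
    s <- random_seq(sample(8:16, 1))
    expect_equal(fold_rna(s)$score, oracle_fold_score(s), info = s)
  }
})

test_that("every folded structure is nested with valid loops", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_seq(sample(20:80, 1))
    f <- fold_rna(s)
    p <- f$partner
    idx <- which(!is.na(p))
    # partner symmetry and no self pairing
    expect_true(all(p[p[idx]] == idx))
    # loop constraint
    expect_true(all(abs(p[idx] - idx) > 3))
    # nesting: no crossing pairs
    op <- idx[idx < p[idx]]
    if (length(op) > 1) {
      for (a in op) {
        inside <- op[op > a & op < p[a]]
        expect_true(all(p[inside] < p[a]))
      }
    }
    # dot-bracket consistency
    db <- strsplit(f$dot_bracket, "")[[1]]
    expect_equal(which(db == "("), sort(op))
  }
})

test_that("hairpin evaluation enforces each annotation criterion", {
  set.seed(8)
  # planted perfect stem: passes with zero duplex mismatches
  mature <- random_seq(22)
  arm5 <- paste0(random_seq(20), mature, random_seq(20))
  prec <- paste0(arm5, "AAAA", revcomp(arm5))
  ev <- evaluate_hairpin(prec, 20, 22)
  expect_true(ev$pass)
  expect_equal(ev$mismatches, 0)
  expect_gte(ev$paired_frac, 0.9)

  # homopolymer window: nothing pairs
  ev2 <- evaluate_hairpin(strrep("A", 120), 40, 22)
  expect_false(ev2$pass)

  # mature straddling the loop fails the one-arm criterion
  half <- random_seq(30)
  prec3 <- paste0(half, "AAAAAA", revcomp(half))
  ev3 <- evaluate_hairpin(prec3, 25, 20)  # covers loop positions
  expect_false(ev3$one_arm)

  # mature outside candidate is an input error
  expect_error(evaluate_hairpin("ACGTACGT", 5, 10), "not contained")
})

test_that("novel calling recovers planted precursors from the fixture", {
  b <- small_bundle()
  refs <- small_refs()
  planted <- refs$manifest[!refs$manifest$conserved, ]
  called <- b$novel_calls
  recovered <- sum(planted$mature_sequence %in% called$sequence)
  expect_gte(recovered, ceiling(0.8 * nrow(planted)))
  # called loci overlap the planted precursor intervals
  for (i in seq_len(nrow(called))) {
    j <- match(called$sequence[i], planted$mature_sequence)
    if (is.na(j)) next
    expect_equal(called$strand[i], planted$strand[j])
    expect_true(called$prec_start[i] < planted$prec_end[j] &&
                  planted$prec_start[j] < called$prec_end[i])
  }
  # one call per distinct mature sequence
  expect_equal(anyDuplicated(called$sequence), 0)
})

test_that("novel calling degenerate inputs yield empty call sets", {
  genome <- c(g = random_seq(500))
  expect_equal(nrow(call_novel(character(0), genome)), 0)
  # a tag mapping nowhere produces no call
  expect_equal(nrow(call_novel(strrep("ACGTT", 4), genome)), 0)
})

test_that("novel call export writes FASTA, structures and GFF3", {
  b <- small_bundle()
  d <- withr::local_tempdir()
  paths <- export_novel_calls(b$novel_calls, d)
  expect_true(all(file.exists(paths)))
  gff <- readLines(paths[["gff3"]])
  expect_equal(gff[1], "##gff-version 3")
  expect_equal(length(gff) - 1, nrow(b$novel_calls))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(as.character(fa), setNames(b$novel_calls$precursor,
                                          names(fa)))
})
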