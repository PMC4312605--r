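ADAPT <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming handles full, partial and absent matches", {
  insert <- "ACGTACGT"
  # full adapter present: prefix before the leftmost occurrence
  expect_identical(trim_adapter(paste0(insert, ADAPT), ADAPT), insert)
  # adapter-only read: empty insert
  expect_identical(trim_adapter(ADAPT, ADAPT), NA_character_)
  # no adapter, length within the insert window: returned unchanged
  r24 <- strrep("AC", 12)
  expect_identical(trim_adapter(r24, ADAPT), r24)
  # no adapter and too long to be an insert: dropped
  expect_identical(trim_adapter(strrep("AC", 20), ADAPT), NA_character_)
  # partial terminal adapter >= min_overlap is trimmed (longest prefix)
  read <- paste0(r24, substr(ADAPT, 1, 8))
  expect_identical(trim_adapter(read, ADAPT), r24)
})

test_that("short terminal overlaps below min_overlap are left untouched", {
  r20 <- strrep("CA", 10)
  read <- paste0(r20, substr(ADAPT, 1, 5))  # 25 nt, within insert window
  expect_identical(trim_adapter(read, ADAPT), read)
})

test_that("trimming rejects non-nucleotide input and empty adapters", {
  expect_error(trim_adapter("ACGTXX", ADAPT), "non-nucleotide")
  expect_error(trim_adapter("ACGT", ""), "non-empty")
})

test_that("re-trimming fixture inserts is a no-op (idempotence)", {
  cfg <- small_config()
  refs <- small_refs()
  counts <- simulate_counts(refs$manifest, cfg, stream = "idem")
  reads <- synthesize_reads(counts, refs, cfg)
  ins <- trim_adapter(reads$t2$read, cfg$adapter_sequence)
  ins <- ins[!is.na(ins)]
  # an insert that happens to end in >= 6 bases of adapter prefix is
  # indistinguishable from an untrimmed read and is trimmed again; such
  # collisions are rare (4^-6 per read) and excluded from the identity
  ends_like_adapter <- rep(FALSE, length(ins))
  for (k in 6:(nchar(cfg$adapter_sequence) - 1)) {
    ends_like_adapter <- ends_like_adapter |
      endsWith(ins, substr(cfg$adapter_sequence, 1, k))
  }
  expect_lt(mean(ends_like_adapter), 0.002)
  keep <- ins[!ends_like_adapter]
  expect_identical(trim_adapter(keep, cfg$adapter_sequence), keep)
})

test_that("quality and length filters account for every read once", {
  q40 <- function(n) strrep("I", n)
  inserts <- c(strrep("A", 15), strrep("A", 16), strrep("A", 30),
               strrep("A", 31), paste0(strrep("A", 20), "N"),
               strrep("G", 24), NA)
  quals <- c(q40(15), q40(16), q40(30), q40(31), q40(21),
             paste0(strrep("#", 10), strrep("I", 14)), q40(10))
  res <- filter_clean(inserts, quals)
  # 15 and 31 nt dropped by length; 16 and 30 kept; N and low-quality
  # dropped; NA insert counted as adapter-dropped
  expect_equal(res$counters$total_raw, 7)
  expect_equal(res$counters$adapter_dropped, 1)
  expect_equal(res$counters$quality_dropped, 2)
  expect_equal(res$counters$length_dropped, 2)
  expect_equal(res$counters$retained, 2)
  expect_setequal(res$clean, c(strrep("A", 16), strrep("A", 30)))
  with(res$counters,
       expect_equal(total_raw,
                    adapter_dropped + quality_dropped + length_dropped +
                      retained))
})

test_that("an all-Q40 24-nt insert is kept", {
  res <- filter_clean(strrep("ACGT", 6), strrep("I", 24))
  expect_equal(res$counters$retained, 1)
})

test_that("collapsing counts occurrences per library and round-trips", {
  libs <- list(c1 = c(strrep("A", 24), strrep("A", 24), strrep("C", 24)),
               t1 = character(0),
               c2 = strrep("C", 24),
               t2 = c(strrep("G", 20)))
  tags <- collapse_tags(libs)
  expect_equal(nrow(tags), 3)
  a_row <- tags[tags$sequence == strrep("A", 24), ]
  expect_equal(a_row$c1, 2L)
  expect_equal(a_row$t1, 0L)
  expect_equal(sum(tags$c1), length(libs$c1))
  expect_equal(sum(tags$t1), 0L)
  # expand by counts and re-collapse: identity
  expanded <- lapply(c("c1", "t1", "c2", "t2"), function(l) {
    rep(tags$sequence, tags[[l]])
  })
  names(expanded) <- c("c1", "t1", "c2", "t2")
  expect_equal(collapse_tags(expanded), tags)
})

test_that("size distribution tallies unique tags and reads per length", {
  tags <- tibble::tibble(sequence = strrep("A", 24), c1 = 5L, t1 = 0L,
                         c2 = 0L, t2 = 0L)
  sd <- size_distribution(tags)
  expect_equal(sd$unique_tags[sd$length == 24], 1L)
  expect_equal(sd$total_reads[sd$length == 24], 5L)
  expect_equal(sum(sd$unique_tags), 1L)

  empty <- size_distribution(tags[0, ])
  expect_true(all(empty$unique_tags == 0 & empty$total_reads == 0))
  expect_equal(empty$length, 16:30)
})

test_that("library statistics form percentages of the raw total", {
  s <- library_stats(100, 100, 100)
  expect_equal(s$clean_pct, 100)
  expect_equal(s$unique_pct, 100)
  expect_error(library_stats(0, 0, 0), "positive")
  s2 <- library_stats(200, 117, 33)
  expect_equal(s2$clean_pct, 58.5)
  expect_equal(s2$unique_pct, 16.5)
})

test_that("fixture preprocessing conserves reads at every stage", {
  b <- small_bundle()
  cnt <- b$library_stats
  expect_equal(cnt$total_raw, rep(20000L, 4))
  # recount from the collapsed tags: per-library sums equal retained totals
  for (i in seq_along(c("c1", "t1", "c2", "t2"))) {
    lib <- c("c1", "t1", "c2", "t2")[i]
    expect_equal(sum(b$tags[[lib]]), cnt$clean_total[i])
  }
  # the 24-nt class is the modal unique-tag length
  sd <- b$size_distribution
  expect_equal(sd$length[which.max(sd$unique_tags)], 24L)
})
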