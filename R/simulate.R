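# Synthetic small RNA study generator.
#
# Emulates a two-genotype dehydration-stress design: four libraries
# (genotype 1 control/stress = C1/T1, genotype 2 control/stress = C2/T2),
# each a mix of conserved and novel miRNA reads, rRNA/tRNA/snoRNA/snRNA
# fragments, unassignable background sequences and a small fraction of
# low-quality reads. Every planted miRNA carries a known expression-pattern
# category and fold change, recorded in a truth manifest, so the full
# pipeline can be validated against ground truth.

LIBRARIES <- c("c1", "t1", "c2", "t2")

PATTERN_LEVELS <- c("up_both", "down_both", "opposite",
                    "genotype1_only", "genotype2_only", "unclassified")

# default insert length weights, 16..30 nt, modal at 24 nt
default_length_weights <- function() {
  w <- c(1, 1, 2, 3, 4, 7, 12, 16, 22, 14, 8, 5, 3, 2, 1)
  names(w) <- as.character(16:30)
  w / sum(w)
}

#' Configuration for the synthetic small RNA study
#'
#' Bundles and validates every tunable of the generator. The defaults define
#' the reference study conditions used throughout the package's tests: four
#' libraries of 200,000 reads, a 24-nt modal insert length, category
#' contamination shares echoing a typical plant small RNA annotation table,
#' 40 conserved and 8 novel planted miRNAs, and per-genotype fold changes
#' covering every expression-pattern category.
#'
#' @param seed Integer root seed; every stage derives a named substream from
#'   it, so partial reruns are reproducible.
#' @param n_reads_per_library Total reads generated per library.
#' @param adapter_sequence 3' adapter ligated to every insert.
#' @param read_length Sequencer read length in bases.
#' @param length_distribution Named numeric vector of insert-length
#'   probabilities over 16..30 nt (must sum to 1).
#' @param category_fractions Named probabilities over
#'   rRNA/tRNA/snoRNA/snRNA/miRNA/other (must sum to 1). The miRNA share is
#'   realised through the planted count model; the remainder of each library
#'   is filled with the other categories in these proportions.
#' @param n_conserved_mirnas,n_novel_precursors Numbers of planted miRNAs
#'   with (conserved) and without (novel) a mature-reference entry.
#' @param genome_length Length of the synthetic genome in bases.
#' @param baseline_range Range of per-library baseline mean read counts for
#'   planted miRNAs (drawn log-uniformly).
#' @param fold_choices Fold changes sampled for non-null planted miRNAs.
#' @param dispersion Negative-binomial overdispersion of the count model;
#'   0 gives Poisson sampling, matching the assumption of the downstream
#'   exact test.
#' @param error_rate Per-base substitution probability applied to miRNA and
#'   contaminant reads.
#' @param lowq_fraction Fraction of each library emitted as low-quality
#'   reads (dropped by the quality filter).
#' @param n_transcripts Number of synthetic transcripts with planted target
#'   sites (0 disables transcript generation).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 20140101,
                       n_reads_per_library = 200000,
                       adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 40,
                       length_distribution = default_length_weights(),
                       category_fractions = c(rRNA = 0.30, tRNA = 0.25,
                                              snoRNA = 0.08, snRNA = 0.03,
                                              miRNA = 0.04, other = 0.30),
                       n_conserved_mirnas = 40,
                       n_novel_precursors = 8,
                       genome_length = 100000,
                       baseline_range = c(40, 300),
                       fold_choices = c(3, 4, 6),
                       dispersion = 0.002,
                       error_rate = 0.001,
                       lowq_fraction = 0.02,
                       n_transcripts = 12) {
  stopifnot(n_reads_per_library > 0, n_conserved_mirnas > 0,
            n_novel_precursors > 0, genome_length > 0, read_length > 30,
            dispersion >= 0, error_rate >= 0, error_rate < 1,
            lowq_fraction >= 0, lowq_fraction < 1)
  adapter_sequence <- normalize_seq(adapter_sequence)
  if (abs(sum(length_distribution) - 1) > 1e-9) {
    stop("length_distribution must sum to 1", call. = FALSE)
  }
  lens <- as.integer(names(length_distribution))
  if (any(is.na(lens)) || any(lens < 16) || any(lens > 30)) {
    stop("length_distribution must be named by insert lengths in 16..30",
         call. = FALSE)
  }
  want <- c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA", "other")
  if (!setequal(names(category_fractions), want) ||
      abs(sum(category_fractions) - 1) > 1e-9) {
    stop("category_fractions must be named ", paste(want, collapse = "/"),
         " and sum to 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_reads_per_library = as.integer(n_reads_per_library),
                 adapter_sequence = adapter_sequence,
                 read_length = as.integer(read_length),
                 length_distribution = length_distribution,
                 category_fractions = category_fractions[want],
                 n_conserved_mirnas = as.integer(n_conserved_mirnas),
                 n_novel_precursors = as.integer(n_novel_precursors),
                 genome_length = as.integer(genome_length),
                 baseline_range = baseline_range,
                 fold_choices = fold_choices,
                 dispersion = dispersion,
                 error_rate = error_rate,
                 lowq_fraction = lowq_fraction,
                 n_transcripts = as.integer(n_transcripts)),
            class = "sim_config")
}

sample_insert_lengths <- function(n, config) {
  lens <- as.integer(names(config$length_distribution))
  if (n == 0) return(integer(0))
  sample(lens, n, replace = TRUE, prob = config$length_distribution)
}

# Build one hairpin precursor hosting `mature` on its 5' arm: 60-90 nt stem
# arms, 4-8 nt loop, mature kept >= 2 nt away from the loop, and up to two
# mismatches planted in the 3' arm so the duplex is imperfect but still
# passes the plant annotation criteria by construction.
build_precursor <- function(mature) {
  m <- nchar(mature)
  stem_len <- sample(60:90, 1)
  loop_len <- sample(4:8, 1)
  offset <- sample.int(stem_len - m - 1, 1)  # mature end >= 2 nt from loop
  arm5 <- random_dna(stem_len)
  substr(arm5, offset, offset + m - 1) <- mature
  arm3 <- revcomp(arm5)
  n_mm <- sample(0:2, 1)
  if (n_mm > 0) {
    pos <- sample.int(stem_len, n_mm)
    s <- strsplit(arm3, "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
    arm3 <- paste(s, collapse = "")
  }
  loop <- random_dna(loop_len)
  list(sequence = paste0(arm5, loop, arm3),
       mature_offset = offset - 1L)  # 0-based within precursor
}

make_fold_plan <- function(n, fold_choices) {
  base <- c(up_both = 0.17, down_both = 0.12, opposite = 0.17,
            genotype1_only = 0.12, genotype2_only = 0.12)
  counts <- floor(base * n)
  counts["null"] <- n - sum(counts)
  categories <- rep(names(counts), counts)
  tibble::tibble(
    pattern = sample(categories),
    fold = ifelse(pattern == "null", 1,
                  sample(fold_choices, n, replace = TRUE)),
    direction = sample(c(1, -1), n, replace = TRUE)
  )
}

#' Build the synthetic reference bundle
#'
#' Generates a toy genome with planted hairpin precursors, the per-category
#' contaminant reference sets (rRNA, tRNA, snoRNA, snRNA), a mature miRNA
#' reference containing only the conserved planted miRNAs, optional
#' transcripts with planted target sites, and the truth manifest recording
#' every planted miRNA's locus, pattern category and expected per-library
#' mean counts. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (named character), `references`
#'   (named list of named character vectors), `mature` (named character),
#'   `transcripts` (named character) and `manifest` (tibble).
#' @export
build_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "references", {
    n_mir <- config$n_conserved_mirnas + config$n_novel_precursors

    # distinct mature sequences, 20-24 nt
    matures <- character(0)
    while (length(unique(matures)) < n_mir) {
      matures <- unique(c(matures, random_dna(sample(20:24, n_mir, TRUE))))
    }
    matures <- matures[seq_len(n_mir)]
    is_conserved <- rep(c(TRUE, FALSE),
                        c(config$n_conserved_mirnas, config$n_novel_precursors))
    ids <- ifelse(is_conserved,
                  sprintf("con-miR-%03d", cumsum(is_conserved)),
                  sprintf("nov-miR-%03d", cumsum(!is_conserved)))

    precursors <- lapply(matures, build_precursor)
    prec_len <- vapply(precursors, function(p) nchar(p$sequence), 1L)
    need <- sum(prec_len) + n_mir * 50
    if (config$genome_length < need) {
      stop("genome_length too short to host ", n_mir,
           " precursors: need at least ", need, " bases", call. = FALSE)
    }

    genome <- random_dna(config$genome_length)
    # non-overlapping placement on an even grid, random strand
    slot <- config$genome_length %/% n_mir
    if (slot <= max(prec_len) + 2) {
      stop("genome_length too short to host ", n_mir, " precursors",
           call. = FALSE)
    }
    starts <- (seq_len(n_mir) - 1L) * slot +
      vapply(seq_len(n_mir), function(i) sample.int(slot - prec_len[i] - 1L, 1),
             1L)
    strands <- sample(c("+", "-"), n_mir, replace = TRUE)

    rows <- vector("list", n_mir)
    for (i in seq_len(n_mir)) {
      p <- precursors[[i]]
      plen <- prec_len[i]
      g0 <- starts[i]  # 0-based precursor start in genome
      inserted <- if (strands[i] == "+") p$sequence else revcomp(p$sequence)
      substr(genome, g0 + 1, g0 + plen) <- inserted
      if (strands[i] == "+") {
        m0 <- g0 + p$mature_offset
      } else {
        m0 <- g0 + plen - p$mature_offset - nchar(matures[i])
      }
      rows[[i]] <- tibble::tibble(
        mirna_id = ids[i], mature_sequence = matures[i],
        conserved = is_conserved[i],
        chrom = "chr_sim", prec_start = g0, prec_end = g0 + plen,
        mature_start = m0, mature_end = m0 + nchar(matures[i]),
        strand = strands[i], precursor_sequence = p$sequence,
        mature_offset = p$mature_offset
      )
    }
    manifest <- dplyr::bind_rows(rows)

    plan <- make_fold_plan(n_mir, config$fold_choices)
    baseline <- round(exp(stats::runif(n_mir, log(config$baseline_range[1]),
                                       log(config$baseline_range[2]))))
    f <- plan$fold
    up1 <- dplyr::case_when(
      plan$pattern == "up_both" ~ f,
      plan$pattern == "down_both" ~ 1 / f,
      plan$pattern == "opposite" ~ 1 / f,  # down in the tolerant genotype
      plan$pattern == "genotype1_only" ~ ifelse(plan$direction > 0, f, 1 / f),
      .default = 1
    )
    up2 <- dplyr::case_when(
      plan$pattern == "up_both" ~ f,
      plan$pattern == "down_both" ~ 1 / f,
      plan$pattern == "opposite" ~ f,      # up in the susceptible genotype
      plan$pattern == "genotype2_only" ~ ifelse(plan$direction > 0, f, 1 / f),
      .default = 1
    )
    manifest <- manifest |>
      dplyr::mutate(pattern = plan$pattern, fold = plan$fold,
                    mean_c1 = baseline, mean_t1 = baseline * up1,
                    mean_c2 = baseline, mean_t2 = baseline * up2)

    references <- list(
      rRNA = stats::setNames(random_dna(sample(800:2000, 5, TRUE)),
                             sprintf("rRNA_%02d", 1:5)),
      tRNA = stats::setNames(random_dna(sample(70:90, 20, TRUE)),
                             sprintf("tRNA_%02d", 1:20)),
      snoRNA = stats::setNames(random_dna(sample(100:200, 15, TRUE)),
                               sprintf("snoRNA_%02d", 1:15)),
      snRNA = stats::setNames(random_dna(sample(100:180, 10, TRUE)),
                              sprintf("snRNA_%02d", 1:10))
    )
    mature <- stats::setNames(matures[is_conserved], ids[is_conserved])

    transcripts <- character(0)
    if (config$n_transcripts > 0) {
      hosts <- sample(ids, config$n_transcripts, replace = TRUE)
      transcripts <- random_dna(sample(400:900, config$n_transcripts, TRUE))
      for (i in seq_along(transcripts)) {
        site <- revcomp(matures[match(hosts[i], ids)])
        pos <- sample.int(nchar(transcripts[i]) - nchar(site) - 1L, 1)
        substr(transcripts[i], pos, pos + nchar(site) - 1) <- site
      }
      names(transcripts) <- sprintf("transcript_%03d_%s", seq_along(hosts),
                                    hosts)
    }

    list(genome = c(chr_sim = genome), references = references,
         mature = mature, transcripts = transcripts, manifest = manifest)
  })
}

#' Draw per-library read counts for the planted miRNAs
#'
#' Counts are negative binomial with the manifest's per-library means and the
#' configured overdispersion (`dispersion = 0` gives Poisson draws). Mean
#' ratios between stress and control equal the planted fold changes;
#' null-category miRNAs share one mean across all four libraries.
#'
#' @param manifest Truth manifest from [build_references()].
#' @param config A [sim_config()].
#' @param stream Substream label, so repeated draws can be made independent.
#' @return Tibble `mirna_id`, `c1`, `t1`, `c2`, `t2` (integer counts).
#' @export
simulate_counts <- function(manifest, config, stream = "counts") {
  stopifnot(inherits(config, "sim_config"))
  draw <- function(mu) {
    if (config$dispersion <= 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
  }
  with_substream(config$seed, stream, {
    tibble::tibble(
      mirna_id = manifest$mirna_id,
      c1 = draw(manifest$mean_c1), t1 = draw(manifest$mean_t1),
      c2 = draw(manifest$mean_c2), t2 = draw(manifest$mean_t2)
    )
  })
}

lowq_quality <- function(lens) {
  vapply(lens, function(l) {
    q <- rep("I", l)
    q[sample.int(l, max(1, round(0.4 * l)))] <- "#"
    paste(q, collapse = "")
  }, "")
}

#' Synthesize the four FASTQ libraries
#'
#' Each read is an insert followed by the 3' adapter, truncated to the read
#' length. miRNA reads are exact copies of planted mature sequences (with
#' optional sequencing errors); contaminant reads are random fragments of the
#' category references; "other" reads are random sequences; a configured
#' fraction of reads carries low qualities. Per library, exactly
#' `n_reads_per_library` reads are emitted.
#'
#' @param counts Count table from [simulate_counts()].
#' @param refs Reference bundle from [build_references()].
#' @param config A [sim_config()].
#' @return Named list (`c1`, `t1`, `c2`, `t2`) of tibbles with columns
#'   `read`, `quality`, `origin`.
#' @export
synthesize_reads <- function(counts, refs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(counts[LIBRARIES] < 0)) stop("counts must be nonnegative")
  manifest <- refs$manifest
  mature_of <- stats::setNames(manifest$mature_sequence, manifest$mirna_id)

  contaminant_fragments <- function(n, records) {
    if (n == 0) return(character(0))
    rec <- sample(seq_along(records), n, replace = TRUE)
    lens <- pmin(sample_insert_lengths(n, config), nchar(records)[rec])
    starts <- vapply(seq_len(n), function(i) {
      sample.int(nchar(records[rec[i]]) - lens[i] + 1L, 1)
    }, 1L)
    substring(records[rec], starts, starts + lens - 1)
  }

  out <- vector("list", length(LIBRARIES))
  names(out) <- LIBRARIES
  for (lib in LIBRARIES) {
    out[[lib]] <- with_substream(config$seed, paste0("reads_", lib), {
      n_total <- config$n_reads_per_library
      mi_counts <- counts[[lib]]
      n_mi <- sum(mi_counts)
      if (n_mi > n_total) {
        stop("library ", lib, ": planted miRNA reads exceed library size")
      }
      mi_seqs <- rep(mature_of[counts$mirna_id], mi_counts)
      mi_origin <- rep(counts$mirna_id, mi_counts)

      n_lowq <- min(round(config$lowq_fraction * n_total), n_total - n_mi)
      n_rest <- n_total - n_mi - n_lowq
      fr <- config$category_fractions[c("rRNA", "tRNA", "snoRNA", "snRNA",
                                        "other")]
      alloc <- as.vector(stats::rmultinom(1, n_rest, fr / sum(fr)))
      names(alloc) <- names(fr)

      cont <- lapply(c("rRNA", "tRNA", "snoRNA", "snRNA"), function(cat) {
        contaminant_fragments(alloc[[cat]], refs$references[[cat]])
      })
      cont_seqs <- unlist(cont)
      cont_origin <- rep(c("rRNA", "tRNA", "snoRNA", "snRNA"),
                         alloc[c("rRNA", "tRNA", "snoRNA", "snRNA")])
      other_seqs <- random_dna(sample_insert_lengths(alloc[["other"]], config))
      lowq_seqs <- random_dna(sample_insert_lengths(n_lowq, config))

      noisy <- mutate_seqs(c(mi_seqs, cont_seqs), config$error_rate)
      inserts <- c(noisy, other_seqs, lowq_seqs)
      origin <- c(mi_origin, cont_origin,
                  rep("other", length(other_seqs)),
                  rep("lowq", length(lowq_seqs)))

      reads <- substr(paste0(inserts, config$adapter_sequence),
                      1, config$read_length)
      rlens <- nchar(reads)
      n_good <- length(inserts) - n_lowq
      qual <- c(strrep("I", rlens[seq_len(n_good)]),
                lowq_quality(rlens[n_good + seq_len(n_lowq)]))
      ord <- sample.int(length(reads))
      tibble::tibble(read = reads[ord], quality = qual[ord],
                     origin = origin[ord])
    })
  }
  out
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

write_fastq <- function(reads, path, prefix = "read") {
  ids <- sprintf("%s_%07d", prefix, seq_len(nrow(reads)))
  lines <- character(4 * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", ids)
  lines[seq(2, length(lines), 4)] <- reads$read
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete synthetic study on disk
#'
#' Runs [build_references()], [simulate_counts()] and [synthesize_reads()]
#' and writes the genome, reference FASTAs, four FASTQ libraries, the truth
#' manifest and the true count table under `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (named file paths), `manifest`,
#'   `counts` and the in-memory `refs` bundle.
#' @export
simulate_srna_study <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- build_references(config)
  counts <- simulate_counts(refs$manifest, config)
  reads <- synthesize_reads(counts, refs, config)

  p <- list(genome = file.path(out_dir, "genome.fa"),
            mature = file.path(out_dir, "mature_mirna.fa"),
            manifest = file.path(out_dir, "truth_manifest.tsv"),
            counts = file.path(out_dir, "true_counts.tsv"))
  write_fasta(refs$genome, p$genome)
  write_fasta(refs$mature, p$mature)
  for (cat in names(refs$references)) {
    p[[cat]] <- file.path(out_dir, paste0("ref_", cat, ".fa"))
    write_fasta(refs$references[[cat]], p[[cat]])
  }
  if (length(refs$transcripts) > 0) {
    p$transcripts <- file.path(out_dir, "transcripts.fa")
    write_fasta(refs$transcripts, p$transcripts)
  }
  for (lib in LIBRARIES) {
    p[[lib]] <- file.path(out_dir, paste0(toupper(lib), ".fastq"))
    write_fastq(reads[[lib]][c("read", "quality")], p[[lib]],
                prefix = toupper(lib))
  }
  readr::write_tsv(refs$manifest, p$manifest)
  readr::write_tsv(counts, p$counts)
  invisible(list(paths = p, manifest = refs$manifest, counts = counts,
                 refs = refs))
}
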