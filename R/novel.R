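# Novel miRNA calling: perfect genome mapping of unannotated tags,
# precursor window excision, hairpin folding, and the plant miRNA
# annotation criteria (mature confined to one stem arm, a mostly paired
# duplex with a bounded number of mismatches and small asymmetric bulges,
# a well-paired stem, and a 20-24 nt mature with a 2-nt 3' overhang star).

#' Exact genome mapping of tag sequences
#'
#' Finds all perfect occurrences of each tag on both strands; a minus-strand
#' locus is an occurrence of the tag's reverse complement, reported on the
#' forward coordinate system with `strand == "-"`. Coordinates are 0-based,
#' half-open.
#'
#' @param tags Character vector of tag sequences (16-30 nt).
#' @param genome Named character vector (or `DNAStringSet`) of contigs.
#' @return Tibble `sequence`, `chrom`, `start`, `end`, `strand`.
#' @export
map_exact <- function(tags, genome) {
  tags <- normalize_seq(tags)
  genome_set <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome_set))) names(genome_set) <- "contig_1"
  empty <- tibble::tibble(sequence = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0))
  if (length(tags) == 0) return(empty)

  hits <- list(empty)
  strands <- list(`+` = tags, `-` = revcomp(tags))
  for (strand in names(strands)) {
    qseqs <- strands[[strand]]
    by_width <- split(seq_along(tags), nchar(qseqs))
    for (idx in by_width) {
      pd <- Biostrings::PDict(qseqs[idx])
      for (ci in seq_along(genome_set)) {
        m <- Biostrings::matchPDict(pd, genome_set[[ci]])
        starts <- IRanges::start(m)
        n_hit <- lengths(starts)
        if (sum(n_hit) == 0) next
        hits[[length(hits) + 1]] <- tibble::tibble(
          sequence = rep(tags[idx], n_hit),
          chrom = names(genome_set)[ci],
          start = unlist(starts) - 1L,
          end = unlist(starts) - 1L + rep(nchar(tags[idx]), n_hit),
          strand = strand
        )
      }
    }
  }
  dplyr::bind_rows(hits) |>
    dplyr::arrange(.data$sequence, .data$chrom, .data$start, .data$strand)
}

#' Excise candidate precursor windows around a mapped mature locus
#'
#' Two windows are cut per locus, one with the long flank downstream of the
#' mature (mature near the 5' end of the hairpin) and one with the long
#' flank upstream (mature near the 3' end), both reported in the mature
#' strand's orientation and clipped at contig edges.
#'
#' @param locus One-row tibble (or list) with `chrom`, `start`, `end`,
#'   `strand` in 0-based half-open forward coordinates.
#' @param genome Named character vector of contigs.
#' @param upstream,downstream Short and long flank lengths (defaults 20 and
#'   200 nt).
#' @return Tibble `window` (1 or 2), `sequence`, `mature_offset` (0-based
#'   position of the mature within the oriented window), `win_start`,
#'   `win_end` (forward genome coordinates).
#' @export
excise_candidates <- function(locus, genome, upstream = 20, downstream = 200) {
  chrom_seq <- genome[[locus$chrom]]
  clen <- nchar(chrom_seq)
  s <- locus$start
  e <- locus$end
  stopifnot(s >= 0, s < e, e <= clen)

  flanks <- list(c(upstream, downstream), c(downstream, upstream))
  if (locus$strand == "-") flanks <- rev(flanks)
  rows <- lapply(seq_along(flanks), function(w) {
    lo <- max(0, s - flanks[[w]][1])
    hi <- min(clen, e + flanks[[w]][2])
    seq_fwd <- substr(chrom_seq, lo + 1, hi)
    if (locus$strand == "+") {
      tibble::tibble(window = w, sequence = seq_fwd,
                     mature_offset = s - lo, win_start = lo, win_end = hi)
    } else {
      tibble::tibble(window = w, sequence = revcomp(seq_fwd),
                     mature_offset = hi - e, win_start = lo, win_end = hi)
    }
  })
  dplyr::bind_rows(rows)
}

#' Fold an RNA/DNA sequence by weighted maximum base pairing
#'
#' Nussinov-style dynamic programme over nested structures: pair weights
#' GC = 3, AU = 2, GU = 1, hairpin loops of at least `min_loop` unpaired
#' bases, deterministic traceback (the 5'-most base that can pair at the
#' optimum is paired, with its 3'-most compatible partner).
#'
#' @param sequence Nucleotide string (T and U equivalent).
#' @param min_loop Minimum loop span (default 3).
#' @return A `hairpin_structure` list: `sequence`, `partner` (1-based pair
#'   partner per position, `NA` if unpaired), `dot_bracket`, `score`,
#'   `n_pairs`.
#' @export
fold_rna <- function(sequence, min_loop = 3) {
  sequence <- normalize_seq(sequence)
  if (nchar(sequence) < min_loop + 2) {
    stop("sequence too short to fold (need at least min_loop + 2 bases)",
         call. = FALSE)
  }
  res <- .nussinov_cpp(sequence, as.integer(min_loop))
  partner <- res$partner + 1L
  partner[partner == 0L] <- NA_integer_
  structure(list(sequence = sequence, partner = partner,
                 dot_bracket = res$dot_bracket, score = res$score,
                 n_pairs = res$n_pairs),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n",
      sprintf("score %d, %d pairs\n", x$score, x$n_pairs), sep = "")
  invisible(x)
}

#' Default thresholds of the plant miRNA annotation criteria
#'
#' @param max_duplex_mismatch Maximum unpaired mature bases in the
#'   miRNA/miRNA* duplex.
#' @param max_bulge Maximum asymmetric bulge (nt) within the duplex.
#' @param min_paired_frac Minimum fraction of paired bases over the hairpin
#'   region.
#' @param mature_len Allowed mature length range.
#' @param min_loop Folding loop constraint.
#' @return Named list of thresholds.
#' @export
novel_criteria <- function(max_duplex_mismatch = 4, max_bulge = 2,
                           min_paired_frac = 0.6, mature_len = c(20, 24),
                           min_loop = 3) {
  list(max_duplex_mismatch = max_duplex_mismatch, max_bulge = max_bulge,
       min_paired_frac = min_paired_frac, mature_len = mature_len,
       min_loop = min_loop)
}

#' Evaluate a candidate precursor against the annotation criteria
#'
#' Folds the candidate and checks that the mature lies entirely within one
#' stem arm (no self-pairing, all partners on one side), that at most
#' `max_duplex_mismatch` mature bases are unpaired, that no asymmetric
#' bulge in the duplex exceeds `max_bulge`, that the hairpin region
#' enclosing the mature is at least `min_paired_frac` paired, and that the
#' mature length is within range. The star sequence is excised from the
#' opposite arm with the canonical 2-nt 3' overhang.
#'
#' @param candidate Precursor candidate sequence.
#' @param mature_offset 0-based offset of the mature within `candidate`.
#' @param mature_len Mature length (bases).
#' @param criteria Thresholds from [novel_criteria()].
#' @return One-row tibble of decision flags and duplex metrics.
#' @export
evaluate_hairpin <- function(candidate, mature_offset, mature_len,
                             criteria = novel_criteria()) {
  candidate <- normalize_seq(candidate)
  n <- nchar(candidate)
  ms <- mature_offset + 1L          # 1-based
  me <- mature_offset + mature_len
  if (ms < 1 || me > n) {
    stop("mature not contained in candidate", call. = FALSE)
  }
  fold <- fold_rna(candidate, min_loop = criteria$min_loop)
  partner <- fold$partner
  mat_pos <- ms:me
  q <- partner[mat_pos]
  paired_pos <- mat_pos[!is.na(q)]
  q <- q[!is.na(q)]

  self_paired <- any(q >= ms & q <= me)
  one_arm <- length(q) > 0 && !self_paired && (all(q > me) || all(q < ms))

  mismatches <- mature_len - length(q)
  duplex_ok <- mismatches <= criteria$max_duplex_mismatch

  largest_bulge <- 0L
  if (length(q) >= 2) {
    dp <- diff(paired_pos) - 1L
    dq <- abs(diff(q)) - 1L
    largest_bulge <- max(abs(dp - dq))
  }
  bulge_ok <- largest_bulge <= criteria$max_bulge

  # hairpin region: outermost pair enclosing the mature, else the span of
  # the mature and its partners
  enc <- which(!is.na(partner) & seq_len(n) <= ms & partner >= me)
  if (length(enc) > 0) {
    lo <- min(enc)
    hi <- max(partner[enc])
  } else if (length(q) > 0) {
    lo <- min(ms, q)
    hi <- max(me, q)
  } else {
    lo <- ms
    hi <- me
  }
  region <- lo:hi
  paired_frac <- mean(!is.na(partner[region]))
  paired_ok <- paired_frac >= criteria$min_paired_frac

  length_ok <- mature_len >= criteria$mature_len[1] &&
    mature_len <= criteria$mature_len[2]

  star <- NA_character_
  if (length(q) > 0 && one_arm) {
    star <- substr(candidate, min(q), min(max(q) + 2L, n))
  }

  tibble::tibble(
    one_arm = one_arm, duplex_ok = duplex_ok, bulge_ok = bulge_ok,
    paired_ok = paired_ok, length_ok = length_ok,
    pass = one_arm && duplex_ok && bulge_ok && paired_ok && length_ok,
    mismatches = mismatches, largest_bulge = largest_bulge,
    paired_frac = paired_frac, hairpin_start = lo - 1L, hairpin_end = hi,
    star_sequence = star, dot_bracket = fold$dot_bracket,
    fold_score = fold$score
  )
}

#' Call novel miRNAs from unannotated tags
#'
#' Maps each tag perfectly to the genome (up to `max_loci` loci per tag),
#' excises the two candidate windows per locus, evaluates each against the
#' annotation criteria, and keeps the best passing candidate per distinct
#' mature sequence (highest paired fraction, ties by locus and window
#' order).
#'
#' @param unannotated Tag table (with `sequence` and per-library counts) or
#'   character vector of tag sequences.
#' @param genome Named character vector of contigs.
#' @param criteria Thresholds from [novel_criteria()].
#' @param upstream,downstream Window flanks (see [excise_candidates()]).
#' @param max_loci Maximum mapped loci evaluated per tag.
#' @return Tibble of calls: mature sequence, locus, strand, duplex metrics,
#'   star and dot-bracket, plus any count columns carried through.
#' @export
call_novel <- function(unannotated, genome, criteria = novel_criteria(),
                       upstream = 20, downstream = 200, max_loci = 20) {
  tags <- if (is.character(unannotated)) {
    tibble::tibble(sequence = unannotated)
  } else {
    unannotated
  }
  empty <- tibble::tibble(sequence = character(0))
  if (nrow(tags) == 0) return(empty)
  lens <- nchar(tags$sequence)
  tags <- tags[lens >= criteria$mature_len[1] &
                 lens <= criteria$mature_len[2], ]
  if (nrow(tags) == 0) return(empty)

  loci <- map_exact(tags$sequence, genome)
  if (nrow(loci) == 0) return(empty)
  loci <- dplyr::slice_head(dplyr::group_by(loci, .data$sequence),
                            n = max_loci) |>
    dplyr::ungroup()

  calls <- vector("list", 0)
  for (seq_i in unique(loci$sequence)) {
    seq_loci <- dplyr::filter(loci, .data$sequence == seq_i)
    best <- NULL
    for (li in seq_len(nrow(seq_loci))) {
      locus <- seq_loci[li, ]
      cands <- excise_candidates(locus, genome, upstream, downstream)
      for (wi in seq_len(nrow(cands))) {
        ev <- evaluate_hairpin(cands$sequence[wi], cands$mature_offset[wi],
                               nchar(seq_i), criteria)
        if (!ev$pass) next
        if (is.null(best) || ev$paired_frac > best$paired_frac + 1e-12) {
          best <- dplyr::bind_cols(
            tibble::tibble(sequence = seq_i, chrom = locus$chrom,
                           prec_start = cands$win_start[wi] +
                             (if (locus$strand == "+") ev$hairpin_start
                              else cands$win_end[wi] - cands$win_start[wi] -
                                ev$hairpin_end),
                           prec_end = cands$win_start[wi] +
                             (if (locus$strand == "+") ev$hairpin_end
                              else cands$win_end[wi] - cands$win_start[wi] -
                                ev$hairpin_start),
                           strand = locus$strand,
                           precursor = substr(cands$sequence[wi],
                                              ev$hairpin_start + 1,
                                              ev$hairpin_end)),
            ev[c("paired_frac", "mismatches", "largest_bulge",
                 "star_sequence", "dot_bracket")]
          )
        }
      }
    }
    if (!is.null(best)) calls[[length(calls) + 1]] <- best
  }
  if (length(calls) == 0) return(empty)
  out <- dplyr::bind_rows(calls)
  if (!is.character(unannotated)) {
    count_cols <- setdiff(names(unannotated), c("sequence", "category"))
    out <- dplyr::left_join(out,
                            unannotated[c("sequence", count_cols)],
                            by = "sequence")
  }
  out
}

#' Export novel miRNA calls
#'
#' Writes the precursor sequences as FASTA, the dot-bracket structures as
#' plain text, and the precursor loci as GFF3 (1-based inclusive
#' coordinates, per the format).
#'
#' @param calls Call table from [call_novel()].
#' @param dir Output directory.
#' @param prefix File name prefix (default "novel").
#' @return Invisibly, the written paths.
#' @export
export_novel_calls <- function(calls, dir, prefix = "novel") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("%s-%03d", prefix, seq_len(nrow(calls)))
  fa <- file.path(dir, paste0(prefix, "_precursors.fa"))
  db <- file.path(dir, paste0(prefix, "_structures.txt"))
  gff <- file.path(dir, paste0(prefix, "_loci.gff3"))
  if (nrow(calls) > 0) {
    write_fasta(stats::setNames(calls$precursor, ids), fa)
    writeLines(paste0(">", ids, "\n", calls$precursor, "\n",
                      calls$dot_bracket), db)
    gff_rows <- sprintf(
      "%s\tmirpattern\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
      calls$chrom, calls$prec_start + 1L, calls$prec_end, calls$strand, ids)
    writeLines(c("##gff-version 3", gff_rows), gff)
  } else {
    write_fasta(character(0), fa)
    writeLines(character(0), db)
    writeLines("##gff-version 3", gff)
  }
  invisible(c(fasta = fa, structures = db, gff3 = gff))
}
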