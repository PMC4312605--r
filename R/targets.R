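# miRU-style miRNA-target complementarity scoring: position-wise penalties
# over the first `score_len` miRNA positions after an optimal gapped
# antiparallel alignment, with seed-region penalties doubled, and a sliding
# scan over transcripts for sites under the score cutoff.

#' Penalty scheme for target complementarity scoring
#'
#' @param mismatch,wobble,gap Penalties for a mismatch, a G:U wobble and a
#'   gap (defaults 1, 0.5, 2).
#' @param seed Range of miRNA positions (1-based from the 5' end) whose
#'   penalties are multiplied by `seed_multiplier` (default 2-13, doubled).
#' @param seed_multiplier Seed penalty multiplier.
#' @param score_len Number of miRNA 5' positions scored (default 20).
#' @param cutoff Maximum expectation score E for a reported site.
#' @param max_gaps Maximum gaps in a duplex (default 1).
#' @param accessibility Parsed for compatibility with the conventions of
#'   plant target-prediction servers and ignored (no partition-function
#'   model is computed); supplying it raises a warning.
#' @return A `penalty_scheme` list.
#' @export
penalty_scheme <- function(mismatch = 1, wobble = 0.5, gap = 2,
                           seed = c(2, 13), seed_multiplier = 2,
                           score_len = 20, cutoff = 3, max_gaps = 1,
                           accessibility = NULL) {
  stopifnot(mismatch >= 0, wobble >= 0, gap >= 0, seed_multiplier >= 0,
            score_len > 0, cutoff >= 0, max_gaps >= 0,
            seed[1] >= 1, seed[2] <= score_len)
  if (!is.null(accessibility)) {
    warning("target accessibility (UPE) is parsed but ignored: ",
            "no partition-function energy model is computed",
            call. = FALSE)
  }
  structure(list(mismatch = mismatch, wobble = wobble, gap = gap,
                 seed = seed, seed_multiplier = seed_multiplier,
                 score_len = as.integer(score_len), cutoff = cutoff,
                 max_gaps = as.integer(max_gaps)),
            class = "penalty_scheme")
}

#' Optimal gapped duplex alignment between a miRNA and a site
#'
#' Minimises the total penalty of an antiparallel alignment of the miRNA
#' (5'->3') against the site (transcript orientation, 5'->3'; it is
#' reversed internally so position k of the miRNA faces position k of the
#' site read 3'->5'). At most `max_gaps` gaps; ties resolved toward fewer
#' gaps.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site Candidate site on the transcript, 5'->3'.
#' @param scheme A [penalty_scheme()].
#' @return List `score`, `n_gaps`, `mirna_aln` (5'->3'), `site_aln`
#'   (3'->5'), `pairing` (`|` Watson-Crick, `o` wobble, space otherwise).
#' @export
best_alignment <- function(mirna, site, scheme = penalty_scheme()) {
  mirna <- normalize_seq(mirna)
  site <- normalize_seq(site)
  if (abs(nchar(site) - nchar(mirna)) > scheme$max_gaps) {
    stop("length difference exceeds max_gaps", call. = FALSE)
  }
  site_rev <- paste(rev(strsplit(site, "")[[1]]), collapse = "")
  res <- .duplex_dp_cpp(mirna, site_rev, scheme$max_gaps, scheme$gap,
                        scheme$seed[1], scheme$seed[2], scheme$score_len,
                        scheme$seed_multiplier, scheme$mismatch,
                        scheme$wobble)
  res
}

#' Score a miRNA:site duplex
#'
#' Runs [best_alignment()] and annotates the duplex: the expectation score
#' E, the alignment strings, and whether the central positions 9-11 are
#' fully paired (the conventional cleavage-vs-translational-repression
#' flag).
#'
#' @inheritParams best_alignment
#' @return One-row tibble `score`, `n_gaps`, `mirna_aln`, `pairing`,
#'   `site_aln`, `mode` ("cleavage" or "translational").
#' @export
score_duplex <- function(mirna, site, scheme = penalty_scheme()) {
  res <- best_alignment(mirna, site, scheme)
  # central mismatch at miRNA positions 9-11 signals translational repression
  mir_pos <- cumsum(strsplit(res$mirna_aln, "")[[1]] != "-")
  marks <- strsplit(res$pairing, "")[[1]]
  central <- marks[mir_pos >= 9 & mir_pos <= 11]
  mode <- if (any(central != "|")) "translational" else "cleavage"
  tibble::tibble(score = res$score, n_gaps = res$n_gaps,
                 mirna_aln = res$mirna_aln, pairing = res$pairing,
                 site_aln = res$site_aln, mode = mode)
}

#' Scan transcripts for predicted target sites
#'
#' Slides windows of the miRNA length (+/- the allowed gaps) over each
#' transcript, scores every window with [score_duplex()], and reports
#' non-overlapping sites with E at or below the scheme cutoff, sorted by
#' score then coordinate. Site coordinates are 0-based half-open on the
#' transcript.
#'
#' @param mirnas Named character vector of miRNA sequences (5'->3').
#' @param transcripts Named character vector of transcript sequences.
#' @param scheme A [penalty_scheme()].
#' @return Tibble `mirna_id`, `transcript_id`, `start`, `end`, `score`,
#'   `mode`, `mirna_aln`, `pairing`, `site_aln`.
#' @export
scan_transcripts <- function(mirnas, transcripts, scheme = penalty_scheme()) {
  mirnas <- normalize_seq(mirnas)
  transcripts <- normalize_seq(transcripts)
  if (is.null(names(mirnas))) {
    names(mirnas) <- paste0("mirna_", seq_along(mirnas))
  }
  if (is.null(names(transcripts))) {
    names(transcripts) <- paste0("transcript_", seq_along(transcripts))
  }
  out <- list()
  for (mi in names(mirnas)) {
    m <- nchar(mirnas[[mi]])
    win_lens <- unique(pmax(1, (m - scheme$max_gaps):(m + scheme$max_gaps)))
    for (ti in names(transcripts)) {
      tr <- transcripts[[ti]]
      tlen <- nchar(tr)
      tr_rev <- paste(rev(strsplit(tr, "")[[1]]), collapse = "")
      cand <- list()
      for (w in win_lens) {
        if (w > tlen) next
        for (s in seq_len(tlen - w + 1)) {
          # window read 3'->5' is a forward substring of the reversed
          # transcript, so no per-window string reversal is needed
          site_rev <- substr(tr_rev, tlen - s - w + 2, tlen - s + 1)
          e <- .duplex_dp_cpp(mirnas[[mi]], site_rev, scheme$max_gaps,
                              scheme$gap, scheme$seed[1], scheme$seed[2],
                              scheme$score_len, scheme$seed_multiplier,
                              scheme$mismatch, scheme$wobble)$score
          if (!is.na(e) && e <= scheme$cutoff) {
            site <- substr(tr, s, s + w - 1)
            sc <- score_duplex(mirnas[[mi]], site, scheme)
            cand[[length(cand) + 1]] <- dplyr::bind_cols(
              tibble::tibble(mirna_id = mi, transcript_id = ti,
                             start = s - 1L, end = s - 1L + w),
              sc
            )
          }
        }
      }
      if (length(cand) == 0) next
      # ties prefer ungapped (minimal) windows, then the leftmost site
      cand <- dplyr::arrange(dplyr::bind_rows(cand), .data$score,
                             .data$n_gaps, .data$start)
      # greedy non-overlapping selection, best score first
      taken <- logical(0)
      sel <- integer(0)
      for (i in seq_len(nrow(cand))) {
        ov <- FALSE
        for (j in sel) {
          if (cand$start[i] < cand$end[j] && cand$start[j] < cand$end[i]) {
            ov <- TRUE
            break
          }
        }
        if (!ov) sel <- c(sel, i)
      }
      out[[length(out) + 1]] <- cand[sel, ]
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna_id = character(0),
                          transcript_id = character(0),
                          start = integer(0), end = integer(0),
                          score = numeric(0), mode = character(0)))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$mirna_id, .data$transcript_id, .data$score,
                   .data$start) |>
    dplyr::select("mirna_id", "transcript_id", "start", "end", "score",
                  "mode", "mirna_aln", "pairing", "site_aln")
}
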