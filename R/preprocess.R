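# Preprocessing: adapter trimming, quality/length filtering, collapsing
# reads to unique tags, and the library bookkeeping tables.

#' Trim the 3' adapter from read sequences
#'
#' Returns the insert upstream of the leftmost full adapter occurrence. When
#' the full adapter is absent, a terminal adapter prefix of at least
#' `min_overlap` bases at the read's 3' end is trimmed instead (the longest
#' such prefix). Reads with no adapter evidence are kept unchanged when they
#' are already no longer than `max_insert` (an insert can fill the whole
#' read without adapter read-through); longer adapter-free reads, and reads
#' whose insert would be empty, yield `NA`.
#'
#' @param reads Character vector of read sequences (A/C/G/T/N).
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum terminal adapter overlap to trim (default 6).
#' @param max_insert Longest believable insert (default 30 nt).
#' @return Character vector of inserts, `NA` where no insert was recovered.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6, max_insert = 30) {
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  reads <- normalize_seq(reads, allow_n = TRUE)
  adapter <- normalize_seq(adapter)

  out <- rep(NA_character_, length(reads))
  pos <- regexpr(adapter, reads, fixed = TRUE)
  full <- pos > 0
  out[full] <- substr(reads[full], 1, pos[full] - 1)

  todo <- which(!full)
  if (length(todo) > 0) {
    lens <- nchar(reads[todo])
    kmax <- min(nchar(adapter) - 1L, max(lens) - 1L)
    done <- rep(FALSE, length(todo))
    if (kmax >= min_overlap) {
      for (k in kmax:min_overlap) {  # longest terminal overlap wins
        cand <- which(!done & lens > k)
        if (length(cand) == 0) next
        hit <- substr(reads[todo[cand]], lens[cand] - k + 1, lens[cand]) ==
          substr(adapter, 1, k)
        idx <- cand[hit]
        out[todo[idx]] <- substr(reads[todo[idx]], 1, lens[idx] - k)
        done[idx] <- TRUE
      }
    }
    rest <- todo[!done]
    keep <- nchar(reads[rest]) <= max_insert
    out[rest[keep]] <- reads[rest[keep]]
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Quality- and length-filter trimmed inserts
#'
#' Drops inserts containing N, inserts where more than 20% of bases fall
#' below Q20, and inserts outside the `min_len`..`max_len` window. Every
#' input read is accounted for exactly once in the returned counters.
#'
#' @param inserts Character vector of inserts (`NA` = adapter-dropped).
#' @param qualities Phred+33 quality strings of the original reads; each is
#'   truncated to its insert's length.
#' @param min_len,max_len Retained insert length window (default 16..30).
#' @param max_low_frac Maximum tolerated fraction of sub-Q20 bases.
#' @return List with `clean` (character vector of retained inserts) and
#'   `counters` (one-row tibble: total_raw, adapter_dropped,
#'   quality_dropped, length_dropped, retained).
#' @export
filter_clean <- function(inserts, qualities = NULL, min_len = 16,
                         max_len = 30, max_low_frac = 0.2) {
  n <- length(inserts)
  adapter_dropped <- is.na(inserts)

  has_n <- !adapter_dropped & grepl("N", inserts, fixed = TRUE)
  low_bad <- rep(FALSE, n)
  if (!is.null(qualities)) {
    lens <- ifelse(adapter_dropped, 0L, nchar(inserts))
    q <- substr(qualities, 1, lens)
    # Phred+33 scores below Q20 are the ASCII range '!'..'4'
    n_low <- nchar(q) - nchar(gsub("[!-4]", "", q))
    low_bad <- !adapter_dropped & lens > 0 & (n_low / pmax(lens, 1)) > max_low_frac
  }
  quality_dropped <- !adapter_dropped & (has_n | low_bad)

  len <- nchar(inserts)
  length_dropped <- !adapter_dropped & !quality_dropped &
    (len < min_len | len > max_len)

  kept <- !adapter_dropped & !quality_dropped & !length_dropped
  counters <- tibble::tibble(
    total_raw = n,
    adapter_dropped = sum(adapter_dropped),
    quality_dropped = sum(quality_dropped),
    length_dropped = sum(length_dropped),
    retained = sum(kept)
  )
  list(clean = normalize_seq(inserts[kept]), counters = counters)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(read = as.character(x),
                 quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Preprocess one FASTQ library to clean reads
#'
#' Reads the library, trims the 3' adapter ([trim_adapter()]) and applies
#' the quality and 16-30 nt length filters ([filter_clean()]).
#'
#' @param fastq Path to a FASTQ file, or a tibble with `read` and `quality`
#'   columns.
#' @param adapter 3' adapter sequence.
#' @inheritParams trim_adapter
#' @inheritParams filter_clean
#' @return As [filter_clean()].
#' @export
preprocess_library <- function(fastq, adapter, min_overlap = 6,
                               min_len = 16, max_len = 30) {
  dat <- if (is.character(fastq)) read_fastq(fastq) else fastq
  inserts <- trim_adapter(dat$read, adapter, min_overlap = min_overlap,
                          max_insert = max_len)
  filter_clean(inserts, dat$quality, min_len = min_len, max_len = max_len)
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' @param libraries Named list of character vectors of clean read sequences,
#'   one per library (names become count columns, e.g. c1/t1/c2/t2).
#' @return Tibble with a `sequence` column and one integer count column per
#'   library; one row per distinct sequence.
#' @export
collapse_tags <- function(libraries) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  libs <- names(libraries)
  per_lib <- lapply(libs, function(lib) {
    s <- libraries[[lib]]
    if (length(s) == 0) {
      return(tibble::tibble(sequence = character(0), n = integer(0),
                            library = lib))
    }
    tab <- table(s)
    tibble::tibble(sequence = names(tab), n = as.integer(tab), library = lib)
  })
  out <- dplyr::bind_rows(per_lib) |>
    tidyr::pivot_wider(names_from = "library", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$sequence)
  for (lib in libs) {  # all-empty libraries still get a count column
    if (!lib %in% names(out)) out[[lib]] <- integer(nrow(out))
  }
  out[c("sequence", libs)]
}

#' Unique-tag and read-count size distribution
#'
#' @param tags Tag table from [collapse_tags()].
#' @param min_len,max_len Length range reported (zero-filled).
#' @return Tibble `length`, `unique_tags`, `total_reads`.
#' @export
size_distribution <- function(tags, min_len = 16, max_len = 30) {
  count_cols <- setdiff(names(tags), "sequence")
  base <- tibble::tibble(length = min_len:max_len)
  if (nrow(tags) == 0) {
    return(dplyr::mutate(base, unique_tags = 0L, total_reads = 0L))
  }
  tags |>
    dplyr::mutate(length = nchar(.data$sequence),
                  reads = rowSums(dplyr::pick(dplyr::all_of(count_cols)))) |>
    dplyr::summarise(unique_tags = dplyr::n(),
                     total_reads = as.integer(sum(.data$reads)),
                     .by = "length") |>
    dplyr::right_join(base, by = "length") |>
    dplyr::arrange(.data$length) |>
    tidyr::replace_na(list(unique_tags = 0L, total_reads = 0L))
}

#' Library summary percentages
#'
#' Reproduces the classic library bookkeeping layout: total raw reads, clean
#' reads and unique clean reads with their percentages of the raw total,
#' rounded to two decimals.
#'
#' @param total_raw,clean_total,unique_total Per-library totals (vectors of
#'   equal length).
#' @param library Optional library labels.
#' @param allow_zero Report `NA` percentages for empty libraries instead of
#'   raising the undefined-percentage error (used by the pipeline so an
#'   empty input still yields a valid bundle).
#' @return Tibble with counts and `clean_pct`, `unique_pct`.
#' @export
library_stats <- function(total_raw, clean_total, unique_total,
                          library = NULL, allow_zero = FALSE) {
  if (any(total_raw == 0) && !allow_zero) {
    stop("total_raw must be positive to form percentages", call. = FALSE)
  }
  total_div <- ifelse(total_raw == 0, NA_real_, total_raw)
  stopifnot(all(clean_total <= total_raw), all(unique_total >= 0))
  tibble::tibble(
    library = library %||% paste0("lib", seq_along(total_raw)),
    total_raw = total_raw,
    clean_total = clean_total,
    unique_total = unique_total,
    clean_pct = round2(clean_total / total_div * 100),
    unique_pct = round2(unique_total / total_div * 100)
  )
}
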