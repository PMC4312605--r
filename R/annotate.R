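# Cascade annotation of unique tags against ordered reference sets.
#
# The cascade mirrors the conventional small RNA triage: structural RNA
# categories (Rfam-style rRNA/tRNA/snoRNA/snRNA) take priority over the
# mature miRNA catalogue; anything left is "other" and feeds novel miRNA
# calling. First match wins, so every tag receives exactly one category.

CATEGORY_ORDER <- c("rRNA", "tRNA", "snoRNA", "snRNA", "repeat", "miRNA")

#' Assemble an ordered reference bundle for cascade annotation
#'
#' @param ... Named character vectors (or `DNAStringSet`s) of reference
#'   sequences; recognised names are rRNA, tRNA, snoRNA, snRNA, repeat and
#'   miRNA. The cascade priority is fixed
#'   (rRNA > tRNA > snoRNA > snRNA > repeat > miRNA) regardless of the
#'   argument order; the optional repeat set slots between snRNA and miRNA.
#' @param policy Match policy: `"exact"` (tag, on either strand, is an exact
#'   substring of a reference record) or `"mm1"` (at most one mismatch;
#'   intended for small inputs).
#' @return A `reference_sets` object.
#' @export
reference_sets <- function(..., policy = c("exact", "mm1")) {
  policy <- match.arg(policy)
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !is.null(names(sets[[1]]))) {
    sets <- sets[[1]]
  }
  unknown <- setdiff(names(sets), CATEGORY_ORDER)
  if (length(unknown) > 0) {
    stop("unknown reference categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(s) normalize_seq(as.character(s)))
  if (any(vapply(sets, function(s) any(!nzchar(s)), TRUE))) {
    stop("reference sequences must be non-empty", call. = FALSE)
  }
  structure(list(sets = sets[intersect(CATEGORY_ORDER, names(sets))],
                 policy = policy),
            class = "reference_sets")
}

# TRUE for each tag that occurs (either strand) as a substring of any
# reference record. Exact matching uses width-grouped PDicts so large tag
# sets stay fast; the mm1 policy scans per tag and is meant for small sets.
match_any_reference <- function(tags, ref_seqs, policy = "exact") {
  if (length(tags) == 0 || length(ref_seqs) == 0) {
    return(rep(FALSE, length(tags)))
  }
  subject <- Biostrings::DNAStringSet(ref_seqs)
  hit <- rep(FALSE, length(tags))
  if (policy == "exact") {
    for (strand_seqs in list(tags, revcomp(tags))) {
      by_width <- split(seq_along(tags), nchar(strand_seqs))
      for (idx in by_width) {
        sub_idx <- idx[!hit[idx]]
        if (length(sub_idx) == 0) next
        pd <- Biostrings::PDict(strand_seqs[sub_idx])
        counts <- Biostrings::vcountPDict(pd, subject, collapse = 1)
        hit[sub_idx] <- hit[sub_idx] | counts > 0
      }
    }
  } else {
    for (i in seq_along(tags)) {
      for (q in c(tags[i], revcomp(tags[i]))) {
        n <- sum(Biostrings::vcountPattern(q, subject, max.mismatch = 1))
        if (n > 0) {
          hit[i] <- TRUE
          break
        }
      }
    }
  }
  hit
}

#' Classify unique tags by cascade reference matching
#'
#' @param tags Tag table from [collapse_tags()] (needs a `sequence`
#'   column), or a character vector of tag sequences.
#' @param references A [reference_sets()] bundle.
#' @return The tag table with a `category` column (factor over the cascade
#'   categories plus `"other"`).
#' @export
classify_tags <- function(tags, references) {
  stopifnot(inherits(references, "reference_sets"))
  seqs <- if (is.character(tags)) tags else tags$sequence
  category <- rep("other", length(seqs))
  unassigned <- rep(TRUE, length(seqs))
  for (cat in names(references$sets)) {
    idx <- which(unassigned)
    if (length(idx) == 0) break
    hits <- match_any_reference(seqs[idx], references$sets[[cat]],
                                references$policy)
    category[idx[hits]] <- cat
    unassigned[idx[hits]] <- FALSE
  }
  category <- factor(category, levels = c(names(references$sets), "other"))
  if (is.character(tags)) {
    tibble::tibble(sequence = tags, category = category)
  } else {
    dplyr::mutate(tags, category = category)
  }
}

#' Per-category annotation summary of the four libraries
#'
#' Counts unique tags and read-weighted totals per category and library,
#' with percentages on two denominators: the annotated tag universe
#' (`unique_pct`, `reads_pct`, the classic annotation-table convention) and
#' the library clean-read totals (`reads_pct_clean`), since either may be
#' wanted when comparing with published summaries.
#'
#' @param classified Output of [classify_tags()] on a tag table with
#'   per-library count columns.
#' @param clean_totals Optional named vector of library clean-read totals
#'   for the second denominator.
#' @return Tibble `category`, `library`, `unique_tags`, `reads`,
#'   `unique_pct`, `reads_pct` (and `reads_pct_clean` when totals given).
#' @export
annotate_libraries <- function(classified, clean_totals = NULL) {
  count_cols <- setdiff(names(classified), c("sequence", "category"))
  long <- classified |>
    tidyr::pivot_longer(dplyr::all_of(count_cols), names_to = "library",
                        values_to = "n") |>
    dplyr::summarise(unique_tags = sum(.data$n > 0),
                     reads = sum(.data$n),
                     .by = c("category", "library")) |>
    tidyr::complete(category = unique(classified$category),
                    library = count_cols,
                    fill = list(unique_tags = 0L, reads = 0L)) |>
    dplyr::mutate(
      unique_pct = round2(.data$unique_tags / sum(.data$unique_tags) * 100),
      reads_pct = round2(.data$reads / sum(.data$reads) * 100),
      .by = "library"
    )
  if (!is.null(clean_totals)) {
    long <- long |>
      dplyr::mutate(reads_pct_clean = round2(
        .data$reads / clean_totals[.data$library] * 100))
  }
  dplyr::arrange(long, .data$library,
                 factor(.data$category, levels = c(CATEGORY_ORDER, "other")))
}

#' Tags left for novel miRNA calling
#'
#' @param classified Output of [classify_tags()].
#' @return The subset of rows with category `"other"`.
#' @export
partition_unannotated <- function(classified) {
  dplyr::filter(classified, .data$category == "other")
}
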