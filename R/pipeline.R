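# End-to-end orchestration: preprocess -> annotate -> novel calling ->
# differential expression -> pattern classification -> target scanning,
# with stage outputs written as TSVs and a report bundle mirroring the
# classic library/annotation/DE table layouts.

#' Assign miRNA-category tags to mature reference records
#'
#' Each tag annotated as miRNA is matched (either strand, exact substring)
#' to the mature reference; counts of all tags assigned to the same mature
#' record are summed, giving the per-miRNA read counts that enter the
#' differential-expression tests. A tag matching several records is
#' assigned to the first in reference order.
#'
#' @param mirna_tags Tag table restricted to miRNA-category tags.
#' @param mature Named character vector of mature miRNA reference records.
#' @return Tibble `mirna_id` plus summed per-library count columns.
#' @export
count_mature_mirnas <- function(mirna_tags, mature) {
  count_cols <- setdiff(names(mirna_tags), c("sequence", "category"))
  empty <- tibble::tibble(mirna_id = character(0))
  if (nrow(mirna_tags) == 0 || length(mature) == 0) return(empty)
  subject <- Biostrings::DNAStringSet(normalize_seq(mature))
  assign_to <- rep(NA_integer_, nrow(mirna_tags))
  for (strand_seqs in list(mirna_tags$sequence,
                           revcomp(mirna_tags$sequence))) {
    by_width <- split(seq_len(nrow(mirna_tags)), nchar(strand_seqs))
    for (idx in by_width) {
      open <- idx[is.na(assign_to[idx])]
      if (length(open) == 0) next
      pd <- Biostrings::PDict(strand_seqs[open])
      hits <- Biostrings::vcountPDict(pd, subject) > 0
      first <- apply(hits, 1, function(r) {
        w <- which(r)
        if (length(w) == 0) NA_integer_ else w[1]
      })
      assign_to[open] <- first
    }
  }
  keep <- !is.na(assign_to)
  if (!any(keep)) return(empty)
  mirna_tags[keep, count_cols, drop = FALSE] |>
    dplyr::mutate(mirna_id = names(mature)[assign_to[keep]]) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(count_cols), sum),
                     .by = "mirna_id")
}

#' Pipeline configuration
#'
#' Either a `simulation` block ([sim_config()]) from which the four
#' libraries and references are generated, or explicit paths to four FASTQ
#' libraries and the reference FASTA files.
#'
#' @param simulation Optional [sim_config()]; when given, inputs are
#'   generated under `out_dir`.
#' @param fastq Named character vector of FASTQ paths (`c1`, `t1`, `c2`,
#'   `t2`).
#' @param references Named character vector of reference FASTA paths
#'   (rRNA/tRNA/snoRNA/snRNA), plus `mature`.
#' @param genome Path to the genome FASTA.
#' @param transcripts Optional transcript FASTA for target scanning.
#' @param adapter 3' adapter sequence.
#' @param criteria [screen_criteria()] thresholds.
#' @param novel [novel_criteria()] thresholds.
#' @param scheme [penalty_scheme()] for target scoring.
#' @param test Differential-expression test ("poisson" or "chisq").
#' @param out_dir Output directory for stage TSVs (`NULL` = in-memory
#'   only).
#' @param max_target_mirnas Cap on the number of screened miRNAs scanned
#'   against transcripts (strongest fold changes first).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, fastq = NULL,
                            references = NULL, genome = NULL,
                            transcripts = NULL,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            criteria = screen_criteria(),
                            novel = novel_criteria(),
                            scheme = penalty_scheme(),
                            test = "poisson", out_dir = NULL,
                            max_target_mirnas = 10) {
  if (is.null(simulation) &&
      (is.null(fastq) || is.null(references) || is.null(genome))) {
    stop("either a simulation block or fastq + references + genome paths ",
         "must be given", call. = FALSE)
  }
  structure(list(simulation = simulation, fastq = fastq,
                 references = references, genome = genome,
                 transcripts = transcripts, adapter = adapter,
                 criteria = criteria, novel = novel, scheme = scheme,
                 test = test, out_dir = out_dir,
                 max_target_mirnas = max_target_mirnas),
            class = "pipeline_config")
}

read_fasta_named <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Run the full pipeline
#'
#' Executes every stage in order, writing each stage's table under
#' `out_dir` (when set) before the next stage starts, and returns a
#' `report_bundle` with the library statistics, size distribution,
#' annotation summary, per-miRNA counts, differential-expression results,
#' screened hits, pattern classification with per-category tables, novel
#' miRNA calls and target predictions.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list of tibbles (plus the `mir_de` object).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
    }
    tbl
  }

  if (!is.null(config$simulation)) {
    sim_dir <- if (!is.null(out_dir)) file.path(out_dir, "simulated") else
      tempfile("mirpattern_sim_")
    sim <- simulate_srna_study(config$simulation, sim_dir)
    fastq <- unlist(sim$paths[LIBRARIES])
    ref_paths <- unlist(sim$paths[c("rRNA", "tRNA", "snoRNA", "snRNA")])
    mature <- sim$refs$mature
    genome <- sim$refs$genome
    transcripts <- sim$refs$transcripts
    adapter <- config$simulation$adapter_sequence
    truth <- sim$manifest
  } else {
    fastq <- config$fastq[LIBRARIES]
    ref_paths <- config$references[c("rRNA", "tRNA", "snoRNA", "snRNA")]
    mature <- read_fasta_named(config$references[["mature"]])
    genome <- read_fasta_named(config$genome)
    transcripts <- if (!is.null(config$transcripts)) {
      read_fasta_named(config$transcripts)
    } else character(0)
    adapter <- config$adapter
    truth <- NULL
  }

  # --- preprocess ----------------------------------------------------------
  pre <- lapply(fastq, preprocess_library, adapter = adapter)
  names(pre) <- LIBRARIES
  counters <- dplyr::bind_rows(lapply(pre, `[[`, "counters"))
  clean <- lapply(pre, `[[`, "clean")
  tags <- collapse_tags(clean)
  unique_totals <- vapply(LIBRARIES, function(l) sum(tags[[l]] > 0), 1L)
  stats_tbl <- emit(library_stats(counters$total_raw, counters$retained,
                                  unique_totals,
                                  library = toupper(LIBRARIES),
                                  allow_zero = TRUE),
                    "library_stats")
  size_tbl <- emit(size_distribution(tags), "size_distribution")
  clean_totals <- stats::setNames(counters$retained, LIBRARIES)

  # --- annotate ------------------------------------------------------------
  refs <- lapply(ref_paths, read_fasta_named)
  names(refs) <- c("rRNA", "tRNA", "snoRNA", "snRNA")
  refs$miRNA <- mature
  classified <- classify_tags(tags, reference_sets(refs))
  annot_tbl <- emit(annotate_libraries(classified, clean_totals),
                    "annotation_summary")

  # --- novel miRNA calling -------------------------------------------------
  unann <- partition_unannotated(classified)
  novel_calls <- call_novel(unann, genome, criteria = config$novel)
  emit(novel_calls, "novel_calls")

  # --- differential expression ---------------------------------------------
  mirna_tags <- dplyr::filter(classified, .data$category == "miRNA")
  conserved_counts <- count_mature_mirnas(mirna_tags, mature)
  catalog <- tibble::tibble(mirna_id = conserved_counts$mirna_id,
                            sequence = unname(mature[
                              conserved_counts$mirna_id]),
                            source = "conserved")
  novel_counts <- if (nrow(novel_calls) > 0 &&
                        all(LIBRARIES %in% names(novel_calls))) {
    novel_calls |>
      dplyr::mutate(mirna_id = paste0("novel-", dplyr::row_number())) |>
      dplyr::select("mirna_id", dplyr::all_of(LIBRARIES),
                    novel_sequence = "sequence")
  } else {
    tibble::tibble(mirna_id = character(0))
  }
  if (nrow(novel_counts) > 0) {
    catalog <- dplyr::bind_rows(
      catalog,
      tibble::tibble(mirna_id = novel_counts$mirna_id,
                     sequence = novel_counts$novel_sequence,
                     source = "novel"))
  }
  counts <- dplyr::bind_rows(conserved_counts,
                             dplyr::select(novel_counts, -dplyr::any_of(
                               "novel_sequence")))
  de <- NULL
  de_hits <- tibble::tibble()
  classified_mirnas <- tibble::tibble()
  class_counts <- summarize_classes(factor(character(0),
                                           levels = PATTERN_LEVELS))
  if (nrow(counts) > 0) {
    de <- diff_expression(counts, clean_totals, test = config$test,
                          criteria = config$criteria)
    emit(de$results, "de_results")
    de_hits <- emit(screen_de(de), "de_hits")

    # --- classification ----------------------------------------------------
    wide <- de$results |>
      dplyr::select("mirna_id", "genotype", "log2_ratio") |>
      tidyr::pivot_wider(names_from = "genotype",
                         values_from = "log2_ratio")
    sig_ids <- unique(de_hits$mirna_id)
    classified_mirnas <- wide |>
      dplyr::filter(.data$mirna_id %in% sig_ids) |>
      dplyr::mutate(pattern = classify_pattern(
        .data$genotype1, .data$genotype2,
        threshold = config$criteria$log2_threshold))
    classified_mirnas <- emit(classified_mirnas, "classified_mirnas")
    class_counts <- emit(summarize_classes(classified_mirnas),
                         "pattern_counts")
  }

  # --- target prediction ---------------------------------------------------
  target_predictions <- tibble::tibble()
  if (length(transcripts) > 0 && nrow(de_hits) > 0) {
    top <- de_hits |>
      dplyr::arrange(dplyr::desc(.data$fold_change)) |>
      dplyr::distinct(.data$mirna_id) |>
      utils::head(config$max_target_mirnas)
    seq_of <- c(mature,
                stats::setNames(novel_counts$novel_sequence,
                                novel_counts$mirna_id))
    scan_ids <- intersect(top$mirna_id, names(seq_of))
    if (length(scan_ids) > 0) {
      target_predictions <- scan_transcripts(seq_of[scan_ids], transcripts,
                                             config$scheme)
    }
  }
  emit(target_predictions, "target_predictions")

  structure(list(library_stats = stats_tbl, size_distribution = size_tbl,
                 annotation_summary = annot_tbl, tags = classified,
                 counts = counts, de = de, de_hits = de_hits,
                 classified = classified_mirnas,
                 pattern_counts = class_counts, novel_calls = novel_calls,
                 target_predictions = target_predictions,
                 mirna_catalog = catalog,
                 clean_totals = clean_totals, truth = truth,
                 config = config),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("small RNA pipeline report\n")
  cat("  clean reads: ", paste(x$library_stats$clean_total, collapse = "/"),
      "\n", sep = "")
  cat("  unique tags: ", nrow(x$tags), "\n", sep = "")
  cat("  novel miRNA calls: ", nrow(x$novel_calls), "\n", sep = "")
  cat("  screened DE calls: ", nrow(x$de_hits), "\n", sep = "")
  if (nrow(x$pattern_counts) > 0) {
    cat("  pattern counts: ",
        paste(x$pattern_counts$pattern, x$pattern_counts$n, sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

format2 <- function(x) formatC(x, format = "f", digits = 2)

#' Write the publication-style tables of a report bundle
#'
#' Emits the library-statistics table, the annotation summary, and one DE
#' table per expression-pattern category (up in both, down in both,
#' opposite, single genotype) with TPM and log2 columns formatted at two
#' decimals; empty categories yield header-only files.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
emit_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p)
    paths[[name]] <<- p
  }
  wr(bundle$library_stats, "library_stats")
  wr(bundle$annotation_summary, "annotation_summary")
  wr(bundle$size_distribution, "size_distribution")

  if (!is.null(bundle$de)) {
    tpm_wide <- bundle$de$results |>
      dplyr::select("mirna_id", "genotype", "tpm_control", "tpm_stress",
                    "log2_ratio") |>
      tidyr::pivot_wider(names_from = "genotype",
                         values_from = c("tpm_control", "tpm_stress",
                                         "log2_ratio"))
    groups <- list(up_both = "up_both", down_both = "down_both",
                   opposite = "opposite",
                   one_genotype = c("genotype1_only", "genotype2_only"))
    for (g in names(groups)) {
      ids <- bundle$classified$mirna_id[
        bundle$classified$pattern %in% groups[[g]]]
      tbl <- tpm_wide |>
        dplyr::filter(.data$mirna_id %in% ids) |>
        dplyr::transmute(
          mirna_id = .data$mirna_id,
          tpm_c1 = format2(.data$tpm_control_genotype1),
          tpm_t1 = format2(.data$tpm_stress_genotype1),
          tpm_c2 = format2(.data$tpm_control_genotype2),
          tpm_t2 = format2(.data$tpm_stress_genotype2),
          log2_t1_c1 = format2(.data$log2_ratio_genotype1),
          log2_t2_c2 = format2(.data$log2_ratio_genotype2))
      wr(tbl, paste0("de_", g))
    }
  }
  if (nrow(bundle$novel_calls) > 0) wr(bundle$novel_calls, "novel_calls")
  if (nrow(bundle$target_predictions) > 0) {
    wr(bundle$target_predictions, "target_predictions")
  }
  invisible(paths)
}

#' Size-distribution bar plot (unique tags per insert length)
#'
#' @param size_tbl Output of [size_distribution()], or a `report_bundle`.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(size_tbl) {
  if (inherits(size_tbl, "report_bundle")) {
    size_tbl <- size_tbl$size_distribution
  }
  ggplot2::ggplot(size_tbl, ggplot2::aes(.data$length, .data$unique_tags)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "sequence length (nt)", y = "unique tags") +
    ggplot2::theme_minimal()
}

#' Expression-pattern category counts plot
#'
#' @param counts Output of [summarize_classes()], or a `report_bundle`.
#' @return A ggplot.
#' @export
plot_pattern_counts <- function(counts) {
  if (inherits(counts, "report_bundle")) counts <- counts$pattern_counts
  ggplot2::ggplot(counts, ggplot2::aes(.data$pattern, .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "miRNAs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
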