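# Bundled study summary tables: the published expression values of 46
# conserved dehydration-responsive wheat miRNAs in a drought-tolerant
# (genotype 1) and a drought-susceptible (genotype 2) cultivar, and the
# corresponding library bookkeeping and annotation summaries. These are the
# worked-example inputs for the classifier and the normalisation
# arithmetic.

#' Conserved dehydration-responsive miRNA summary table
#'
#' Per-miRNA normalised expression (TPM, pseudocount-substituted where the
#' library had zero reads) in the four libraries (C1/T1 genotype 1
#' control/stress, C2/T2 genotype 2), the printed per-genotype log2
#' stress/control ratios, the published pattern grouping (up in both, down
#' in both, opposite, single genotype) and the putative target annotation.
#'
#' @return Tibble of 46 miRNAs.
#' @export
conserved_mirna_table <- function() {
  readr::read_tsv(system.file("extdata", "conserved_mirnas.tsv",
                              package = "mirpattern"),
                  show_col_types = FALSE)
}

#' Library bookkeeping summary (raw, clean and unique read totals)
#'
#' @return Tibble of the four libraries with clean/unique percentages of
#'   the raw totals.
#' @export
library_stats_table <- function() {
  readr::read_tsv(system.file("extdata", "library_stats.tsv",
                              package = "mirpattern"),
                  show_col_types = FALSE)
}

#' Annotation summary (unique tags and reads per category and library)
#'
#' @return Tibble of per-category unique-tag and read counts of the
#'   annotated tag universe in each library.
#' @export
annotation_summary_table <- function() {
  readr::read_tsv(system.file("extdata", "annotation_summary.tsv",
                              package = "mirpattern"),
                  show_col_types = FALSE)
}
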