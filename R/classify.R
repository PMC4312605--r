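# Cross-genotype expression-pattern classification and qPCR arithmetic.

#' Classify a pair of per-genotype log2 ratios into an expression pattern
#'
#' With threshold `t` (default 1) on the stress/control log2 ratios `l1`
#' (genotype 1) and `l2` (genotype 2): up in both when both exceed `t`;
#' down in both when both are below `-t`; opposite when both magnitudes
#' exceed `t` with opposite signs; genotype-specific when exactly one
#' magnitude exceeds `t`; unclassified otherwise.
#'
#' @param l1,l2 Finite log2 ratios (vectors of equal length).
#' @param threshold Magnitude cutoff (default 1).
#' @return Factor with levels up_both, down_both, opposite,
#'   genotype1_only, genotype2_only, unclassified.
#' @export
classify_pattern <- function(l1, l2, threshold = 1) {
  stopifnot(all(is.finite(l1)), all(is.finite(l2)),
            length(l1) == length(l2))
  t <- threshold
  out <- dplyr::case_when(
    l1 > t & l2 > t ~ "up_both",
    l1 < -t & l2 < -t ~ "down_both",
    abs(l1) > t & abs(l2) > t ~ "opposite",
    abs(l1) > t & abs(l2) <= t ~ "genotype1_only",
    abs(l1) <= t & abs(l2) > t ~ "genotype2_only",
    .default = "unclassified"
  )
  factor(out, levels = PATTERN_LEVELS)
}

#' Count miRNAs per expression-pattern category
#'
#' @param pattern A factor from [classify_pattern()], or a tibble with a
#'   `pattern` column.
#' @return Tibble `pattern`, `n` (all category levels present, zero-filled;
#'   counts sum to the input size).
#' @export
summarize_classes <- function(pattern) {
  if (is.data.frame(pattern)) pattern <- pattern$pattern
  tab <- table(factor(pattern, levels = PATTERN_LEVELS))
  tibble::tibble(pattern = factor(names(tab), levels = PATTERN_LEVELS),
                 n = as.integer(tab))
}

#' Relative expression by the 2^-ddCT method
#'
#' Double normalisation of qPCR threshold cycles: the target CT is
#' referenced to the reference-gene CT within each condition, and the
#' stressed delta-CT to the control delta-CT.
#'
#' @param target_ct_stress,ref_ct_stress,target_ct_control,ref_ct_control
#'   Mean threshold cycles (replicates averaged upstream).
#' @return `2^-((target_s - ref_s) - (target_c - ref_c))`.
#' @export
ddct <- function(target_ct_stress, ref_ct_stress,
                 target_ct_control, ref_ct_control) {
  stopifnot(all(c(target_ct_stress, ref_ct_stress,
                  target_ct_control, ref_ct_control) > 0))
  2^-((target_ct_stress - ref_ct_stress) -
        (target_ct_control - ref_ct_control))
}

#' Relative expression from a tidy qPCR CT table
#'
#' Averages technical replicates, then applies [ddct()] per gene against
#' the named reference gene within each sample.
#'
#' @param data Tibble with columns `sample`, `gene`, `condition`
#'   (control/stress), `replicate`, `ct`.
#' @param reference Reference gene name (default `"18S"`).
#' @return Tibble `sample`, `gene`, `relative_expression` (stress relative
#'   to control, reference-normalised).
#' @export
qpcr_relative_expression <- function(data, reference = "18S") {
  stopifnot(all(c("sample", "gene", "condition", "ct") %in% names(data)))
  if (!reference %in% data$gene) {
    stop("reference gene '", reference, "' not in data", call. = FALSE)
  }
  means <- data |>
    dplyr::summarise(ct = mean(.data$ct),
                     .by = c("sample", "gene", "condition"))
  ref <- means |>
    dplyr::filter(.data$gene == reference) |>
    dplyr::select("sample", "condition", ref_ct = "ct")
  means |>
    dplyr::filter(.data$gene != reference) |>
    dplyr::left_join(ref, by = c("sample", "condition")) |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("ct", "ref_ct")) |>
    dplyr::mutate(relative_expression = ddct(.data$ct_stress,
                                             .data$ref_ct_stress,
                                             .data$ct_control,
                                             .data$ref_ct_control)) |>
    dplyr::select("sample", "gene", "relative_expression")
}

#' Sign of association between miRNA and target relative levels
#'
#' Pearson correlation of log2 relative levels across paired conditions;
#' a cleaved target is expected to anti-correlate with its miRNA.
#'
#' @param mirna_levels,target_levels Positive relative-expression values
#'   paired across at least three conditions.
#' @return Tibble `estimate`, `sign`, `p_value`, `n`, `degenerate` (TRUE
#'   when either series is constant, in which case the correlation is
#'   undefined and `estimate` is `NA`).
#' @export
mirna_target_concordance <- function(mirna_levels, target_levels) {
  stopifnot(length(mirna_levels) == length(target_levels),
            all(mirna_levels > 0), all(target_levels > 0))
  if (length(mirna_levels) < 3) {
    stop("need at least 3 paired conditions", call. = FALSE)
  }
  lm <- log2(mirna_levels)
  lt <- log2(target_levels)
  if (stats::sd(lm) == 0 || stats::sd(lt) == 0) {
    return(tibble::tibble(estimate = NA_real_, sign = NA_integer_,
                          p_value = NA_real_, n = length(lm),
                          degenerate = TRUE))
  }
  ct <- stats::cor.test(lm, lt, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 sign = as.integer(sign(ct$estimate)),
                 p_value = ct$p.value, n = length(lm), degenerate = FALSE)
}
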