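# TPM normalisation and differential-expression screening for unreplicated
# count libraries: the exact Poisson test of Audic & Claverie, a 2x2
# Pearson chi-square alternative, Benjamini-Hochberg FDR control, and the
# p < 0.01 / FDR < 0.01 / fold >= 2 screen.

#' Tags-per-million normalisation
#'
#' `TPM = mapped reads / clean library total x 1e6`. Values are returned
#' unrounded; table emitters round to two decimals for display.
#'
#' @param mapped_reads Reads mapped to the feature.
#' @param clean_total Clean-read total of the library (must be positive).
#' @return Numeric TPM values.
#' @export
tpm <- function(mapped_reads, clean_total) {
  if (any(clean_total <= 0)) {
    stop("clean_total must be positive", call. = FALSE)
  }
  mapped_reads / clean_total * 1e6
}

#' Substitute the pseudocount for zero-count TPM values
#'
#' A feature with zero reads in a library gets TPM 0.01 by convention, so
#' log ratios stay defined. The substitution is driven by the underlying
#' count, not by the TPM value.
#'
#' @param tpm_value TPM values.
#' @param count Underlying read counts.
#' @param pseudocount Replacement value (default 0.01).
#' @return TPM values with zero-count entries replaced by `pseudocount`.
#' @export
apply_pseudocount <- function(tpm_value, count, pseudocount = 0.01) {
  stopifnot(all(tpm_value >= 0))
  ifelse(count == 0, pseudocount, tpm_value)
}

#' Log2 expression ratio
#'
#' @param stress,control TPM values after pseudocount substitution (both
#'   must be positive).
#' @return `log2(stress / control)`, unrounded.
#' @export
log2_ratio <- function(stress, control) {
  if (any(stress <= 0) || any(control <= 0)) {
    stop("log2_ratio needs positive TPM values; apply the pseudocount first",
         call. = FALSE)
  }
  log2(stress / control)
}

# log P(Y = y' | x) for the Audic-Claverie posterior predictive with
# library-size ratio f = N2/N1:
#   p(y'|x) = f^y' (x+y')! / (x! y'! (1+f)^(x+y'+1))
ac_log_pmf <- function(yp, x, f) {
  yp * log(f) + lgamma(x + yp + 1) - lgamma(x + 1) - lgamma(yp + 1) -
    (x + yp + 1) * log1p(f)
}

#' Exact Poisson (Audic-Claverie) test for two count libraries
#'
#' Compares a feature's count `x` in a library of total `n1` with its count
#' `y` in a library of total `n2` under Poisson sampling. The conditional
#' distribution of `y` given `x` is summed term by term in log space; the
#' two-sided p-value doubles the smaller tail (point included in both) and
#' is capped at 1.
#'
#' @param x,y Feature counts in the two libraries.
#' @param n1,n2 Library totals.
#' @return Numeric vector of two-sided p-values.
#' @export
ac_test <- function(x, n1, y, n2) {
  if (any(c(x, y) < 0) || any(c(n1, n2) <= 0)) {
    stop("counts must be nonnegative and totals positive", call. = FALSE)
  }
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  n1 <- rep_len(n1, n)
  n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    f <- n2[i] / n1[i]
    lower <- min(sum(exp(ac_log_pmf(0:y[i], x[i], f))), 1)
    # upper tail summed directly past the distribution's bulk, so tiny
    # p-values are not lost to cancellation against 1
    m <- (x[i] + 1) * f
    sd <- sqrt((x[i] + 1) * f * (1 + f))
    hi <- ceiling(max(y[i], m + 20 * sd)) + 50
    upper <- min(sum(exp(ac_log_pmf(y[i]:hi, x[i], f))), 1)
    max(min(1, 2 * min(lower, upper)), 1e-300)
  }, 0)
}

#' Pearson chi-square test on a 2x2 library table
#'
#' Tests homogeneity of a feature's proportion between two libraries using
#' the table `[[x, n1 - x], [y, n2 - y]]`, 1 df, no continuity correction.
#' Degenerate tables (an all-zero margin) return p = 1 with a flag.
#'
#' @inheritParams ac_test
#' @return Tibble `statistic`, `p_value`, `degenerate`.
#' @export
chisq_test2 <- function(x, n1, y, n2) {
  if (any(c(x, y) < 0) || any(c(n1, n2) <= 0)) {
    stop("counts must be nonnegative and totals positive", call. = FALSE)
  }
  a <- x
  b <- n1 - x
  c <- y
  d <- n2 - y
  n <- n1 + n2
  degenerate <- (a + c) == 0 | (b + d) == 0
  stat <- ifelse(degenerate, 0,
                 n * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)))
  p <- ifelse(degenerate, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  tibble::tibble(statistic = stat, p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()].
#'
#' @param p P-values in (0, 1].
#' @return Adjusted q-values (same order as input).
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Screening thresholds for differential expression
#'
#' @param p_threshold,fdr_threshold,fold_threshold Significance and fold
#'   cutoffs (defaults 0.01, 0.01 and 2).
#' @param log2_threshold Comparative-classification cutoff on |log2 ratio|.
#' @param pseudocount Zero-count TPM replacement.
#' @return Named list of thresholds.
#' @export
screen_criteria <- function(p_threshold = 0.01, fdr_threshold = 0.01,
                            fold_threshold = 2, log2_threshold = 1,
                            pseudocount = 0.01) {
  stopifnot(p_threshold > 0, fdr_threshold > 0, fold_threshold > 0,
            log2_threshold > 0, pseudocount > 0)
  list(p_threshold = p_threshold, fdr_threshold = fdr_threshold,
       fold_threshold = fold_threshold, log2_threshold = log2_threshold,
       pseudocount = pseudocount)
}

#' Differential-expression tests for both genotype contrasts
#'
#' Runs the chosen test per miRNA for stress vs control within each
#' genotype (T1/C1 and T2/C2), computes TPM with pseudocount substitution,
#' log2 ratios and fold changes, and adjusts p-values per contrast with
#' Benjamini-Hochberg.
#'
#' @param counts Tibble with `mirna_id` and count columns `c1`, `t1`, `c2`,
#'   `t2`.
#' @param clean_totals Named vector of library clean-read totals
#'   (`c1`, `t1`, `c2`, `t2`), the TPM denominators and test totals.
#' @param test `"poisson"` (exact Audic-Claverie, the default) or
#'   `"chisq"`.
#' @param criteria [screen_criteria()] thresholds.
#' @return A `mir_de` object; `tidy()` returns the per-contrast result
#'   table, `glance()` a one-row summary, and [screen_de()] the screened
#'   hits.
#' @export
diff_expression <- function(counts, clean_totals, test = c("poisson", "chisq"),
                            criteria = screen_criteria()) {
  test <- match.arg(test)
  stopifnot(all(c("mirna_id", LIBRARIES) %in%
                  c(names(counts), "mirna_id")),
            all(LIBRARIES %in% names(clean_totals)))

  one_contrast <- function(genotype, ctl, str) {
    x <- counts[[ctl]]
    y <- counts[[str]]
    n1 <- clean_totals[[ctl]]
    n2 <- clean_totals[[str]]
    p <- if (test == "poisson") {
      ac_test(x, n1, y, n2)
    } else {
      chisq_test2(x, n1, y, n2)$p_value
    }
    tpm_c <- apply_pseudocount(tpm(x, n1), x, criteria$pseudocount)
    tpm_t <- apply_pseudocount(tpm(y, n2), y, criteria$pseudocount)
    ratio <- tpm_t / tpm_c
    tibble::tibble(
      mirna_id = counts$mirna_id, genotype = genotype,
      x = x, y = y, n1 = n1, n2 = n2,
      tpm_control = tpm_c, tpm_stress = tpm_t,
      sub_control = x == 0, sub_stress = y == 0,
      log2_ratio = log2_ratio(tpm_t, tpm_c),
      fold_change = pmax(ratio, 1 / ratio),
      p_value = p,
      q_value = bh_fdr(p)
    )
  }
  results <- dplyr::bind_rows(one_contrast("genotype1", "c1", "t1"),
                              one_contrast("genotype2", "c2", "t2"))
  results$significant <- results$p_value < criteria$p_threshold &
    results$q_value < criteria$fdr_threshold &
    results$fold_change >= criteria$fold_threshold
  structure(list(results = results, criteria = criteria, test = test,
                 clean_totals = clean_totals),
            class = "mir_de")
}

#' Screen differential-expression results
#'
#' Keeps miRNA/contrast pairs with `p < p_threshold`, `q < fdr_threshold`
#' and fold change (larger of ratio and inverse ratio) at least
#' `fold_threshold`.
#'
#' @param de A `mir_de` object from [diff_expression()] or its tidy result
#'   table.
#' @param criteria Optional [screen_criteria()] override.
#' @return Tibble of screened rows.
#' @export
screen_de <- function(de, criteria = NULL) {
  results <- if (inherits(de, "mir_de")) de$results else de
  criteria <- criteria %||%
    (if (inherits(de, "mir_de")) de$criteria else screen_criteria())
  dplyr::filter(results,
                .data$p_value < criteria$p_threshold,
                .data$q_value < criteria$fdr_threshold,
                .data$fold_change >= criteria$fold_threshold)
}

#' @export
print.mir_de <- function(x, ...) {
  hits <- screen_de(x)
  cat("Differential expression (", x$test, " test): ",
      length(unique(x$results$mirna_id)), " miRNAs x 2 contrasts; ",
      nrow(hits), " significant calls\n", sep = "")
  invisible(x)
}

#' @rdname diff_expression
#' @param x A `mir_de` object.
#' @param ... Unused.
#' @method tidy mir_de
#' @export
tidy.mir_de <- function(x, ...) x$results

#' @rdname diff_expression
#' @method glance mir_de
#' @export
glance.mir_de <- function(x, ...) {
  hits <- screen_de(x)
  tibble::tibble(
    n_mirnas = length(unique(x$results$mirna_id)),
    n_tests = nrow(x$results),
    n_significant = nrow(hits),
    n_significant_g1 = sum(hits$genotype == "genotype1"),
    n_significant_g2 = sum(hits$genotype == "genotype2"),
    test = x$test
  )
}

#' Volcano-style plot of a differential-expression result
#'
#' @param object A `mir_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mir_de
#' @export
autoplot.mir_de <- function(object, ...) {
  dat <- object$results
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2_ratio,
                                    -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2(stress / control)", y = "-log10 p",
                  colour = "screened") +
    ggplot2::theme_minimal()
}
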