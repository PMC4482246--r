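# Control-genotype allele frequency and Hardy-Weinberg screening.

.check_triple <- function(counts) {
  if (length(counts) != 3 || any(!is.finite(counts)) || any(counts < 0)) {
    stop("genotype counts must be three non-negative numbers ",
         "(ref-hom, het, var-hom)", call. = FALSE)
  }
  if (sum(counts) == 0) stop("genotype counts sum to zero", call. = FALSE)
  as.numeric(counts)
}

#' Variant-allele frequency of a genotype triple
#'
#' Frequency of the variant allele, `(het + 2 * var_hom) / (2 * n)`. The
#' value is the risk-allele frequency and is deliberately not folded to the
#' minor allele, so it can exceed 0.5.
#'
#' @param counts Genotype counts `(ref_hom, het, var_hom)`.
#' @return Frequency in `[0, 1]`.
#' @export
#' @examples
#' variant_allele_freq(c(101, 166, 115))  # 0.518
variant_allele_freq <- function(counts) {
  counts <- .check_triple(counts)
  unname((counts[2] + 2 * counts[3]) / (2 * sum(counts)))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Asymptotic chi-square goodness-of-fit test of a genotype triple against
#' the Hardy-Weinberg proportions `((1-p)^2, 2p(1-p), p^2)` with `p`
#' estimated from the same counts. One degree of freedom (three classes,
#' one estimated parameter); no continuity correction. A monomorphic sample
#' (`p` of 0 or 1) yields `chi2 = 0`, `p_value = 1` and is flagged.
#'
#' @param counts Genotype counts `(ref_hom, het, var_hom)`.
#' @param alpha Significance level for the `in_equilibrium` flag.
#' @return An object of class `hwe_result`: list with `chi2`, `p_value`,
#'   `variant_allele_freq`, `in_equilibrium`, `monomorphic`.
#' @export
#' @examples
#' hwe_test(c(101, 166, 115))$p_value  # about 0.011
hwe_test <- function(counts, alpha = 0.05) {
  counts <- .check_triple(counts)
  n <- sum(counts)
  p <- variant_allele_freq(counts)
  if (p == 0 || p == 1) {
    res <- list(chi2 = 0, p_value = 1, variant_allele_freq = p,
                in_equilibrium = TRUE, monomorphic = TRUE)
  } else {
    expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((counts - expected)^2 / expected)
    p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    res <- list(chi2 = chi2, p_value = p_value, variant_allele_freq = p,
                in_equilibrium = p_value >= alpha, monomorphic = FALSE)
  }
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi2 = %.4f, p = %.4g, variant allele freq = %.4f%s\n",
              x$chi2, x$p_value, x$variant_allele_freq,
              if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}

#' Screen a study table for Hardy-Weinberg deviation in controls
#'
#' Tests every study's control genotypes for HWE deviation. With
#' `policy = "flag"` (the default) all studies are kept and deviating ones
#' are only annotated; `policy = "exclude"` drops studies whose control HWE
#' p-value falls below `alpha`. Flagging is the default because published
#' pooled analyses routinely retain borderline studies even when an HWE
#' inclusion criterion is stated.
#'
#' @param table A `study_table`.
#' @param policy `"flag"` or `"exclude"`.
#' @param alpha HWE significance level, in (0, 1).
#' @return List with `table` (the kept `study_table`) and `report`, a data
#'   frame of per-study `study_id`, `maf`, `chi2`, `p_value`, `flagged`.
#' @export
#' @examples
#' scr <- hwe_screen(bundled_fixture("rs2294008"))
#' scr$report[scr$report$flagged, "study_id"]
hwe_screen <- function(table, policy = c("flag", "exclude"), alpha = 0.05) {
  stopifnot(inherits(table, "study_table"))
  policy <- match.arg(policy)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  tests <- lapply(seq_len(nrow(table)), function(i) {
    hwe_test(as.numeric(table[i, c("ctrl_ref_hom", "ctrl_het", "ctrl_var_hom")]),
             alpha = alpha)
  })
  report <- data.frame(
    study_id = table$study_id,
    maf = vapply(tests, `[[`, numeric(1), "variant_allele_freq"),
    chi2 = vapply(tests, `[[`, numeric(1), "chi2"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    flagged = !vapply(tests, `[[`, logical(1), "in_equilibrium"),
    stringsAsFactors = FALSE
  )
  kept <- table
  if (policy == "exclude") {
    keep <- !report$flagged
    if (!any(keep)) {
      stop("HWE exclusion at alpha = ", alpha, " removes every study",
           call. = FALSE)
    }
    kept <- as_study_table(as.data.frame(table)[keep, , drop = FALSE])
  }
  list(table = kept, report = report)
}

#' Write an HWE screening report as TSV
#'
#' @param report The `report` element of [hwe_screen()].
#' @param path Output path.
#' @export
write_hwe_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
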