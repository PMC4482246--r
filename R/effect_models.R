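# Genetic-model contrasts and crude per-study odds ratios.

# z for 95% limits; kept at the conventional two-digit value so printed
# intervals line up with the epidemiological literature this package mirrors.
.z95 <- 1.96

#' The five genetic-model contrasts
#'
#' Names of the genotype collapsing rules supported throughout the package:
#' `homozygous` (variant-homozygote vs reference-homozygote), `heterozygous`
#' (heterozygote vs reference-homozygote), `recessive` (variant-homozygote
#' vs carriers of the reference allele), `dominant` (carriers of the variant
#' allele vs reference-homozygote) and `allele` (variant vs reference allele
#' counts, persons doubled to alleles).
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() {
  c("homozygous", "heterozygous", "recessive", "dominant", "allele")
}

#' Collapse one study's genotype counts into a 2x2 contrast
#'
#' Builds the exposure-by-status table `(a, b, c, d)` = (exposed cases,
#' unexposed cases, exposed controls, unexposed controls) for a genetic
#' model. The homozygous and heterozygous contrasts drop the third genotype
#' class; recessive and dominant merge it; the allele contrast counts
#' alleles, so its margins are twice the person totals.
#'
#' @param record One row of a `study_table` (or any list with the six count
#'   fields).
#' @param model One of [genetic_models()].
#' @return Named numeric vector `c(a, b, c, d)` of class `two_by_two`.
#' @export
#' @examples
#' rec <- list(case_ref_hom = 17, case_het = 64, case_var_hom = 49,
#'             ctrl_ref_hom = 30, ctrl_het = 63, ctrl_var_hom = 32)
#' build_contrast(rec, "dominant")  # 113 17 95 30
build_contrast <- function(record, model = genetic_models()) {
  model <- match.arg(model)
  cr <- as.numeric(record[["case_ref_hom"]])
  ch <- as.numeric(record[["case_het"]])
  cv <- as.numeric(record[["case_var_hom"]])
  kr <- as.numeric(record[["ctrl_ref_hom"]])
  kh <- as.numeric(record[["ctrl_het"]])
  kv <- as.numeric(record[["ctrl_var_hom"]])
  tab <- switch(model,
    homozygous   = c(a = cv, b = cr, c = kv, d = kr),
    heterozygous = c(a = ch, b = cr, c = kh, d = kr),
    recessive    = c(a = cv, b = cr + ch, c = kv, d = kr + kh),
    dominant     = c(a = ch + cv, b = cr, c = kh + kv, d = kr),
    allele       = c(a = 2 * cv + ch, b = 2 * cr + ch,
                     c = 2 * kv + kh, d = 2 * kr + kh)
  )
  class(tab) <- "two_by_two"
  tab
}

#' Crude odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `ad / bc` of a 2x2 table with the Woolf
#' (log-normal) standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and 95% limits
#' `exp(log OR -/+ 1.96 se)`. If any cell is zero the Haldane-Anscombe
#' continuity `correction` is added to all four cells first; the correction
#' is never applied to tables without zero cells.
#'
#' @param table A `two_by_two` (or named vector with `a`, `b`, `c`, `d`).
#' @param correction Amount added to every cell when a zero cell occurs
#'   (default 0.5). With `correction = 0` a zero row entry leaves the effect
#'   undefined and is an error.
#' @param study_id Optional study label carried into the estimate.
#' @param model Optional genetic-model label carried into the estimate.
#' @return One-row data frame of class `effect_estimate`: `study_id`,
#'   `model`, `a`..`d`, `log_or`, `se`, `or`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @export
#' @examples
#' odds_ratio(c(a = 49, b = 17, c = 32, d = 30))  # OR 2.70 (1.29-5.68)
odds_ratio <- function(table, correction = 0.5, study_id = NA_character_,
                       model = NA_character_) {
  x <- as.numeric(table[c("a", "b", "c", "d")])
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("2x2 cells must be non-negative numbers", call. = FALSE)
  }
  if (!is.numeric(correction) || correction < 0) {
    stop("correction must be >= 0", call. = FALSE)
  }
  corrected <- any(x == 0)
  if (corrected) x <- x + correction
  if (any(x == 0)) {
    stop("undefined effect: zero cell(s) remain with correction = 0",
         if (!is.na(study_id)) paste0(" [study ", study_id, "]") else "",
         call. = FALSE)
  }
  log_or <- log(x[1]) + log(x[4]) - log(x[2]) - log(x[3])
  se <- sqrt(sum(1 / x))
  out <- data.frame(
    study_id = study_id, model = model,
    a = x[1], b = x[2], c = x[3], d = x[4],
    log_or = log_or, se = se, or = exp(log_or),
    ci_low = exp(log_or - .z95 * se), ci_high = exp(log_or + .z95 * se),
    corrected = corrected, stringsAsFactors = FALSE
  )
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Per-study odds ratios for a whole table under one genetic model
#'
#' @param table A `study_table`.
#' @param model One of [genetic_models()].
#' @param correction Zero-cell continuity correction passed to
#'   [odds_ratio()].
#' @return A data frame of class `effect_estimates` (one row per study,
#'   input order preserved) with the columns of [odds_ratio()].
#' @export
#' @examples
#' est <- estimate_all(bundled_fixture("rs2294008"), "dominant")
#' est[est$study_id == "sun2014_usa_gastric", c("or", "ci_low", "ci_high")]
estimate_all <- function(table, model = genetic_models(), correction = 0.5) {
  stopifnot(inherits(table, "study_table"))
  model <- match.arg(model)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    odds_ratio(build_contrast(table[i, ], model), correction = correction,
               study_id = table$study_id[i], model = model)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Write per-study effect estimates as TSV
#'
#' @param estimates An `effect_estimates` data frame.
#' @param path Output path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
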