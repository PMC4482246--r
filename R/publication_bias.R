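# Small-study / publication-bias diagnostics: Egger regression, Begg rank
# correlation, funnel-plot data.

#' Egger's regression asymmetry test
#'
#' Classic (unweighted) form: ordinary least squares of the standard-normal
#' deviate `log_or / se` on precision `1 / se`; the intercept measures
#' funnel asymmetry and is tested against zero with a two-sided t test on
#' `k - 2` degrees of freedom.
#'
#' @param estimates Data frame with `log_or` and `se` columns, k >= 3 rows.
#' @return Object of class `egger_result`: `intercept`, `intercept_se`,
#'   `t_stat`, `p_value`, `slope`, `k`.
#' @export
#' @examples
#' est <- estimate_all(bundled_fixture("rs2294008"), "dominant")
#' egger_test(est)$p_value  # about 0.186
egger_test <- function(estimates) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 3) stop("Egger's test requires at least 3 studies", call. = FALSE)
  snd <- estimates$log_or / estimates$se
  prec <- 1 / estimates$se
  fit <- stats::lm(snd ~ prec)
  coefs <- summary(fit)$coefficients
  res <- list(
    intercept = unname(coefs["(Intercept)", "Estimate"]),
    intercept_se = unname(coefs["(Intercept)", "Std. Error"]),
    t_stat = unname(coefs["(Intercept)", "t value"]),
    p_value = unname(coefs["(Intercept)", "Pr(>|t|)"]),
    slope = unname(coefs["prec", "Estimate"]),
    k = k
  )
  class(res) <- "egger_result"
  res
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf(
    "Egger's test (k = %d): intercept %.3f (se %.3f), t = %.3f, p = %.4g\n",
    x$k, x$intercept, x$intercept_se, x$t_stat, x$p_value))
  invisible(x)
}

#' Begg and Mazumdar's rank correlation test
#'
#' Kendall rank correlation (tau-b, so ties are handled) between the
#' variance-standardized deviations from the fixed-effects pooled log odds
#' ratio, `(y_i - y_fixed) / sqrt(v_i - 1/sum(w))`, and the sampling
#' variances `v_i`. The p-value uses the normal approximation to the
#' Kendall score with a 0.5 continuity correction.
#'
#' @param estimates Data frame with `log_or` and `se` columns, k >= 3 rows.
#' @return Object of class `begg_result`: `kendall_tau`, `score` (P minus Q
#'   count), `z_stat`, `p_value`, `k`.
#' @export
begg_test <- function(estimates) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 3) stop("Begg's test requires at least 3 studies", call. = FALSE)
  y <- estimates$log_or
  v <- estimates$se^2
  w <- 1 / v
  y_fixed <- sum(w * y) / sum(w)
  v_star <- v - 1 / sum(w)
  t_i <- (y - y_fixed) / sqrt(v_star)
  tau <- stats::cor(t_i, v, method = "kendall")
  # Kendall score: concordant minus discordant pairs
  score <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      score <- score + sign(t_i[j] - t_i[i]) * sign(v[j] - v[i])
    }
  }
  sd_score <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  z <- if (score == 0) 0 else (abs(score) - 1) / sd_score
  res <- list(
    kendall_tau = tau, score = score, z_stat = z,
    p_value = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
    k = k
  )
  class(res) <- "begg_result"
  res
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("Begg's test (k = %d): Kendall tau = %.3f, z = %.3f, p = %.4g\n",
              x$k, x$kendall_tau, x$z_stat, x$p_value))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' @param estimates Data frame with `study_id`, `log_or`, `se` columns.
#' @return Data frame with one row per study: `study_id`, `effect`
#'   (log odds ratio), `se`, `precision` (`1/se`).
#' @export
funnel_data <- function(estimates) {
  estimates <- .as_estimates(estimates)
  data.frame(
    study_id = if ("study_id" %in% names(estimates)) estimates$study_id
               else as.character(seq_len(nrow(estimates))),
    effect = estimates$log_or,
    se = estimates$se,
    precision = 1 / estimates$se,
    stringsAsFactors = FALSE
  )
}

#' Publication-bias report for one set of estimates
#'
#' @param estimates An [estimate_all()] result with k >= 3 rows.
#' @return List with `egger` ([egger_test()]), `begg` ([begg_test()]) and
#'   `funnel` ([funnel_data()]).
#' @export
bias_report <- function(estimates) {
  list(egger = egger_test(estimates), begg = begg_test(estimates),
       funnel = funnel_data(estimates))
}
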