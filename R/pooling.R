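# Fixed-effects (Mantel-Haenszel, inverse-variance) and random-effects
# (DerSimonian-Laird) pooling of per-study log odds ratios, with Cochran's Q.

.as_estimates <- function(estimates) {
  if (!is.data.frame(estimates) ||
      !all(c("log_or", "se") %in% names(estimates))) {
    stop("estimates must be a data frame with 'log_or' and 'se' columns",
         call. = FALSE)
  }
  if (nrow(estimates) < 1) stop("no estimates to pool", call. = FALSE)
  if (any(estimates$se <= 0)) stop("standard errors must be > 0", call. = FALSE)
  estimates
}

#' Cochran's Q heterogeneity test and DerSimonian-Laird tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of per-study
#' log odds ratios from their fixed-effects mean; under homogeneity it is
#' chi-square with `k - 1` degrees of freedom. The between-study variance is
#' the DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))`, and
#' `I2 = max(0, (Q - df) / Q)` describes the heterogeneous fraction.
#'
#' @param estimates Data frame with `log_or` and `se` columns (k >= 2 rows).
#' @return Object of class `heterogeneity_result`: `q`, `df`, `p_het`,
#'   `tau2`, `i2`, `k`.
#' @export
cochran_q <- function(estimates) {
  estimates <- .as_estimates(estimates)
  k <- nrow(estimates)
  if (k < 2) stop("heterogeneity is undefined for fewer than 2 studies",
                  call. = FALSE)
  y <- estimates$log_or
  w <- 1 / estimates$se^2
  y_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fixed)^2)
  df <- k - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  res <- list(
    q = q, df = df,
    p_het = stats::pchisq(q, df = df, lower.tail = FALSE),
    tau2 = tau2,
    i2 = if (q > 0) max(0, (q - df) / q) else 0,
    k = k
  )
  class(res) <- "heterogeneity_result"
  res
}

.new_pooled <- function(method, estimates, log_or, se, het) {
  res <- list(
    model = if ("model" %in% names(estimates)) estimates$model[1] else NA,
    method = method,
    k = nrow(estimates),
    pooled_or = exp(log_or),
    ci_low = exp(log_or - .z95 * se),
    ci_high = exp(log_or + .z95 * se),
    log_or = log_or,
    se = se,
    het = het,
    components = estimates
  )
  class(res) <- "pooled_result"
  res
}

# Q/tau2 for any k >= 1 (k = 1: degenerate, no heterogeneity).
.het_or_null <- function(estimates) {
  if (nrow(estimates) >= 2) {
    cochran_q(estimates)
  } else {
    res <- list(q = 0, df = 0, p_het = NA_real_, tau2 = 0, i2 = 0, k = 1)
    class(res) <- "heterogeneity_result"
    res
  }
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' Pools 2x2 tables as `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; the
#' confidence interval uses the Robins-Breslow-Greenland variance of the
#' pooled log odds ratio. Cell counts are used as given (no zero-cell
#' correction); a single study reduces exactly to its crude odds ratio.
#'
#' @param tables Data frame (or matrix) with columns `a`, `b`, `c`, `d`,
#'   one row per study; typically the columns of an [estimate_all()] result.
#' @return A `pooled_result` with `method = "MH_fixed"`.
#' @export
pool_mh <- function(tables) {
  tab <- as.data.frame(tables)
  if (!all(c("a", "b", "c", "d") %in% names(tab))) {
    stop("tables must have columns a, b, c, d", call. = FALSE)
  }
  if (nrow(tab) < 1) stop("no tables to pool", call. = FALSE)
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  n <- a + b + cc + d
  if (any(n <= 0)) stop("every 2x2 table must have positive total", call. = FALSE)
  R_i <- a * d / n
  S_i <- b * cc / n
  R <- sum(R_i); S <- sum(S_i)
  if (S == 0) stop("undefined Mantel-Haenszel effect: sum(b*c/n) is zero",
                   call. = FALSE)
  log_or <- log(R / S)
  # Robins-Breslow-Greenland variance
  P_i <- (a + d) / n
  Q_i <- (b + cc) / n
  v <- sum(P_i * R_i) / (2 * R^2) +
       sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
       sum(Q_i * S_i) / (2 * S^2)
  est <- if (all(c("log_or", "se") %in% names(tab))) tab else {
    do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      odds_ratio(c(a = a[i], b = b[i], c = cc[i], d = d[i]),
                 study_id = if ("study_id" %in% names(tab)) tab$study_id[i]
                            else as.character(i),
                 model = if ("model" %in% names(tab)) tab$model[1]
                         else NA_character_)
    }))
  }
  .new_pooled("MH_fixed", est, log_or, sqrt(v), .het_or_null(est))
}

#' Inverse-variance fixed-effects pooling
#'
#' Weighted mean of per-study log odds ratios with weights `1 / se^2`;
#' pooled standard error `1 / sqrt(sum(w))`.
#'
#' @param estimates Data frame with `log_or` and `se` columns.
#' @return A `pooled_result` with `method = "IV_fixed"`.
#' @export
pool_iv_fixed <- function(estimates) {
  estimates <- .as_estimates(estimates)
  w <- 1 / estimates$se^2
  log_or <- sum(w * estimates$log_or) / sum(w)
  .new_pooled("IV_fixed", estimates, log_or, 1 / sqrt(sum(w)),
              .het_or_null(estimates))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Weighted mean of per-study log odds ratios with weights
#' `1 / (se^2 + tau2)`, where `tau2` is the DerSimonian-Laird moment
#' estimator from [cochran_q()]. When `tau2 = 0` the result coincides
#' exactly with [pool_iv_fixed()].
#'
#' @param estimates Data frame with `log_or` and `se` columns.
#' @return A `pooled_result` with `method = "DL_random"`.
#' @export
pool_dl_random <- function(estimates) {
  estimates <- .as_estimates(estimates)
  het <- .het_or_null(estimates)
  w <- 1 / (estimates$se^2 + het$tau2)
  log_or <- sum(w * estimates$log_or) / sum(w)
  .new_pooled("DL_random", estimates, log_or, 1 / sqrt(sum(w)), het)
}

#' Pool per-study estimates under a model-selection policy
#'
#' `policy = "auto"` follows the conventional rule: DerSimonian-Laird
#' random effects when the heterogeneity p-value is below `het_alpha`
#' (default 0.10), Mantel-Haenszel fixed effects otherwise.
#' `"force_random"` always uses DerSimonian-Laird — the configuration that
#' reproduces the bundled PSCA results, whose source analysis applied the
#' random-effects model throughout. `"force_fixed"` always uses
#' Mantel-Haenszel. A single study is returned unchanged under any policy.
#'
#' @param estimates An [estimate_all()] result (needs `a`..`d` columns for
#'   the Mantel-Haenszel branch).
#' @param policy `"auto"`, `"force_random"` or `"force_fixed"`.
#' @param het_alpha Heterogeneity threshold for the auto rule.
#' @return A `pooled_result`; `method` records the choice taken.
#' @export
#' @examples
#' est <- estimate_all(bundled_fixture("rs2294008"), "dominant")
#' pool(est, policy = "force_random")  # OR 1.34 (1.21-1.48)
pool <- function(estimates, policy = c("auto", "force_random", "force_fixed"),
                 het_alpha = 0.10) {
  policy <- match.arg(policy)
  estimates <- .as_estimates(estimates)
  if (nrow(estimates) == 1) {
    return(.new_pooled("single_study", estimates, estimates$log_or[1],
                       estimates$se[1], .het_or_null(estimates)))
  }
  switch(policy,
    force_random = pool_dl_random(estimates),
    force_fixed = pool_mh(estimates),
    auto = {
      het <- cochran_q(estimates)
      if (het$p_het < het_alpha) pool_dl_random(estimates)
      else pool_mh(estimates)
    }
  )
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled OR (%s, %s, k = %d): %.2f (95%% CI %.2f-%.2f)\n",
              if (is.na(x$model)) "log-OR" else x$model, x$method, x$k,
              x$pooled_or, x$ci_low, x$ci_high))
  if (x$k > 1) {
    cat(sprintf("  Q = %.3f on %d df, p_het = %.4g, tau2 = %.4f, I2 = %.1f%%\n",
                x$het$q, x$het$df, x$het$p_het, x$het$tau2, 100 * x$het$i2))
  }
  invisible(x)
}

#' Flatten a pooled result to a one-row data frame
#'
#' @param pooled A `pooled_result`.
#' @return One-row data frame with model, method, k, OR, CI and
#'   heterogeneity columns.
#' @export
pooled_summary_row <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_result"))
  data.frame(
    model = pooled$model, method = pooled$method, k = pooled$k,
    or = pooled$pooled_or, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    log_or = pooled$log_or, se = pooled$se,
    q = pooled$het$q, df = pooled$het$df, p_het = pooled$het$p_het,
    tau2 = pooled$het$tau2, i2 = pooled$het$i2,
    stringsAsFactors = FALSE
  )
}
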