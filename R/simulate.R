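# Genotype-count simulator with known truth, for pipeline validation and
# parameter-recovery experiments.

#' Configuration for the study simulator
#'
#' The generator emulates the structure of a candidate-SNP case-control
#' meta-analysis: control genotypes in Hardy-Weinberg proportions at a
#' study-specific variant-allele frequency, case genotypes tilted by a
#' multiplicative per-allele odds ratio (rare-disease approximation), and
#' optional Normal between-study spread of the log odds ratio.
#'
#' Defaults mirror the bundled PSCA tables: arm sizes of a few hundred to a
#' few thousand subjects and control variant-allele frequencies between
#' 0.2 and 0.6.
#'
#' @param k Number of studies.
#' @param n_case_range,n_ctrl_range Integer ranges (min, max) for the arm
#'   sizes, drawn uniformly per study.
#' @param p0_range Range (within (0, 1), away from the boundaries) for the
#'   control variant-allele frequency, drawn uniformly per study.
#' @param theta True per-allele log odds ratio.
#' @param tau Between-study standard deviation of the log odds ratio
#'   (0 = homogeneous).
#' @param seed Root seed; per-study generator states are split off
#'   deterministically so study i does not depend on k.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(k, n_case_range = c(200L, 2000L),
                       n_ctrl_range = c(200L, 2000L),
                       p0_range = c(0.2, 0.6), theta = 0, tau = 0,
                       seed = 1L) {
  stopifnot(k >= 1, length(n_case_range) == 2, length(n_ctrl_range) == 2,
            length(p0_range) == 2)
  if (n_case_range[1] > n_case_range[2] || n_ctrl_range[1] > n_ctrl_range[2] ||
      n_case_range[1] < 1 || n_ctrl_range[1] < 1) {
    stop("arm-size ranges must be ordered and positive", call. = FALSE)
  }
  if (p0_range[1] <= 0 || p0_range[2] >= 1 || p0_range[1] > p0_range[2]) {
    stop("p0_range must lie strictly inside (0, 1): ",
         "boundary frequencies give monomorphic studies", call. = FALSE)
  }
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  cfg <- list(k = as.integer(k), n_case_range = as.integer(n_case_range),
              n_ctrl_range = as.integer(n_ctrl_range), p0_range = p0_range,
              theta = theta, tau = tau, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic stream split: study i always sees the same generator state
# for a given root seed, independent of k.
.study_seed <- function(seed, i) {
  (as.double(seed) + 7919 * as.double(i)) %% 2147483629
}

#' Simulate one case-control study
#'
#' Control genotype probabilities are the Hardy-Weinberg proportions at a
#' drawn allele frequency `p0`; case genotype probabilities are the control
#' probabilities times the per-genotype odds multipliers
#' `(1, exp(theta_i), exp(2 theta_i))`, renormalized, where
#' `theta_i ~ Normal(theta, tau^2)` is the study's per-allele log odds
#' ratio. Genotype counts are multinomial draws with uniformly drawn arm
#' sizes.
#'
#' @param config A [sim_config()].
#' @param i Study index (1-based); determines the split random stream.
#' @return One-row `study_table` row as a data frame (combine with
#'   [simulate_meta()] for a full validated table).
#' @export
simulate_study <- function(config, i = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.study_seed(config$seed, i))
  p0 <- stats::runif(1, config$p0_range[1], config$p0_range[2])
  theta_i <- stats::rnorm(1, config$theta, config$tau)
  draw_n <- function(rng) {
    # guard the sample(n, 1) scalar pitfall when the range is a single value
    if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
  }
  n_case <- draw_n(config$n_case_range)
  n_ctrl <- draw_n(config$n_ctrl_range)
  ctrl_p <- c((1 - p0)^2, 2 * p0 * (1 - p0), p0^2)
  case_p <- ctrl_p * exp(theta_i * (0:2))
  case_p <- case_p / sum(case_p)
  case_counts <- as.vector(stats::rmultinom(1, n_case, case_p))
  ctrl_counts <- as.vector(stats::rmultinom(1, n_ctrl, ctrl_p))
  data.frame(
    study_id = sprintf("sim_%03d", i), author = "Simulated",
    year = 2000L + (i %% 26), cancer_type = "simulated", country = "none",
    ethnicity = "mixed", control_source = "PB",
    genotyping_method = "simulated",
    case_ref_hom = case_counts[1], case_het = case_counts[2],
    case_var_hom = case_counts[3],
    ctrl_ref_hom = ctrl_counts[1], ctrl_het = ctrl_counts[2],
    ctrl_var_hom = ctrl_counts[3],
    variant = "simSNP", stringsAsFactors = FALSE
  )
}

#' Simulate a whole meta-analysis table
#'
#' @param config A [sim_config()].
#' @return A validated `study_table` of `config$k` simulated studies.
#' @export
#' @examples
#' tab <- simulate_meta(sim_config(k = 5, theta = log(1.5), seed = 42))
#' pool(estimate_all(tab, "allele"), policy = "auto")
simulate_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(seq_len(config$k), function(i) simulate_study(config, i))
  as_study_table(do.call(rbind, rows))
}

#' Parameter-recovery experiment for the pooled estimators
#'
#' Repeatedly simulates a meta-analysis, runs the allele-model pipeline
#' (per-study Woolf odds ratios, pooling under `policy`), and summarizes
#' how well the pooled estimate recovers the generating per-allele odds
#' ratio: mean pooled OR, empirical SD of pooled log-ORs, 95% CI coverage
#' of the truth, rejection rate of the null (CI excludes 1), and the mean
#' between-study variance estimate.
#'
#' @param config A [sim_config()]; its `seed` drives the whole experiment
#'   (rep r uses root seed `seed + 104729 * r`).
#' @param reps Number of replicate meta-analyses (>= 100 recommended for
#'   distributional summaries).
#' @param policy Pooling policy, see [pool()].
#' @return List: `reps`, `true_or`, `mean_pooled_or`, `mean_pooled_log_or`,
#'   `sd_pooled_log_or`, `coverage`, `reject_null_rate`, `mean_tau2`,
#'   `tau2_zero_rate`.
#' @export
recovery_experiment <- function(config, reps,
                                policy = c("auto", "force_random",
                                           "force_fixed")) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  policy <- match.arg(policy)
  true_or <- exp(config$theta)
  res <- vapply(seq_len(reps), function(r) {
    cfg_r <- config
    cfg_r$seed <- (as.double(config$seed) + 104729 * r) %% 2147483629
    tab <- simulate_meta(cfg_r)
    p <- pool(estimate_all(tab, "allele"), policy = policy)
    c(log_or = p$log_or,
      covered = as.numeric(p$ci_low <= true_or && true_or <= p$ci_high),
      rejects = as.numeric(p$ci_low > 1 || p$ci_high < 1),
      tau2 = p$het$tau2)
  }, numeric(4))
  list(
    reps = reps, true_or = true_or,
    mean_pooled_or = mean(exp(res["log_or", ])),
    mean_pooled_log_or = mean(res["log_or", ]),
    sd_pooled_log_or = stats::sd(res["log_or", ]),
    coverage = mean(res["covered", ]),
    reject_null_rate = mean(res["rejects", ]),
    mean_tau2 = mean(res["tau2", ]),
    tau2_zero_rate = mean(res["tau2", ] == 0)
  )
}
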