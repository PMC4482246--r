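# Full-pipeline reproduction run and forest-plot data export.

#' Run the complete meta-analysis pipeline and write a report bundle
#'
#' Executes, for one study table, every stage of the pipeline: HWE
#' screening of control genotypes, per-study crude odds ratios and pooled
#' results for each requested genetic model, subgroup analyses, optional
#' leave-one-out sensitivity and publication-bias tests. All tables are
#' written as TSV and a machine-readable summary as JSON under `out_dir`.
#'
#' @param input Path to a study TSV (see [read_studies()]); ignored when
#'   `fixture` is given.
#' @param fixture Name of a bundled fixture (`"rs2294008"` or
#'   `"rs2976392"`) to analyse instead of `input`.
#' @param models Genetic models to run; `"all"` or a subset of
#'   [genetic_models()].
#' @param policy Pooling policy, see [pool()]. `"force_random"` (default)
#'   reproduces the bundled PSCA results.
#' @param hwe_policy,hwe_alpha HWE screening policy and level, see
#'   [hwe_screen()].
#' @param group_by Metadata fields for subgroup analyses (character
#'   vector; may be empty).
#' @param sensitivity Run leave-one-out per model?
#' @param bias Run Egger/Begg tests and funnel export per model?
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and only returns the summary.
#' @param verbose Log policy decisions and study counts to the console?
#' @return (Invisibly) the summary list also written to `summary.json`.
#' @export
#' @examples
#' \donttest{
#' run <- run_meta(fixture = "rs2294008", models = "dominant",
#'                 out_dir = NULL, verbose = FALSE)
#' run$pooled$dominant$or
#' }
run_meta <- function(input = NULL, fixture = NULL, models = "all",
                     policy = c("force_random", "auto", "force_fixed"),
                     hwe_policy = c("flag", "exclude"), hwe_alpha = 0.05,
                     group_by = c("cancer_type", "ethnicity",
                                  "control_source"),
                     sensitivity = FALSE, bias = FALSE, out_dir = NULL,
                     verbose = TRUE) {
  policy <- match.arg(policy)
  hwe_policy <- match.arg(hwe_policy)
  if (identical(models, "all")) models <- genetic_models()
  if (length(models) == 0) stop("no genetic models requested", call. = FALSE)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  table <- if (!is.null(fixture)) bundled_fixture(fixture)
           else if (!is.null(input)) read_studies(input)
           else stop("supply either 'input' or 'fixture'", call. = FALSE)
  tc <- total_counts(table)
  say("loaded %d studies of %s: %d cases, %d controls", nrow(table),
      table$variant[1], tc["cases"], tc["controls"])

  screened <- hwe_screen(table, policy = hwe_policy, alpha = hwe_alpha)
  say("HWE policy '%s' at alpha %.3g: %d kept, %d flagged", hwe_policy,
      hwe_alpha, nrow(screened$table), sum(screened$report$flagged))
  table <- screened$table

  emit <- !is.null(out_dir)
  if (emit && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path_of <- function(...) file.path(out_dir, sprintf(...))
  if (emit) write_hwe_report(screened$report, path_of("hwe_report.tsv"))

  summary <- list(
    variant = table$variant[1], n_studies = nrow(table),
    total_cases = unname(tc["cases"]), total_controls = unname(tc["controls"]),
    policy = policy, hwe_policy = hwe_policy,
    pooled = list(), subgroups = list(), sensitivity = list(), bias = list()
  )

  for (m in models) {
    est <- estimate_all(table, m)
    pooled <- pool(est, policy = policy)
    say("%-12s pooled by %s: OR %.2f (%.2f-%.2f), p_het %.4g", m,
        pooled$method, pooled$pooled_or, pooled$ci_low, pooled$ci_high,
        pooled$het$p_het)
    summary$pooled[[m]] <- pooled_summary_row(pooled)
    if (emit) {
      write_estimates(est, path_of("estimates_%s.tsv", m))
      utils::write.table(render_forest(pooled), path_of("forest_%s.tsv", m),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    for (g in group_by) {
      rep_g <- subgroup_pool(table, g, m, policy = policy)
      summary$subgroups[[m]][[g]] <- subgroup_summary(rep_g)
      if (emit) {
        utils::write.table(subgroup_summary(rep_g),
                           path_of("subgroup_%s_%s.tsv", g, m),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    if (sensitivity && nrow(table) >= 2) {
      sens <- leave_one_out(table, m, policy = policy)
      summary$sensitivity[[m]] <- list(
        min_or = sens$min_or, max_or = sens$max_or,
        qualitative_change = sens$qualitative_change)
      if (emit) {
        utils::write.table(sens$omissions, path_of("sensitivity_%s.tsv", m),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    if (bias && nrow(table) >= 3) {
      br <- bias_report(est)
      summary$bias[[m]] <- list(
        egger = list(intercept = br$egger$intercept,
                     p_value = br$egger$p_value),
        begg = list(kendall_tau = br$begg$kendall_tau,
                    p_value = br$begg$p_value))
      if (emit) {
        utils::write.table(br$funnel, path_of("funnel_%s.tsv", m),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if (emit) {
    jsonlite::write_json(summary, path_of("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    say("report bundle written to %s", out_dir)
  }
  invisible(summary)
}

#' Forest-plot data for a pooled result
#'
#' One row per component study (label, OR, CI, relative weight) plus a
#' final summary row carrying the pooled estimate. Weights are the
#' normalized pooling weights of the method used (inverse-variance with
#' tau2 for random effects).
#'
#' @param pooled A `pooled_result`.
#' @return Data frame with columns `study_id`, `or`, `ci_low`, `ci_high`,
#'   `weight`, `is_summary`.
#' @export
render_forest <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_result"))
  est <- pooled$components
  w <- 1 / (est$se^2 + if (pooled$method == "DL_random") pooled$het$tau2 else 0)
  rows <- data.frame(
    study_id = if ("study_id" %in% names(est)) est$study_id
               else as.character(seq_len(nrow(est))),
    or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
    weight = w / sum(w), is_summary = FALSE, stringsAsFactors = FALSE
  )
  rbind(rows, data.frame(
    study_id = sprintf("pooled (%s)", pooled$method),
    or = pooled$pooled_or, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    weight = 1, is_summary = TRUE, stringsAsFactors = FALSE
  ))
}
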