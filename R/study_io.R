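#' @keywords internal
"_PACKAGE"

# Canonical column set for a study table. Genotype counts are stored in
# reference-homozygote -> heterozygote -> variant-homozygote order for both
# arms, so the orientation of every downstream contrast is unambiguous.
.study_columns <- c(
  "study_id", "author", "year", "cancer_type", "country", "ethnicity",
  "control_source", "genotyping_method",
  "case_ref_hom", "case_het", "case_var_hom",
  "ctrl_ref_hom", "ctrl_het", "ctrl_var_hom",
  "variant"
)

.count_columns <- c(
  "case_ref_hom", "case_het", "case_var_hom",
  "ctrl_ref_hom", "ctrl_het", "ctrl_var_hom"
)

#' Construct a validated study table
#'
#' A study table is a `data.frame` (class `study_table`) with one row per
#' case-control study and a fixed column set: study metadata plus the six
#' genotype counts (case and control counts for reference-homozygote,
#' heterozygote and variant-homozygote carriers).
#'
#' @param df A data frame holding the canonical columns (see
#'   [read_studies()] for the list).
#' @return The validated `study_table`.
#' @export
as_study_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.study_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, .study_columns]
  rownames(df) <- NULL
  validate_study_table(df)
  class(df) <- c("study_table", "data.frame")
  df
}

validate_study_table <- function(df) {
  if (nrow(df) == 0) stop("study table has no rows", call. = FALSE)
  for (col in .count_columns) {
    x <- df[[col]]
    bad <- !is.finite(x) | x < 0 | x != floor(x)
    if (any(bad)) {
      stop(sprintf("row %d: '%s' must be a non-negative integer (got %s)",
                   which(bad)[1], col, format(x[which(bad)[1]])),
           call. = FALSE)
    }
  }
  case_n <- rowSums(df[, c("case_ref_hom", "case_het", "case_var_hom")])
  ctrl_n <- rowSums(df[, c("ctrl_ref_hom", "ctrl_het", "ctrl_var_hom")])
  if (any(case_n == 0)) {
    stop("row ", which(case_n == 0)[1], ": case genotype counts sum to zero",
         call. = FALSE)
  }
  if (any(ctrl_n == 0)) {
    stop("row ", which(ctrl_n == 0)[1], ": control genotype counts sum to zero",
         call. = FALSE)
  }
  dup <- duplicated(df$study_id)
  if (any(dup)) {
    stop("duplicate study_id: ", df$study_id[which(dup)[1]], call. = FALSE)
  }
  if (length(unique(df$variant)) != 1) {
    stop("study table mixes variants: ",
         paste(unique(df$variant), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a study table from delimiter-separated text
#'
#' Reads one row per study. The header must name the canonical columns:
#' `study_id`, `author`, `year`, `cancer_type`, `country`, `ethnicity`,
#' `control_source`, `genotyping_method`, `case_ref_hom`, `case_het`,
#' `case_var_hom`, `ctrl_ref_hom`, `ctrl_het`, `ctrl_var_hom`, `variant`.
#' Counts must parse as non-negative integers; both arms of every study must
#' be non-empty; `study_id` must be unique and `variant` homogeneous.
#'
#' @param path Path to a UTF-8 text file.
#' @param delimiter Field delimiter; tab by default, use `","` for CSV.
#' @return A [as_study_table()] object; row order preserved.
#' @export
#' @examples
#' tab <- bundled_fixture("rs2294008")
#' tmp <- tempfile(fileext = ".tsv")
#' write_studies(tab, tmp)
#' identical(total_counts(read_studies(tmp)), total_counts(tab))
read_studies <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = delimiter, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  missing_cols <- setdiff(.study_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("year", .count_columns)) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(parsed) & !is.na(df[[col]])
    if (any(bad)) {
      stop(sprintf("row %d: '%s' is not numeric: '%s'",
                   which(bad)[1], col, df[[col]][which(bad)[1]]),
           call. = FALSE)
    }
    df[[col]] <- parsed
  }
  as_study_table(df)
}

#' Write a study table as delimiter-separated text
#'
#' @param table A `study_table`.
#' @param path Output path.
#' @param delimiter Field delimiter (tab default).
#' @export
write_studies <- function(table, path, delimiter = "\t") {
  stopifnot(inherits(table, "study_table"))
  utils::write.table(table, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled PSCA case-control fixture
#'
#' Returns the genotype counts and study metadata of the published
#' case-control studies of the two PSCA polymorphisms shipped with the
#' package: 32 studies of rs2294008 C>T (30028 cases, 38765 controls) or 14
#' studies of rs2976392 G>A (8190 cases, 7176 controls). Only raw genotype
#' counts are stored; derived quantities (allele frequencies, HWE p-values)
#' are always recomputed.
#'
#' @param variant_id `"rs2294008"` or `"rs2976392"`.
#' @return A `study_table`.
#' @export
#' @examples
#' total_counts(bundled_fixture("rs2294008"))
bundled_fixture <- function(variant_id) {
  known <- c("rs2294008", "rs2976392")
  if (!is.character(variant_id) || length(variant_id) != 1 ||
      !variant_id %in% known) {
    stop("unknown variant_id '", paste(variant_id, collapse = ","),
         "'; bundled fixtures: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(variant_id, "_studies.tsv"),
                      package = "genemeta", mustWork = TRUE)
  read_studies(path)
}

#' Total case and control counts of a study table
#'
#' @param table A `study_table`.
#' @return Named integer vector `c(cases = , controls = )`.
#' @export
total_counts <- function(table) {
  stopifnot(inherits(table, "study_table"))
  c(cases = sum(table$case_ref_hom + table$case_het + table$case_var_hom),
    controls = sum(table$ctrl_ref_hom + table$ctrl_het + table$ctrl_var_hom))
}

#' @export
print.study_table <- function(x, ...) {
  tc <- total_counts(x)
  cat(sprintf("Study table: %d studies of %s (%d cases, %d controls)\n",
              nrow(x), x$variant[1], tc["cases"], tc["controls"]))
  print.data.frame(x, ...)
  invisible(x)
}
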