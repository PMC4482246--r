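# Shared helpers: hand-built estimate frames and tiny study tables.

make_estimates <- function(log_or, se, model = "allele") {
  data.frame(study_id = sprintf("s%02d", seq_along(log_or)),
             model = model, log_or = log_or, se = se,
             or = exp(log_or), stringsAsFactors = FALSE)
}

# one-row study record as a plain list (build_contrast accepts it)
sun2014_record <- list(case_ref_hom = 17, case_het = 64, case_var_hom = 49,
                       ctrl_ref_hom = 30, ctrl_het = 63, ctrl_var_hom = 32)

# minimal valid study table with n identical studies
tiny_table <- function(n = 2, case = c(50, 60, 40), ctrl = c(70, 50, 30)) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(study_id = paste0("t", i), author = "A", year = 2000 + i,
               cancer_type = "gastric", country = "X", ethnicity = "Asian",
               control_source = "HB", genotyping_method = "Taqman",
               case_ref_hom = case[1], case_het = case[2],
               case_var_hom = case[3],
               ctrl_ref_hom = ctrl[1], ctrl_het = ctrl[2],
               ctrl_var_hom = ctrl[3],
               variant = "rsTEST", stringsAsFactors = FALSE)
  }))
  as_study_table(rows)
}
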