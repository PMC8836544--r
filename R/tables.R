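# Published incidence-by-category tables from a 629-patient external
# validation cohort, shipped so the between-category statistics can be
# recomputed without patient-level data.

#' Reference incidence-by-category tables
#'
#' Event/total counts per risk category observed when the three risk models
#' were applied to an external validation cohort of 629 trastuzumab-treated
#' women with stage I-III HER2+ breast cancer (CTRCD by the CREC
#' definition), plus the corresponding sensitivity-analysis tables: the
#' points model restricted to women aged 67 and over, the cardiac risk
#' score restricted to anthracycline recipients, and the HFA-ICOS proforma
#' in the biomarker subgroup.
#'
#' @return named list of `contingency_summary` objects:
#'   `ezaz`, `nsabp_tertiles`, `hfa_icos`, `ezaz_age67`,
#'   `nsabp_anthracycline`, `hfa_icos_biomarkers`.
#' @export
validation_cohort_tables <- function() {
  list(
    ezaz = contingency_summary(
      c("low", "medium", "high"), c(577, 45, 7), c(141, 9, 1)),
    nsabp_tertiles = contingency_summary(
      c("low", "medium", "high"), c(223, 204, 202), c(40, 50, 61)),
    hfa_icos = contingency_summary(
      c("low", "medium", "high", "very_high"),
      c(193, 404, 27, 5), c(30, 109, 10, 2)),
    ezaz_age67 = contingency_summary(
      c("low", "medium", "high"), c(45, 15, 4), c(15, 4, 1)),
    nsabp_anthracycline = contingency_summary(
      c("low", "medium", "high"), c(201, 184, 183), c(38, 47, 53)),
    hfa_icos_biomarkers = contingency_summary(
      c("low", "medium", "high"), c(40, 140, 4), c(10, 46, 1))
  )
}
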