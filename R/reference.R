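#' Post-QC case/control sizes of six public Alzheimer's disease cohorts
#'
#' Case and control counts after genotype QC, European-ancestry
#' selection and exclusion of samples with missing age or sex, for the
#' six public studies whose joint structure the synthetic generator
#' emulates: ADNI, ADNI2, GenADA, eMERGE, NIA-LOAD and Framingham.
#' Totals are 4,171 cases and 9,358 controls.  These counts are the
#' default per-study sizes of [sim_config()] and the fixed study order
#' used for meta-analysis direction strings.
#'
#' @return A data.frame with columns `study`, `n_cases`, `n_controls`.
#' @examples
#' ref <- reference_study_sizes()
#' sum(ref$n_cases)     # 4171
#' sum(ref$n_controls)  # 9358
#' @export
reference_study_sizes <- function() {
  data.frame(
    study = c("ADNI", "ADNI2", "GenADA", "eMERGE", "NIA-LOAD", "Framingham"),
    n_cases = c(350L, 53L, 779L, 632L, 2098L, 259L),
    n_controls = c(169L, 125L, 803L, 1843L, 2095L, 4323L),
    stringsAsFactors = FALSE
  )
}
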