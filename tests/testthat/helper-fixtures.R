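# tiny in-code fixtures shared across test files

# long-format series from a named list: values[[analyte]] is a vector over days
make_series <- function(days, values, treatment = "trt", replicate = "rep1") {
  purrr::map_dfr(names(values), function(an) {
    tibble::tibble(treatment = treatment, replicate = replicate,
                   day = days, analyte = an,
                   concentration_uM = values[[an]])
  })
}

# a design where a treatment and its identity-mapped control share BES status
simple_design <- function(bes = FALSE) {
  tibble::tibble(
    treatment_id = c("trt", "ctl"),
    supplement = list(c(NAG = 500), NULL),
    bes = bes,
    preincubation_days = 0L,
    control_id = c("ctl", "ctl")
  )
}

# noiseless model whose measured set covers every reaction pool (closed budget)
closed_model <- function(...) {
  fermentation_model(
    noise_sd = 0,
    measured_analytes = c("NAG", "acetate", "formate", "ethanol",
                          "CO2", "CH4", "H2", "H2O", "NH3"),
    ...
  )
}
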