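# Shared fixtures, built in code.

base_params <- model_params()

# Three distinct calibration regimens, one with a debulk event.
recovery_regimens <- list(
  adt1_only = treatment_regimen(
    data.frame(kind = "ADT1", start_day = 0, end_day = 400)),
  adt1_then_adt2 = treatment_regimen(
    data.frame(kind = c("ADT1", "ADT2"), start_day = c(0, 280),
               end_day = c(280, 560))),
  with_debulk = treatment_regimen(
    data.frame(kind = "ADT1", start_day = 0, end_day = 300),
    data.frame(kind = "SURG", day = 300, fraction = 0.9)))

# Hand-built trajectory for endpoint boundary checks.
fake_trajectory <- function(day, psa) {
  df <- data.frame(day = day, naive = 0, adt1r = 0, adt2r = 0, ctr = 0,
                   adt1r_ctr = 0, adt2r_ctr = 0, total_cells = 0,
                   psa_ng_ml = psa, active_treatment = "NONE",
                   stringsAsFactors = FALSE)
  class(df) <- c("tumor_trajectory", "data.frame")
  df
}
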