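# A deterministic record with distinct arms, used across engine/PSA tests:
# alternative arm has lower utility and higher hazard than surgery.
degenerate_effect_record <- function(age = 68, u_alt = 0.675, u_surg = 0.9,
                                     s_alt = 0.8, s_surg = 0.95, horizon = 5) {
  comparison_record(
    disease = "test disease", surgery = "surgery", alternative = "alternative",
    surv_altern = survival_estimate(s_alt, horizon, family = "degenerate"),
    surv_surg = survival_estimate(s_surg, horizon, family = "degenerate"),
    qol_altern = utility_estimate(u_alt, u_alt, u_alt),
    qol_surg = utility_estimate(u_surg, u_surg, u_surg),
    age = age_estimate(age, age, age))
}

bradycardia_record <- function() {
  reg <- surgdelay_registry()
  reg[[which(vapply(reg, `[[`, "", "disease") == "Symptomatic bradycardia")]]
}
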