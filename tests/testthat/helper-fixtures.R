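# shared fixtures built in code

toy_basal <- function() {
  list(
    basal_component("grass silage", 400, 0.16),
    basal_component("compound feed", 400, 0.19)
  )
}

# a two-treatment design with known BCAA amounts, for small tests
toy_design <- function(bcaa = c(Val = 0.088, Ile = 0.085, Leu = 0.139)) {
  single_supplement_design(bcaa_mmol = bcaa)
}

# minimal valid vessel-record data frame
toy_records <- function() {
  data.frame(
    treatment_id = rep(c("Control", "TEST"), each = 2),
    replicate = rep(1:2, 2),
    time_h = 24,
    acetic_mM = c(50, 51, 60, 61),
    propionic_mM = c(25, 25, 30, 30),
    butyric_mM = c(8, 8, 9, 9),
    valeric_mM = c(3, 3, 4, 4),
    isobutyric_mM = c(0.4, 0.4, 1.4, 1.4),
    methylbutyric2_mM = c(0.4, 0.4, 1.4, 1.4),
    isovaleric_mM = c(0.45, 0.45, 2.0, 2.0),
    lactic_mM = 0.1,
    nh3_mM = c(7, 7, 12, 12),
    gas_mL = c(100, 101, 120, 121),
    bacteria_copies_per_mL = 3e11
  )
}
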