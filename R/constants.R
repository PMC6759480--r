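#' Branched-chain amino acid constants
#'
#' Molar masses of the free amino acids and the mapping of each
#' branched-chain amino acid (BCAA) onto the branched-chain volatile fatty
#' acid (BCVFA) produced by its oxidative deamination and decarboxylation:
#' valine to isobutyric, isoleucine to 2-methylbutyric, leucine to
#' isovaleric acid. The conversion is mole-for-mole (one BCAA yields one
#' BCVFA).
#'
#' Molar masses are those of the free amino acids (g/mol), not residue
#' masses: the supplements are dosed and assayed as hydrolysed amino acids,
#' and only the free-acid masses reproduce the amino-acid-as-percent-of-
#' protein bookkeeping used throughout.
#'
#' @return A list with components `molar_mass_g_per_mol` (named numeric:
#'   Val, Ile, Leu) and `bcvfa_partner` (named character mapping each BCAA
#'   to the column name of its partner acid).
#' @export
#' @examples
#' aa_constants()$bcvfa_partner[["Val"]]
aa_constants <- function() {
  list(
    molar_mass_g_per_mol = c(Val = 117.15, Ile = 131.17, Leu = 131.17),
    bcvfa_partner = c(
      Val = "isobutyric_mM",
      Ile = "methylbutyric2_mM",
      Leu = "isovaleric_mM"
    )
  )
}

#' @keywords internal
BCAA <- c("Val", "Ile", "Leu")

## canonical analyte column order for vessel records (units in names)
#' @keywords internal
VFA_COLUMNS <- c(
  "acetic_mM", "propionic_mM", "butyric_mM", "valeric_mM",
  "isobutyric_mM", "methylbutyric2_mM", "isovaleric_mM"
)

#' @keywords internal
RECORD_COLUMNS <- c(
  "treatment_id", "replicate", "time_h",
  VFA_COLUMNS, "lactic_mM", "total_bcvfa_mM", "total_vfa_mM",
  "nh3_mM", "gas_mL", "bacteria_copies_per_mL"
)

#' @keywords internal
MANDATORY_COLUMNS <- c("treatment_id", "replicate", "time_h")

check_bcaa_names <- function(x, what = "BCAA mapping") {
  bad <- setdiff(names(x), BCAA)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s has unknown amino-acid key(s): %s (expected Val, Ile, Leu)",
      what, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}
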