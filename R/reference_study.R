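#' Bundled reference study: design
#'
#' The three-supplement in vitro degradability trial shipped with the
#' package for validation and examples: soybean meal (SBM, 54.2% CP of DM),
#' whey protein (WHEY, 89.2%) and yeast-derived microbial protein (YMP,
#' 45.8%) dosed at three isonitrogenous levels (5, 23 and 53% of diet CP)
#' on an 800 mg grass-silage/compound-feed basal substrate, fermented in
#' 40-mL batch cultures with destructive sampling at 4, 10 and 24 h.
#'
#' @return A design object (see [read_design_config()]): a list with
#'   `treatments` (named list of [treatment_spec()]), `control_id`,
#'   `sampling_times_h`, `replicates_per_time` and `vessel_volume_mL`.
#' @export
#' @examples
#' d <- bcvfa_study_design()
#' names(d$treatments)
bcvfa_study_design <- function() {
  read_design_config(
    system.file("extdata", "study_design.yaml", package = "rupvitro",
                mustWork = TRUE)
  )
}

#' Bundled reference study: treatment means
#'
#' Treatment-level mean analyte concentrations of the reference trial (10
#' treatments at 4, 10 and 24 h; 30 rows). Individual BCVFA concentrations
#' were reported only as a total, so `isobutyric_mM`, `methylbutyric2_mM`
#' and `isovaleric_mM` are `NA` and `total_bcvfa_mM` carries the reported
#' totals; conversion estimates on these means therefore use the molar-sum
#' aggregate. Rows are means, not vessels: `replicate` is 1 throughout and
#' standard errors cannot be derived from them.
#'
#' @return A data frame of vessel-record shape (see [read_observations()]).
#' @export
#' @examples
#' m <- bcvfa_study_means()
#' subset(m, treatment_id == "Control" & time_h == 24)$total_vfa_mM
bcvfa_study_means <- function() {
  read_observations(
    system.file("extdata", "study_means.csv", package = "rupvitro",
                mustWork = TRUE)
  )
}
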