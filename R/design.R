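#' Protein supplement specification
#'
#' Describes one protein supplement: its crude-protein (CP) content as a
#' fraction of dry matter (DM), and optionally its BCAA composition in mg
#' amino acid per g crude protein. Either the composition or per-dose BCAA
#' amounts (on [treatment_spec()]) must be supplied for conversion
#' estimates.
#'
#' @param name Supplement name, e.g. `"SBM"`.
#' @param cp_frac Crude-protein fraction of dry matter, in (0, 1].
#' @param bcaa_mg_per_g_protein Optional named numeric (Val, Ile, Leu):
#'   mg amino acid per g crude protein.
#' @return An object of class `"supplement_spec"`.
#' @export
#' @examples
#' supplement_spec("WHEY", cp_frac = 0.892)
supplement_spec <- function(name, cp_frac, bcaa_mg_per_g_protein = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(cp_frac) || length(cp_frac) != 1L ||
      cp_frac <= 0 || cp_frac > 1) {
    stop("cp_frac must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.null(bcaa_mg_per_g_protein)) {
    check_bcaa_names(bcaa_mg_per_g_protein, "bcaa_mg_per_g_protein")
    if (any(bcaa_mg_per_g_protein < 0)) {
      stop("BCAA contents must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(
      name = name, cp_frac = cp_frac,
      bcaa_mg_per_g_protein = bcaa_mg_per_g_protein
    ),
    class = "supplement_spec"
  )
}

#' Basal diet component
#'
#' @param name Component name, e.g. `"grass silage"`.
#' @param dm_mg Dry matter per vessel (mg), `>= 0`.
#' @param cp_frac Crude-protein fraction of DM, in \[0, 1\].
#' @return An object of class `"basal_component"`.
#' @export
basal_component <- function(name, dm_mg, cp_frac) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(dm_mg) || dm_mg < 0) {
    stop("dm_mg must be >= 0", call. = FALSE)
  }
  if (!is.numeric(cp_frac) || cp_frac < 0 || cp_frac > 1) {
    stop("cp_frac must be in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, dm_mg = dm_mg, cp_frac = cp_frac),
            class = "basal_component")
}

#' Treatment specification
#'
#' One dietary treatment: the basal substrate, an optional protein
#' supplement with its DM dose, and the amounts of Val, Ile and Leu (mmol)
#' introduced with that dose. When both a supplement composition and
#' explicit `bcaa_mmol` are given, the two are cross-checked and must agree
#' within 5\% relative (reported BCAA amounts are rounded to 3 decimals of
#' a mmol, so ~2\% discrepancies are expected).
#'
#' @param id Treatment identifier, e.g. `"SBM_high"`.
#' @param basal List of [basal_component()] objects (non-empty).
#' @param supplement A [supplement_spec()], or `NULL` for control.
#' @param dose_mg_dm Supplement DM per vessel (mg), `>= 0`.
#' @param bcaa_mmol Named numeric (Val, Ile, Leu): mmol introduced with the
#'   supplement dose. Defaults to all zero for controls; computed from the
#'   supplement composition when that is available and `bcaa_mmol` is
#'   missing.
#' @param vessel_volume_mL Culture liquid volume (mL), default 40.
#' @return An object of class `"treatment_spec"`.
#' @export
treatment_spec <- function(id, basal, supplement = NULL, dose_mg_dm = 0,
                           bcaa_mmol = NULL, vessel_volume_mL = 40) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.list(basal) || length(basal) == 0L) {
    stop("basal must be a non-empty list of basal_component", call. = FALSE)
  }
  if (!all(vapply(basal, inherits, logical(1), "basal_component"))) {
    stop("all basal entries must be basal_component objects", call. = FALSE)
  }
  if (dose_mg_dm < 0) stop("dose_mg_dm must be >= 0", call. = FALSE)
  if (vessel_volume_mL <= 0) {
    stop("vessel_volume_mL must be > 0", call. = FALSE)
  }
  if (!is.null(supplement) && !inherits(supplement, "supplement_spec")) {
    stop("supplement must be a supplement_spec or NULL", call. = FALSE)
  }

  from_comp <- NULL
  if (!is.null(supplement) && !is.null(supplement$bcaa_mg_per_g_protein)) {
    from_comp <- bcaa_mmol_from_composition(
      dose_mg_dm, supplement$cp_frac, supplement$bcaa_mg_per_g_protein
    )
  }
  if (is.null(bcaa_mmol)) {
    bcaa_mmol <- if (!is.null(from_comp)) from_comp else
      c(Val = 0, Ile = 0, Leu = 0)
  } else {
    check_bcaa_names(bcaa_mmol, "bcaa_mmol")
    bcaa_mmol <- bcaa_mmol[BCAA]
    names(bcaa_mmol) <- BCAA
    bcaa_mmol[is.na(bcaa_mmol)] <- 0
    if (!is.null(from_comp)) {
      pos <- from_comp > 0
      rel <- abs(bcaa_mmol[pos] - from_comp[pos]) / from_comp[pos]
      if (any(rel > 0.05)) {
        stop(sprintf(
          "bcaa_mmol disagrees with supplement composition by > 5%% (%s)",
          paste(BCAA[pos][rel > 0.05], collapse = ", ")
        ), call. = FALSE)
      }
    }
  }
  structure(
    list(
      id = id, basal = basal, supplement = supplement,
      dose_mg_dm = dose_mg_dm, bcaa_mmol = bcaa_mmol,
      vessel_volume_mL = vessel_volume_mL
    ),
    class = "treatment_spec"
  )
}

#' Isonitrogenous supplement dose
#'
#' Dose of a supplement (mg DM) delivering the same crude-protein mass as a
#' reference dose of another supplement: `dose * target_cp_frac ==
#' ref_dose_mg_dm * ref_cp_frac`.
#'
#' @param ref_dose_mg_dm Reference supplement dose (mg DM), `> 0`.
#' @param ref_cp_frac Reference supplement CP fraction of DM, in (0, 1].
#' @param target_cp_frac Target supplement CP fraction of DM, in (0, 1].
#' @return Target dose in mg DM.
#' @export
#' @examples
#' # 16.0 mg of a 45.8% CP supplement matched by a 54.2% CP supplement:
#' isonitrogenous_dose(16.0, 0.458, 0.542) # 13.5 mg
isonitrogenous_dose <- function(ref_dose_mg_dm, ref_cp_frac, target_cp_frac) {
  if (any(c(ref_dose_mg_dm, ref_cp_frac, target_cp_frac) <= 0)) {
    stop("all arguments must be > 0", call. = FALSE)
  }
  if (ref_cp_frac > 1 || target_cp_frac > 1) {
    stop("crude-protein fractions must be <= 1", call. = FALSE)
  }
  ref_dose_mg_dm * ref_cp_frac / target_cp_frac
}

#' Supplement share of diet dry matter and crude protein
#'
#' @param t A [treatment_spec()].
#' @return A list with `supp_pct_of_diet_dm` and `supp_cp_pct_of_diet_cp`
#'   (both percentages).
#' @export
diet_fractions <- function(t) {
  stopifnot(inherits(t, "treatment_spec"))
  basal_dm <- vapply(t$basal, function(b) b$dm_mg, numeric(1))
  basal_cp <- vapply(t$basal, function(b) b$dm_mg * b$cp_frac, numeric(1))
  total_dm <- t$dose_mg_dm + sum(basal_dm)
  if (total_dm <= 0) stop("total diet DM is zero", call. = FALSE)
  supp_cp <- if (is.null(t$supplement)) 0 else
    t$dose_mg_dm * t$supplement$cp_frac
  total_cp <- supp_cp + sum(basal_cp)
  if (total_cp <= 0) stop("total diet CP is zero", call. = FALSE)
  list(
    supp_pct_of_diet_dm = 100 * t$dose_mg_dm / total_dm,
    supp_cp_pct_of_diet_cp = 100 * supp_cp / total_cp
  )
}

#' BCAA introduced per vessel from supplement composition
#'
#' mmol of each BCAA delivered by `dose_mg_dm` mg supplement DM:
#' `dose * cp_frac` mg protein times `content / 1000` (mg amino acid per mg
#' protein) divided by the free amino acid molar mass (g/mol); mg over
#' g/mol gives mmol directly.
#'
#' @param dose_mg_dm Supplement DM (mg), `>= 0`.
#' @param cp_frac Crude-protein fraction of supplement DM.
#' @param bcaa_mg_per_g_protein Named numeric (Val, Ile, Leu), mg/g protein.
#' @param constants Amino-acid constants, see [aa_constants()].
#' @return Named numeric (Val, Ile, Leu) of mmol per vessel.
#' @export
bcaa_mmol_from_composition <- function(dose_mg_dm, cp_frac,
                                       bcaa_mg_per_g_protein,
                                       constants = aa_constants()) {
  if (dose_mg_dm < 0 || cp_frac < 0) {
    stop("dose and cp_frac must be >= 0", call. = FALSE)
  }
  check_bcaa_names(bcaa_mg_per_g_protein, "bcaa_mg_per_g_protein")
  content <- bcaa_mg_per_g_protein[BCAA]
  content[is.na(content)] <- 0
  mm <- constants$molar_mass_g_per_mol[BCAA]
  out <- dose_mg_dm * cp_frac * (content / 1000) / mm
  names(out) <- BCAA
  out
}

#' Amino acid as percent of crude protein by mass
#'
#' Inverse of [bcaa_mmol_from_composition()] (up to the mg/g vs percent
#' scale): `100 * mmol * molar_mass / (dose * cp_frac)`.
#'
#' @param aa Amino acid name: `"Val"`, `"Ile"` or `"Leu"`.
#' @param aa_mmol mmol of the amino acid in the dose.
#' @param dose_mg_dm Supplement DM (mg).
#' @param cp_frac Crude-protein fraction of supplement DM.
#' @param constants Amino-acid constants, see [aa_constants()].
#' @return Percent of crude protein by mass.
#' @export
#' @examples
#' aa_percent_of_protein("Val", 0.088, 176, 0.892) # ~6.6%
aa_percent_of_protein <- function(aa, aa_mmol, dose_mg_dm, cp_frac,
                                  constants = aa_constants()) {
  aa <- match.arg(aa, BCAA)
  protein_mg <- dose_mg_dm * cp_frac
  if (protein_mg <= 0) stop("dose * cp_frac must be > 0", call. = FALSE)
  if (aa_mmol < 0) stop("aa_mmol must be >= 0", call. = FALSE)
  100 * aa_mmol * constants$molar_mass_g_per_mol[[aa]] / protein_mg
}
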