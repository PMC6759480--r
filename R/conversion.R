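#' Control-subtracted BCVFA increase
#'
#' Difference in branched-chain volatile fatty acid concentrations between
#' a supplemented vessel (or treatment mean) and the unamended control mean
#' at the same sampling time. Negative differences are permitted and
#' returned as-is.
#'
#' @param treatment_mean,control_mean One-row data frames (or lists) of
#'   vessel-record shape: BCVFA columns `isobutyric_mM`,
#'   `methylbutyric2_mM`, `isovaleric_mM`, optionally `total_bcvfa_mM`, and
#'   `time_h`.
#' @return Named numeric of concentration increases (mM) for the three
#'   acids plus `total_bcvfa_mM`. The total uses the three components when
#'   all are present, otherwise the stored `total_bcvfa_mM` column.
#' @export
bcvfa_increase <- function(treatment_mean, control_mean) {
  t_trt <- treatment_mean[["time_h"]]
  t_ctl <- control_mean[["time_h"]]
  if (!is.null(t_trt) && !is.null(t_ctl) &&
      !isTRUE(all.equal(as.numeric(t_trt), as.numeric(t_ctl)))) {
    stop(sprintf("timepoint mismatch: treatment at %s h, control at %s h",
                 t_trt, t_ctl), call. = FALSE)
  }
  acids <- c("isobutyric_mM", "methylbutyric2_mM", "isovaleric_mM")
  get <- function(x, col) {
    v <- x[[col]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  delta <- vapply(acids, function(a) {
    get(treatment_mean, a) - get(control_mean, a)
  }, numeric(1))
  total <- if (!anyNA(delta)) {
    sum(delta)
  } else {
    get(treatment_mean, "total_bcvfa_mM") - get(control_mean, "total_bcvfa_mM")
  }
  c(delta, total_bcvfa_mM = total)
}

#' Concentration to amount per vessel
#'
#' @param conc_mM Concentration in mM (mmol/L).
#' @param volume_mL Vessel liquid volume in mL, `> 0`.
#' @return Amount in mmol: `conc_mM * volume_mL / 1000`.
#' @export
#' @examples
#' mM_to_mmol(2.51, 40) # 0.1004 mmol
mM_to_mmol <- function(conc_mM, volume_mL) {
  if (any(volume_mL <= 0)) stop("volume_mL must be > 0", call. = FALSE)
  conc_mM * volume_mL / 1000
}

#' Percent conversion of introduced BCAA to BCVFA
#'
#' The study's core statistic. Each amino acid's conversion is the
#' control-subtracted amount of its partner acid divided by the amount of
#' amino acid introduced (mole for mole): `100 * delta_mmol(partner(aa)) /
#' mmol(aa)`. Two aggregates are computed: the molar-sum total
#' (`100 * sum(delta) / sum(introduced)`, the headline value, equal to the
#' BCAA-mole-weighted mean of the per-acid values) and the unweighted mean
#' of the three per-acid conversions. RUP (rumen-undegradable protein) is
#' `100 -` the chosen aggregate.
#'
#' Per-acid conversion for an amino acid introduced at zero mmol is
#' undefined and reported as `NA`. Negative conversions (treatment below
#' control) are returned as-is and flagged, never truncated, so that
#' dose-response comparisons stay unbiased.
#'
#' @param delta_bcvfa_mmol Named numeric of control-subtracted BCVFA
#'   amounts (mmol): names `isobutyric_mM`, `methylbutyric2_mM`,
#'   `isovaleric_mM` (any may be `NA`) and optionally `total_bcvfa_mM`
#'   (used for the molar total when a component is missing).
#' @param bcaa_introduced_mmol Named numeric (Val, Ile, Leu) of mmol
#'   introduced; at least one entry must be positive.
#' @param constants Amino-acid constants, see [aa_constants()].
#' @param aggregate Aggregate used for `rup_pct`: `"molar-total"` (default)
#'   or `"mean-of-acids"`.
#' @return An object of class `"conversion_result"`: list with
#'   `per_acid_pct` (named Val/Ile/Leu), `total_pct_molar`,
#'   `mean_of_acids_pct`, `rup_pct`, `aggregate` and `any_negative`.
#' @export
percent_conversion <- function(delta_bcvfa_mmol, bcaa_introduced_mmol,
                               constants = aa_constants(),
                               aggregate = c("molar-total", "mean-of-acids")) {
  aggregate <- match.arg(aggregate)
  check_bcaa_names(bcaa_introduced_mmol, "bcaa_introduced_mmol")
  bcaa <- bcaa_introduced_mmol[BCAA]
  names(bcaa) <- BCAA
  bcaa[is.na(bcaa)] <- 0
  if (!any(bcaa > 0)) {
    stop("at least one BCAA must be introduced at > 0 mmol", call. = FALSE)
  }

  get_delta <- function(nm) {
    v <- if (is.list(delta_bcvfa_mmol)) delta_bcvfa_mmol[[nm]] else
      unname(delta_bcvfa_mmol[nm])
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }
  partner <- constants$bcvfa_partner
  per_acid <- vapply(BCAA, function(aa) {
    d <- get_delta(partner[[aa]])
    if (is.na(d) || bcaa[[aa]] <= 0) return(NA_real_)
    100 * d / bcaa[[aa]]
  }, numeric(1))

  deltas <- vapply(unname(partner), get_delta, numeric(1))
  total_delta <- if (!anyNA(deltas)) sum(deltas) else
    get_delta("total_bcvfa_mM")
  total_pct <- 100 * total_delta / sum(bcaa)
  mean_pct <- if (anyNA(per_acid)) NA_real_ else mean(per_acid)

  headline <- if (aggregate == "molar-total") total_pct else mean_pct
  structure(
    list(
      per_acid_pct = per_acid,
      total_pct_molar = total_pct,
      mean_of_acids_pct = mean_pct,
      rup_pct = 100 - headline,
      aggregate = aggregate,
      any_negative = isTRUE(any(c(per_acid, total_pct) < 0, na.rm = TRUE))
    ),
    class = "conversion_result"
  )
}

#' Rumen-undegradable protein percentage
#'
#' `100 - conversion_pct`. Values outside \[0, 100\] (possible when the
#' treatment fell below the control, or conversion exceeded 100%) are
#' returned unchanged with a warning.
#'
#' @param conversion_pct Percent BCAA-to-BCVFA conversion.
#' @return RUP as a percentage of supplement crude protein.
#' @export
#' @examples
#' rup_percent(62) # 38
rup_percent <- function(conversion_pct) {
  rup <- 100 - conversion_pct
  out_of_range <- !is.na(rup) & (rup < 0 | rup > 100)
  if (any(out_of_range)) {
    warning("RUP outside [0, 100] for ", sum(out_of_range),
            " value(s); returned unchanged", call. = FALSE)
  }
  rup
}

as_design <- function(design) {
  if (inherits(design, "rupvitro_design")) return(design)
  if (is.list(design) &&
      all(vapply(design, inherits, logical(1), "treatment_spec"))) {
    ids <- vapply(design, function(t) t$id, character(1))
    names(design) <- ids
    vol <- unique(vapply(design, function(t) t$vessel_volume_mL, numeric(1)))
    ctrl <- ids[vapply(design, function(t) all(t$bcaa_mmol == 0), logical(1))]
    return(structure(
      list(
        treatments = design,
        control_id = if (length(ctrl)) ctrl[[1]] else NA_character_,
        vessel_volume_mL = vol[[1]],
        sampling_times_h = NULL, replicates_per_time = NULL
      ),
      class = "rupvitro_design"
    ))
  }
  stop("design must be a rupvitro_design or a list of treatment_spec",
       call. = FALSE)
}

#' Conversion table across treatments and timepoints
#'
#' Drives [bcvfa_increase()] and [percent_conversion()] across a whole
#' experiment. Control subtraction uses the mean of the control replicates
#' at the matching timepoint; every supplemented replicate is compared with
#' that control mean so that replicate-level standard errors can be
#' attached to the treatment means.
#'
#' @param records Data frame of vessel records (see [read_observations()]).
#' @param design Design object ([read_design_config()],
#'   [bcvfa_study_design()]) or list of [treatment_spec()].
#' @param time_h Sampling times to evaluate; default all times present.
#' @param volume_mL Vessel volume; defaults to the design's.
#' @param aggregate Aggregate for `rup_pct`, as in [percent_conversion()].
#' @param per_replicate If `TRUE`, return the replicate-level conversions
#'   instead of treatment summaries.
#' @return A data frame with one row per supplemented treatment x time:
#'   `treatment_id`, `time_h`, `n`, per-acid conversion percentages
#'   (`conv_val_pct`, `conv_ile_pct`, `conv_leu_pct`),
#'   `total_pct_molar`, `mean_of_acids_pct`, `se_total_pct` (replicate-level
#'   SE of the molar total; `NA` for single "replicates" such as published
#'   means), `rup_pct`, and `any_negative`.
#' @export
conversion_table <- function(records, design, time_h = NULL,
                             volume_mL = NULL,
                             aggregate = c("molar-total", "mean-of-acids"),
                             per_replicate = FALSE) {
  aggregate <- match.arg(aggregate)
  design <- as_design(design)
  if (is.null(volume_mL)) volume_mL <- design$vessel_volume_mL
  if (is.na(design$control_id) ||
      !design$control_id %in% records$treatment_id) {
    stop("control treatment '", design$control_id,
         "' missing from records", call. = FALSE)
  }
  if (is.null(time_h)) time_h <- sort(unique(records$time_h))

  acid_cols <- c("isobutyric_mM", "methylbutyric2_mM", "isovaleric_mM")
  supplemented <- Filter(function(t) any(t$bcaa_mmol > 0), design$treatments)

  rows <- list()
  rep_rows <- list()
  for (tt in time_h) {
    ctl <- records[records$treatment_id == design$control_id &
                     records$time_h == tt, , drop = FALSE]
    if (nrow(ctl) == 0L) {
      stop("no control records at time ", tt, " h", call. = FALSE)
    }
    ctl_mean <- as.list(colMeans(
      ctl[, intersect(c(acid_cols, "total_bcvfa_mM"), names(ctl)),
          drop = FALSE],
      na.rm = FALSE
    ))
    if (all(acid_cols %in% names(ctl_mean)) &&
        !anyNA(unlist(ctl_mean[acid_cols]))) {
      ctl_mean$total_bcvfa_mM <- sum(unlist(ctl_mean[acid_cols]))
    }
    ctl_mean$time_h <- tt

    for (trt in supplemented) {
      obs <- records[records$treatment_id == trt$id &
                       records$time_h == tt, , drop = FALSE]
      if (nrow(obs) == 0L) next
      reps <- lapply(seq_len(nrow(obs)), function(i) {
        delta_mM <- bcvfa_increase(as.list(obs[i, ]), ctl_mean)
        delta_mmol <- mM_to_mmol(delta_mM, volume_mL)
        percent_conversion(delta_mmol, trt$bcaa_mmol, aggregate = aggregate)
      })
      rep_df <- data.frame(
        treatment_id = trt$id,
        replicate = obs$replicate,
        time_h = tt,
        conv_val_pct = vapply(reps, function(r) r$per_acid_pct[["Val"]],
                              numeric(1)),
        conv_ile_pct = vapply(reps, function(r) r$per_acid_pct[["Ile"]],
                              numeric(1)),
        conv_leu_pct = vapply(reps, function(r) r$per_acid_pct[["Leu"]],
                              numeric(1)),
        total_pct_molar = vapply(reps, function(r) r$total_pct_molar,
                                 numeric(1)),
        mean_of_acids_pct = vapply(reps, function(r) r$mean_of_acids_pct,
                                   numeric(1)),
        rup_pct = vapply(reps, function(r) r$rup_pct, numeric(1)),
        any_negative = vapply(reps, function(r) r$any_negative, logical(1))
      )
      rep_rows[[length(rep_rows) + 1L]] <- rep_df

      n <- nrow(rep_df)
      se <- function(x) if (sum(!is.na(x)) > 1L)
        stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        treatment_id = trt$id,
        time_h = tt,
        n = n,
        conv_val_pct = mean(rep_df$conv_val_pct),
        conv_ile_pct = mean(rep_df$conv_ile_pct),
        conv_leu_pct = mean(rep_df$conv_leu_pct),
        total_pct_molar = mean(rep_df$total_pct_molar),
        mean_of_acids_pct = mean(rep_df$mean_of_acids_pct),
        se_total_pct = se(rep_df$total_pct_molar),
        rup_pct = mean(rep_df$rup_pct),
        any_negative = any(rep_df$any_negative)
      )
    }
  }
  empty_cols <- c("treatment_id", "time_h", "n", "conv_val_pct",
                  "conv_ile_pct", "conv_leu_pct", "total_pct_molar",
                  "mean_of_acids_pct", "se_total_pct", "rup_pct",
                  "any_negative")
  if (per_replicate) {
    if (length(rep_rows) == 0L) {
      return(data.frame())
    }
    out <- do.call(rbind, rep_rows)
  } else {
    if (length(rows) == 0L) {
      out <- as.data.frame(
        stats::setNames(rep(list(logical(0)), length(empty_cols)),
                        empty_cols)
      )
      return(out)
    }
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}
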