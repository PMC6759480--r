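OBS_SCHEMA <- "rupvitro-observations/1"

#' Read a design configuration
#'
#' Reads a YAML design file listing the basal components, the supplements
#' with CP fractions and dose levels (each dose carrying either explicit
#' `bcaa_mmol` or relying on a supplement-level `bcaa_mg_per_g_protein`
#' composition), the vessel volume, replicate count and sampling times, and
#' builds the treatment list (control first). Treatment ids are
#' `<supplement>_<level>`.
#'
#' @param path Path to the YAML file.
#' @return An object of class `"rupvitro_design"`: list with `treatments`
#'   (named list of [treatment_spec()]), `control_id`, `sampling_times_h`,
#'   `replicates_per_time`, `vessel_volume_mL`.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("design config not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (field in c("basal", "supplements")) {
    if (is.null(cfg[[field]])) {
      stop("design config lacks required field '", field, "'",
           call. = FALSE)
    }
  }
  volume <- if (is.null(cfg$vessel_volume_mL)) 40 else cfg$vessel_volume_mL
  control_id <- if (is.null(cfg$control_id)) "Control" else cfg$control_id
  basal <- lapply(cfg$basal, function(b) {
    basal_component(b$name, b$dm_mg, b$cp_frac)
  })

  treatments <- list()
  treatments[[control_id]] <- treatment_spec(
    control_id, basal, vessel_volume_mL = volume
  )
  for (s in cfg$supplements) {
    comp <- if (is.null(s$bcaa_mg_per_g_protein)) NULL else
      unlist(s$bcaa_mg_per_g_protein)
    spec <- supplement_spec(s$name, s$cp_frac, comp)
    for (d in s$doses) {
      id <- paste(s$name, d$level, sep = "_")
      bcaa <- if (is.null(d$bcaa_mmol)) NULL else unlist(d$bcaa_mmol)
      treatments[[id]] <- treatment_spec(
        id, basal, supplement = spec, dose_mg_dm = d$dose_mg_dm,
        bcaa_mmol = bcaa, vessel_volume_mL = volume
      )
    }
  }
  structure(
    list(
      treatments = treatments,
      control_id = control_id,
      sampling_times_h = cfg$sampling_times_h,
      replicates_per_time = cfg$replicates_per_time,
      vessel_volume_mL = volume
    ),
    class = "rupvitro_design"
  )
}

#' Read vessel observations from CSV
#'
#' One row per vessel x sampling time. Mandatory columns: `treatment_id`,
#' `replicate`, `time_h`. Analyte columns carry their unit in the name
#' (`acetic_mM`, ..., `nh3_mM`, `gas_mL`, `bacteria_copies_per_mL`,
#' optionally `total_bcvfa_mM` / `total_vfa_mM`); any may be missing.
#' Unknown columns are dropped with a warning. Empty cells are missing
#' values (never zero). Malformed numeric cells and negative concentrations
#' are reported with their line numbers.
#'
#' @param path Path to the CSV file (comment lines starting with `#`, such
#'   as the schema line written by [write_observations()], are ignored).
#' @return Data frame of validated vessel records.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, na.strings = "", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("observations CSV lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), RECORD_COLUMNS)
  if (length(unknown) > 0L) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  numeric_cols <- setdiff(names(raw), "treatment_id")
  for (col in numeric_cols) {
    v <- raw[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad) > 0L) {
        stop(sprintf("malformed numeric cell(s) in column '%s', line(s) %s",
                     col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
      }
      raw[[col]] <- parsed
    }
  }
  conc_cols <- intersect(names(raw),
                         c(VFA_COLUMNS, "lactic_mM", "total_bcvfa_mM",
                           "total_vfa_mM", "nh3_mM", "gas_mL"))
  for (col in conc_cols) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("negative value(s) in column '%s', line(s) %s",
                   col, paste(bad + 1L, collapse = ", ")), call. = FALSE)
    }
  }
  if ("bacteria_copies_per_mL" %in% names(raw)) {
    bad <- which(!is.na(raw$bacteria_copies_per_mL) &
                   raw$bacteria_copies_per_mL <= 0)
    if (length(bad) > 0L) {
      stop("non-positive bacterial density, line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
  }
  raw
}

#' Write vessel observations to CSV
#'
#' Emits a fixed column order and a schema-version comment line so outputs
#' are diffable across runs; missing values are empty cells.
#'
#' @param records Data frame of vessel records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  cols <- intersect(RECORD_COLUMNS, names(records))
  extra <- setdiff(names(records), RECORD_COLUMNS)
  if (length(extra) > 0L) {
    warning("dropping non-schema column(s) on write: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", OBS_SCHEMA), con)
  utils::write.csv(records[, cols, drop = FALSE], con,
                   row.names = FALSE, na = "")
  invisible(path)
}

write_table_csv <- function(df, path, schema) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", schema), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full degradability analysis
#'
#' End-to-end pipeline: treatment summaries (fermentation module),
#' control-subtracted conversion and RUP estimates (conversion module),
#' per-analyte ANOVA with Tukey letters and the pooled fermentation-
#' parameter correlation table (stats module). Writes `summary.csv`,
#' `conversion.csv`, `anova.csv`, `tukey_letters.csv`, `correlations.csv`
#' and a plain-text `report.txt` echoing the headline conversion/RUP
#' numbers into `out_dir`, and returns the results invisibly.
#'
#' @param design Design object or path to a design YAML.
#' @param observations Data frame of vessel records, or path to an
#'   observations CSV, or `NULL` to simulate from `design` with
#'   [simulate_experiment()] (seeded by `seed`).
#' @param out_dir Output directory, created if absent.
#' @param conversion_time_h Timepoint(s) for the conversion table; default
#'   all observed times (the terminal time carries the headline RUP).
#' @param correlation_time_h Timepoint for the correlation table; default
#'   10 h when present, else the median time.
#' @param alpha Alpha for Tukey letters.
#' @param aggregate Conversion aggregate, see [percent_conversion()].
#' @param seed Seed used when simulating.
#' @return Invisibly, a list with `summary`, `conversion`, `anova`,
#'   `letters`, `correlations` and the output `paths`.
#' @export
run_full_analysis <- function(design, observations = NULL, out_dir,
                              conversion_time_h = NULL,
                              correlation_time_h = NULL,
                              alpha = 0.05,
                              aggregate = "molar-total",
                              seed = 20190311L) {
  if (is.character(design)) design <- read_design_config(design)
  design <- as_design(design)
  if (is.null(observations)) {
    observations <- simulate_experiment(sim_config(design, seed = seed))$records
  } else if (is.character(observations)) {
    observations <- read_observations(observations)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  summary_tab <- treatment_summary(observations)
  conv <- conversion_table(observations, design, time_h = conversion_time_h,
                           aggregate = aggregate)
  stats_out <- tryCatch(
    anova_by_analyte(observations, alpha = alpha),
    error = function(e) list(anova = data.frame(), letters = data.frame())
  )
  times <- sort(unique(observations$time_h))
  if (is.null(correlation_time_h)) {
    correlation_time_h <- if (10 %in% times) 10 else
      times[ceiling(length(times) / 2)]
  }
  correlations <- tryCatch(
    fermentation_correlations(observations, correlation_time_h),
    error = function(e) data.frame()
  )

  paths <- list(
    summary = file.path(out_dir, "summary.csv"),
    conversion = file.path(out_dir, "conversion.csv"),
    anova = file.path(out_dir, "anova.csv"),
    letters = file.path(out_dir, "tukey_letters.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    report = file.path(out_dir, "report.txt")
  )
  write_table_csv(summary_tab, paths$summary, "rupvitro-summary/1")
  write_table_csv(conv, paths$conversion, "rupvitro-conversion/1")
  write_table_csv(stats_out$anova, paths$anova, "rupvitro-anova/1")
  write_table_csv(stats_out$letters, paths$letters, "rupvitro-letters/1")
  write_table_csv(correlations, paths$correlations,
                  "rupvitro-correlations/1")

  design_digest <- digest_design(design)
  rpt <- c(
    "rupvitro full analysis report",
    sprintf("package version: %s",
            as.character(utils::packageVersion("rupvitro"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("design: %d treatments, control '%s', digest %s",
            length(design$treatments), design$control_id, design_digest),
    sprintf("vessels: %d records, times %s h", nrow(observations),
            paste(times, collapse = "/")),
    "",
    "BCAA-to-BCVFA conversion and RUP (molar-total aggregate):"
  )
  final_t <- max(conv$time_h)
  headline <- conv[conv$time_h == final_t, , drop = FALSE]
  for (i in seq_len(nrow(headline))) {
    rpt <- c(rpt, sprintf(
      "  %-12s %2.0f h: conversion %5.1f%%  RUP %5.1f%%%s",
      headline$treatment_id[i], final_t, headline$total_pct_molar[i],
      headline$rup_pct[i],
      if (isTRUE(headline$any_negative[i])) "  [negative delta flagged]"
      else ""
    ))
  }
  writeLines(rpt, paths$report)
  invisible(list(summary = summary_tab, conversion = conv,
                 anova = stats_out$anova, letters = stats_out$letters,
                 correlations = correlations, paths = paths))
}

# stable md5 digest of the design (logged so runs are traceable)
digest_design <- function(design) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  # version/compression pinned so the digest depends only on content
  saveRDS(design, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
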