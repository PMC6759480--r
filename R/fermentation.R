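#' Total branched-chain VFA concentration
#'
#' Sum of isobutyric, 2-methylbutyric and isovaleric acid. If any component
#' is missing for a record the result is `NA` (missing propagates, never
#' treated as zero).
#'
#' @param records Data frame of vessel records.
#' @return Numeric vector (mM), one value per record.
#' @export
total_bcvfa <- function(records) {
  cols <- c("isobutyric_mM", "methylbutyric2_mM", "isovaleric_mM")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack BCVFA column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rowSums(as.matrix(records[, cols, drop = FALSE]))
}

#' Total VFA concentration
#'
#' Acetic + propionic + butyric + valeric + total BCVFA. Lactic acid is an
#' intermediate, not a VFA, and is excluded.
#'
#' @param records Data frame of vessel records.
#' @return Numeric vector (mM), `NA` where any component is missing.
#' @export
total_vfa <- function(records) {
  straight <- c("acetic_mM", "propionic_mM", "butyric_mM", "valeric_mM")
  missing_cols <- setdiff(straight, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack VFA column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rowSums(as.matrix(records[, straight, drop = FALSE])) + total_bcvfa(records)
}

#' Log10 bacterial density
#'
#' @param copies_per_mL 16S rRNA gene copies per mL, `> 0`.
#' @return Base-10 logarithm of the density.
#' @export
log10_bacteria <- function(copies_per_mL) {
  if (any(!is.na(copies_per_mL) & copies_per_mL <= 0)) {
    stop("bacterial density must be > 0", call. = FALSE)
  }
  log10(copies_per_mL)
}

#' Bacterial doublings between two densities
#'
#' @param density_start,density_end Densities (copies/mL), both `> 0`.
#' @return `log2(density_end / density_start)`.
#' @export
#' @examples
#' doublings(3e10, 3e11) # ~3.32, i.e. ~3 doublings
doublings <- function(density_start, density_end) {
  if (any(!is.na(density_start) & density_start <= 0) ||
      any(!is.na(density_end) & density_end <= 0)) {
    stop("densities must be > 0", call. = FALSE)
  }
  log2(density_end / density_start)
}

#' @rdname doublings
#' @export
doublings_rounded <- function(density_start, density_end) {
  round(doublings(density_start, density_end))
}

#' Treatment-level summary of analytes
#'
#' Mean, standard error (SD / sqrt(n)) and n per treatment x time x
#' analyte, the layout of a standard fermentation summary table. Missing
#' values are dropped per cell; a cell with a single observation gets
#' `se = NA`; empty groups are omitted with a warning.
#'
#' @param records Data frame of vessel records.
#' @param analytes Character vector of analyte columns to summarise;
#'   default: every numeric analyte column present, plus derived
#'   `total_bcvfa_mM` / `total_vfa_mM` when their components are available.
#' @param group_keys Grouping columns, default `c("treatment_id", "time_h")`.
#' @return Long data frame: group keys, `analyte`, `n`, `mean`, `se`.
#' @export
treatment_summary <- function(records, analytes = NULL,
                              group_keys = c("treatment_id", "time_h")) {
  stopifnot(all(group_keys %in% names(records)))
  records <- as.data.frame(records)
  bcvfa_cols <- c("isobutyric_mM", "methylbutyric2_mM", "isovaleric_mM")
  if (all(bcvfa_cols %in% names(records))) {
    derived_bcvfa <- total_bcvfa(records)
    if ("total_bcvfa_mM" %in% names(records)) {
      keep <- is.na(derived_bcvfa)
      derived_bcvfa[keep] <- records$total_bcvfa_mM[keep]
    }
    records$total_bcvfa_mM <- derived_bcvfa
    straight <- c("acetic_mM", "propionic_mM", "butyric_mM", "valeric_mM")
    if (all(straight %in% names(records))) {
      derived_vfa <- rowSums(as.matrix(records[, straight])) +
        records$total_bcvfa_mM
      records$total_vfa_mM <- derived_vfa
    }
  }
  if (is.null(analytes)) {
    candidates <- setdiff(names(records), c(group_keys, "replicate"))
    analytes <- candidates[vapply(records[candidates], is.numeric,
                                  logical(1))]
  }
  missing_cols <- setdiff(analytes, names(records))
  if (length(missing_cols) > 0L) {
    stop("unknown analyte column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  key <- interaction(records[group_keys], drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  out <- lapply(groups, function(g) {
    if (nrow(g) == 0L) return(NULL)
    stats_per <- lapply(analytes, function(a) {
      x <- g[[a]][!is.na(g[[a]])]
      n <- length(x)
      data.frame(
        analyte = a,
        n = n,
        mean = if (n > 0L) mean(x) else NA_real_,
        se = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
      )
    })
    cbind(g[1L, group_keys, drop = FALSE], do.call(rbind, stats_per),
          row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
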