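#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA across treatment groups; the layout used here is
#' a single 10-level treatment factor (control included) per analyte and
#' timepoint, matching row-wise post-hoc superscripts in a summary table.
#'
#' The degenerate all-constant case (zero between- and within-group sums of
#' squares) is guarded: F is reported as 0 with p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @return A one-row data frame: `f_stat`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ssw == 0 && ssb == 0) {
    f <- 0
    p <- 1
  } else if (ssw == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  data.frame(f_stat = f, p_value = p, df_between = df_b, df_within = df_w)
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All-pairs comparisons from the studentized-range distribution
#' (Tukey-Kramer for unequal group sizes, via [stats::TukeyHSD()]),
#' summarised as a compact letter display: groups sharing no letter differ
#' at the given alpha; groups not significantly different share at least
#' one letter. Letters are built with the insert-and-absorb algorithm;
#' letter assignment follows the order of the factor levels (i.e. group
#' order in the design), which also breaks ties.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param alpha Significance threshold for the letters (default 0.05; a
#'   secondary 0.10 tier as sometimes used for trends is just
#'   `alpha = 0.10`).
#' @return An object of class `"tukey_letters"`: list with `pairwise_p`
#'   (named numeric, names `"g1-g2"`), `letters` (named character, one
#'   letter string per group, in factor-level order) and `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1))
#' g <- rep(c("a_grp", "b_grp"), each = 6)
#' tukey_hsd(x, g)$letters
tukey_hsd <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  pvals <- tk[, "p adj"]
  names(pvals) <- rownames(tk)

  lev <- levels(groups)
  pmat <- matrix(1, nlevels(groups), nlevels(groups),
                 dimnames = list(lev, lev))
  for (nm in names(pvals)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    # group names may themselves contain "-": re-split against known levels
    if (length(pair) != 2L || !all(pair %in% lev)) {
      pair <- match_pair_levels(nm, lev)
    }
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- pvals[[nm]]
  }
  if (anyNA(pmat)) {
    # zero residual variance with distinct means: NaN from TukeyHSD;
    # identical means cannot be declared different
    mns <- tapply(values, groups, mean)
    for (i in seq_along(lev)) {
      for (j in seq_along(lev)) {
        if (is.na(pmat[i, j])) pmat[i, j] <- as.numeric(mns[i] == mns[j])
      }
    }
  }
  letters_vec <- compact_letters(pmat, alpha)
  structure(
    list(pairwise_p = pvals, pairwise_p_matrix = pmat,
         letters = letters_vec, alpha = alpha),
    class = "tukey_letters"
  )
}

# drop empty columns, exact duplicates, and proper subsets of other columns
absorb_letter_columns <- function(cols) {
  cols <- Filter(any, cols)
  keys <- vapply(cols, function(cl) paste(as.integer(cl), collapse = ""),
                 character(1))
  cols <- cols[!duplicated(keys)]
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (a != b && keep[b] && all(cols[[b]][cols[[a]]]) &&
          sum(cols[[b]]) > sum(cols[[a]])) {
        keep[a] <- FALSE
      }
    }
  }
  cols[keep]
}

# resolve a TukeyHSD comparison name "A-B" where A/B may contain hyphens
match_pair_levels <- function(nm, lev) {
  for (a in lev) {
    for (b in lev) {
      if (a != b && nm == paste0(a, "-", b)) return(c(a, b))
    }
  }
  stop("cannot parse comparison name: ", nm, call. = FALSE)
}

#' Compact letter display (insert-and-absorb)
#'
#' Turns a symmetric matrix of pairwise p-values into letter codes: start
#' from one letter containing every group; for each significant pair whose
#' members still share a letter, duplicate that letter, delete one member
#' from each copy, then absorb any letter whose group set is contained in
#' another's.
#'
#' @param p_matrix Symmetric numeric matrix of pairwise p-values with
#'   group names as dimnames.
#' @param alpha Significance threshold.
#' @return Named character vector of letter strings, one per group, in the
#'   row order of `p_matrix`.
#' @export
compact_letters <- function(p_matrix, alpha = 0.05) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == ncol(p_matrix))
  g <- nrow(p_matrix)
  lev <- rownames(p_matrix)
  if (is.null(lev)) lev <- as.character(seq_len(g))

  cols <- list(rep(TRUE, g)) # each column: logical membership over groups
  sig <- which(p_matrix < alpha & upper.tri(p_matrix), arr.ind = TRUE)
  if (nrow(sig) > 0L) {
    ord <- order(sig[, 1], sig[, 2]) # deterministic processing order
    sig <- sig[ord, , drop = FALSE]
  }
  for (s in seq_len(nrow(sig))) {
    i <- sig[s, 1]
    j <- sig[s, 2]
    offending <- which(vapply(cols, function(cl) cl[i] && cl[j], logical(1)))
    for (ci in offending) {
      col_a <- cols[[ci]]
      col_b <- col_a
      col_a[i] <- FALSE
      col_b[j] <- FALSE
      cols[[ci]] <- col_a
      cols[[length(cols) + 1L]] <- col_b
    }
    cols <- absorb_letter_columns(cols)
  }
  # order letters by first group they contain, for stable readable output
  cols <- Filter(any, cols)
  first <- vapply(cols, function(cl) which(cl)[1], integer(1))
  cols <- cols[order(first)]
  alphabet <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(g), function(i) {
    paste0(alphabet[which(vapply(cols, function(cl) cl[i], logical(1)))],
           collapse = "")
  }, character(1))
  names(out) <- lev
  out
}

#' Pairwise-complete Pearson correlation table
#'
#' Pearson r, two-sided p (t transform with n - 2 degrees of freedom) and
#' the number of complete pairs for every pair of parameters, using
#' pairwise-complete observations so that a vessel missing one assay still
#' contributes to the other cells. Cells with fewer than `min_n` complete
#' pairs are reported as missing.
#'
#' @param data Data frame of numeric parameter columns (one row per
#'   vessel), possibly with missing cells.
#' @param min_n Minimum complete pairs per cell (default 3).
#' @return Data frame with one row per unordered pair: `param1`, `param2`,
#'   `r`, `p`, `n`.
#' @export
pearson_pairwise <- function(data, min_n = 3L) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, logical(1))
  data <- data[, num, drop = FALSE]
  params <- names(data)
  if (length(params) < 2L) {
    stop("need at least two numeric parameters", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(params)) {
    for (j in seq_along(params)) {
      if (j <= i) next
      x <- data[[i]]
      y <- data[[j]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- NA_real_
        p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        param1 = params[i], param2 = params[j], r = r, p = p, n = n
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fermentation-parameter correlations at one timepoint
#'
#' Builds the five standard whole-fermentation parameters (cumulative gas,
#' total VFA, log10 bacterial density, total BCVFA, ammonia) for every
#' vessel at a sampling time and returns their pairwise-complete Pearson
#' correlation table. Vessels from all treatments are pooled.
#'
#' @param records Data frame of vessel records.
#' @param time_h Sampling time to analyse.
#' @return As [pearson_pairwise()].
#' @export
fermentation_correlations <- function(records, time_h) {
  r <- records[records$time_h == time_h, , drop = FALSE]
  if (nrow(r) == 0L) stop("no records at time ", time_h, " h", call. = FALSE)
  params <- data.frame(
    cumulative_gas = r$gas_mL,
    total_vfa = total_vfa(r),
    bacterial_density = log10_bacteria(r$bacteria_copies_per_mL),
    total_bcvfa = total_bcvfa(r),
    ammonia = r$nh3_mM
  )
  pearson_pairwise(params)
}

#' Per-analyte, per-timepoint ANOVA and letters
#'
#' Runs [one_way_anova()] and [tukey_hsd()] for each analyte x sampling
#' time with treatment as the single factor, the layout behind row-wise
#' superscripts in fermentation summary tables. No multiplicity correction
#' is applied across analytes or timepoints.
#'
#' @param records Data frame of vessel records.
#' @param analytes Analyte columns; default all numeric analyte columns.
#' @param times Sampling times; default all present.
#' @param alpha Alpha for the letters.
#' @return List with `anova` (data frame: analyte, time_h, f_stat, p_value,
#'   dfs) and `letters` (data frame: analyte, time_h, treatment_id,
#'   letters).
#' @export
anova_by_analyte <- function(records, analytes = NULL, times = NULL,
                             alpha = 0.05) {
  if (is.null(times)) times <- sort(unique(records$time_h))
  if (is.null(analytes)) {
    skip <- c("treatment_id", "replicate", "time_h")
    candidates <- setdiff(names(records), skip)
    analytes <- candidates[vapply(records[candidates], is.numeric,
                                  logical(1))]
  }
  anova_rows <- list()
  letter_rows <- list()
  for (tt in times) {
    r <- records[records$time_h == tt, , drop = FALSE]
    for (a in analytes) {
      x <- r[[a]]
      g <- r$treatment_id
      ok <- !is.na(x)
      if (length(unique(g[ok])) < 2L || !any(table(g[ok]) >= 2L)) next
      av <- one_way_anova(x, g)
      anova_rows[[length(anova_rows) + 1L]] <-
        cbind(data.frame(analyte = a, time_h = tt), av)
      tk <- tukey_hsd(x, g, alpha = alpha)
      letter_rows[[length(letter_rows) + 1L]] <- data.frame(
        analyte = a, time_h = tt,
        treatment_id = names(tk$letters),
        letters = unname(tk$letters)
      )
    }
  }
  list(
    anova = if (length(anova_rows)) do.call(rbind, anova_rows) else
      data.frame(),
    letters = if (length(letter_rows)) do.call(rbind, letter_rows) else
      data.frame()
  )
}
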