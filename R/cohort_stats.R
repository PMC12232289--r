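# Cohort statistics layer: normality screening, two-group contrasts,
# point-by-point OGTT curve comparison, and Spearman correlations of
# derived indices with OSA severity (AHI).
#
# Tests follow small-cohort practice: Lilliefors-corrected
# Kolmogorov-Smirnov normality screening decides between t-test
# (mean +/- SD) and Mann-Whitney (median, IQR); categorical variables use
# Fisher's exact test when any expected cell is below 5, chi-square
# otherwise; curve comparisons are per-timepoint Mann-Whitney without
# multiplicity adjustment (the number of tests and a Benjamini-Hochberg
# column are reported alongside).

.two_groups <- function(cohort) {
  keep <- cohort$osa_group %in% c("mild", "moderate_severe")
  split(cohort[keep, , drop = FALSE], cohort$osa_group[keep])
}

#' Choose between t-test and Mann-Whitney for a two-group contrast
#'
#' Applies Lilliefors-corrected Kolmogorov-Smirnov normality screening
#' (estimated-parameter critical values) to each group at alpha = 0.05.
#' Both groups normal: t-test with mean +/- SD summaries; otherwise
#' Mann-Whitney with median (IQR). Degenerate groups (all values equal, or
#' too few values to assess normality) fall back to Mann-Whitney, with a
#' warning in the degenerate case.
#'
#' @param x,y Numeric vectors, one per group (NAs dropped; >= 3 values each).
#' @param alpha Normality screening level.
#' @return List with `test` (`"t_test"` or `"mann_whitney"`), `normal`
#'   (logical) and the per-group screening p-values (`NA` when not
#'   assessable).
#' @export
choose_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 values per group")
  degen <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degen) {
    warning("degenerate (constant) group; falling back to Mann-Whitney",
            call. = FALSE)
    return(list(test = "mann_whitney", normal = FALSE,
                p_normal = c(NA_real_, NA_real_)))
  }
  pks <- function(v) {
    if (length(v) < 5) return(NA_real_)  # below lilliefors minimum
    nortest::lillie.test(v)$p.value
  }
  p <- c(pks(x), pks(y))
  normal <- !anyNA(p) && all(p > alpha)
  list(test = if (normal) "t_test" else "mann_whitney", normal = normal,
       p_normal = p)
}

.mw_test <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
}

.summarize <- function(v, normal) {
  v <- v[!is.na(v)]
  if (normal)
    sprintf("%.3g ± %.3g", mean(v), stats::sd(v))
  else
    sprintf("%.3g (%.3g-%.3g)", stats::median(v),
            stats::quantile(v, .25, names = FALSE),
            stats::quantile(v, .75, names = FALSE))
}

#' Two-group comparison table (mild vs moderate-severe OSA)
#'
#' One row per variable: distribution-appropriate summaries and a
#' two-sided p-value. Numeric variables route through [choose_test()];
#' categorical variables (character/factor/logical) use Fisher's exact test
#' when any expected cell count is below 5, chi-square otherwise. No
#' multiplicity adjustment is applied to `p` (mirroring common practice for
#' descriptive cohort tables); the number of tests and a Benjamini-Hochberg
#' adjusted column `p_bh` are reported as supplementary output.
#'
#' @param cohort A `cohort_table` (indices computed for index variables).
#' @param variables Character vector of column names to compare.
#' @return Tibble with columns `variable`, `type`, `test`, `summary_mild`,
#'   `summary_modsev`, `n_mild`, `n_modsev`, `p`, `p_bh`; number of tests in
#'   `attr(, "n_tests")`.
#' @export
compare_groups <- function(cohort, variables) {
  gr <- .two_groups(cohort)
  if (length(gr) < 2 || !nrow(gr$mild) || !nrow(gr$moderate_severe))
    stop("need two non-empty analysis groups")
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) stop("variable not found: ", miss[1])

  rows <- lapply(variables, function(v) {
    xm <- gr$mild[[v]]; ym <- gr$moderate_severe[[v]]
    if (is.numeric(xm)) {
      ct <- withCallingHandlers(
        choose_test(xm, ym),
        warning = function(w) invokeRestart("muffleWarning"))
      p <- if (ct$test == "t_test")
        stats::t.test(xm, ym)$p.value
      else
        .mw_test(xm[!is.na(xm)], ym[!is.na(ym)])
      tibble::tibble(variable = v, type = "numeric", test = ct$test,
                     summary_mild = .summarize(xm, ct$normal),
                     summary_modsev = .summarize(ym, ct$normal),
                     n_mild = sum(!is.na(xm)), n_modsev = sum(!is.na(ym)),
                     p = p)
    } else {
      tab <- table(group = rep(c("mild", "modsev"),
                               c(length(xm), length(ym))),
                   value = c(as.character(xm), as.character(ym)))
      expd <- suppressWarnings(stats::chisq.test(tab)$expected)
      use_fisher <- any(expd < 5)
      p <- if (use_fisher) stats::fisher.test(tab)$p.value
      else suppressWarnings(stats::chisq.test(tab)$p.value)
      pct <- function(v) {
        v <- v[!is.na(v)]
        tb <- table(as.character(v))
        paste(sprintf("%s: %d (%.0f%%)", names(tb), tb,
                      100 * tb / sum(tb)), collapse = ", ")
      }
      tibble::tibble(variable = v, type = "categorical",
                     test = if (use_fisher) "fisher" else "chi_square",
                     summary_mild = pct(xm), summary_modsev = pct(ym),
                     n_mild = sum(!is.na(xm)), n_modsev = sum(!is.na(ym)),
                     p = p)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_tests") <- nrow(out)
  out
}

#' Point-by-point OGTT curve comparison
#'
#' Mann-Whitney test at every common sampling time for one analyte, with
#' per-group medians and interquartile ranges — the small-cohort
#' nonparametric alternative to a repeated-measures model. No multiplicity
#' adjustment is applied (a `p_bh` column is supplied alongside);
#' timepoints with fewer than 3 subjects in either group are skipped with a
#' note.
#'
#' @param cohort A `cohort_table` with a `series` list-column.
#' @param analyte `"glucose"`, `"insulin"` or `"cpeptide"`.
#' @return Tibble with one row per sampling time: group medians, IQR
#'   bounds, per-group n, `p`, `p_bh`, `note`.
#' @export
pointwise_curve_compare <- function(cohort,
                                    analyte = c("glucose", "insulin",
                                                "cpeptide")) {
  analyte <- match.arg(analyte)
  gr <- .two_groups(cohort)
  times <- sort(unique(unlist(lapply(cohort$series, `[[`, "times"))))
  pull_at <- function(g, t) {
    v <- vapply(g$series, function(s) {
      i <- match(t, s$times)
      if (is.na(i)) NA_real_ else s[[analyte]][i]
    }, numeric(1))
    v[!is.na(v)]
  }
  rows <- lapply(times, function(t) {
    xm <- pull_at(gr$mild, t); ym <- pull_at(gr$moderate_severe, t)
    base <- tibble::tibble(
      analyte = analyte, time = t,
      n_mild = length(xm), n_modsev = length(ym),
      median_mild = stats::median(xm), iqr_lo_mild = unname(stats::quantile(xm, .25)),
      iqr_hi_mild = unname(stats::quantile(xm, .75)),
      median_modsev = stats::median(ym),
      iqr_lo_modsev = unname(stats::quantile(ym, .25)),
      iqr_hi_modsev = unname(stats::quantile(ym, .75)))
    if (length(xm) < 3 || length(ym) < 3) {
      base$p <- NA_real_
      base$note <- "skipped: fewer than 3 subjects per group"
    } else {
      base$p <- .mw_test(xm, ym)
      base$note <- ""
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Spearman correlation of derived indices with AHI
#'
#' Rank correlation (average ranks for ties) of each requested index
#' against the apnea-hypopnea index across the analysis groups, with
#' two-sided p-values.
#'
#' @param cohort A `cohort_table` with indices computed.
#' @param indices Character vector of index column names.
#' @return Tibble with `index`, `spearman_r`, `p`, `n`, `note` (constant
#'   indices yield `NA` with a note rather than failing the whole table).
#' @export
spearman_vs_ahi <- function(cohort, indices) {
  keep <- cohort$osa_group %in% c("mild", "moderate_severe")
  d <- cohort[keep, , drop = FALSE]
  rows <- lapply(indices, function(v) {
    if (!v %in% names(d)) stop("index not found: ", v)
    ok <- !is.na(d[[v]]) & !is.na(d$ahi)
    x <- d[[v]][ok]; a <- d$ahi[ok]
    if (length(x) < 4)
      return(tibble::tibble(index = v, spearman_r = NA_real_, p = NA_real_,
                            n = length(x), note = "fewer than 4 pairs"))
    if (stats::sd(x) == 0)
      return(tibble::tibble(index = v, spearman_r = NA_real_, p = NA_real_,
                            n = length(x),
                            note = "undefined: constant index"))
    ct <- suppressWarnings(
      stats::cor.test(a, x, method = "spearman", exact = FALSE))
    tibble::tibble(index = v, spearman_r = unname(ct$estimate),
                   p = ct$p.value, n = length(x), note = "")
  })
  dplyr::bind_rows(rows)
}

#' Full cohort statistics report
#'
#' Bundles the group-comparison table (demographics + index panel), the
#' three per-analyte curve tables, and the AHI correlation table.
#'
#' @param cohort A `cohort_table` after [compute_indices()].
#' @param group_vars Variables for [compare_groups()]; defaults to the
#'   available demographic and index columns.
#' @param corr_indices Indices for [spearman_vs_ahi()].
#' @return List of class `cohort_stats_report` with `group_table`,
#'   `curve_table`, `corr_table`.
#' @export
cohort_stats_report <- function(cohort,
                                group_vars = NULL,
                                corr_indices = c("cl_basal", "cl_total",
                                                 "hiri", "total_isr")) {
  if (is.null(group_vars)) {
    cand <- c("age", "sex", "tanner", "weight", "height", "bmi",
              "bmi_zscore", "sld", "homa_ir", "matsuda_wbisi",
              "stumvoll_mcr", "hiri", "cl_basal", "cl_total",
              "glucose_sensitivity", "basal_isr", "total_isr", "glucose_2h")
    group_vars <- intersect(cand, names(cohort))
  }
  structure(
    list(group_table = compare_groups(cohort, group_vars),
         curve_table = dplyr::bind_rows(
           pointwise_curve_compare(cohort, "glucose"),
           pointwise_curve_compare(cohort, "insulin"),
           pointwise_curve_compare(cohort, "cpeptide")),
         corr_table = spearman_vs_ahi(cohort,
                                      intersect(corr_indices,
                                                names(cohort)))),
    class = "cohort_stats_report")
}

#' @export
print.cohort_stats_report <- function(x, ...) {
  cat("<cohort_stats_report>\n")
  cat(sprintf("  group_table: %d variables (%d tests)\n",
              nrow(x$group_table), attr(x$group_table, "n_tests")))
  cat(sprintf("  curve_table: %d analyte-timepoints\n", nrow(x$curve_table)))
  cat(sprintf("  corr_table:  %d indices vs AHI\n", nrow(x$corr_table)))
  invisible(x)
}
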