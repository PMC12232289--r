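# Scalar OGTT indices and OSA severity grading.
#
# All functions take canonical units (glucose mg/dL, insulin pmol/L); the
# indices whose published formulas use uU/mL convert internally with
# 1 uU/mL = 6.0 pmol/L.

PMOL_PER_UU <- 6.0
MGDL_PER_MM <- 18.0

#' Trapezoidal area under a sampled curve
#'
#' Integrates the linear interpolant of `(times, values)` over
#' `[t_start, t_end]`. Window ends may fall between grid points (boundary
#' values are interpolated), but never outside the sampled range: no
#' extrapolation.
#'
#' @param times Sampling times, minutes, strictly increasing.
#' @param values Sampled values.
#' @param t_start,t_end Integration window, minutes.
#' @return Integral in value-minutes.
#' @export
auc_trapezoid <- function(times, values, t_start = min(times),
                          t_end = max(times)) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  if (t_start >= t_end) stop("t_start must be < t_end")
  if (t_start < times[1] || t_end > times[length(times)])
    stop("window error: [", t_start, ",", t_end,
         "] extends beyond the sampled range")
  inside <- times > t_start & times < t_end
  tt <- c(t_start, times[inside], t_end)
  vv <- c(stats::approx(times, values, t_start)$y, values[inside],
          stats::approx(times, values, t_end)$y)
  if (length(tt) < 2) stop("window error: fewer than 2 points in window")
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' HOMA-IR insulin resistance index
#'
#' `(G0 * I0[uU/mL]) / 405` with fasting glucose in mg/dL and fasting
#' insulin converted from pmol/L.
#'
#' @param g0 Fasting glucose, mg/dL (> 0).
#' @param i0 Fasting insulin, pmol/L (> 0).
#' @return Dimensionless index.
#' @export
homa_ir <- function(g0, i0) {
  if (any(g0 <= 0) || any(i0 <= 0)) stop("g0 and i0 must be positive")
  g0 * (i0 / PMOL_PER_UU) / 405
}

#' Matsuda whole-body insulin sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * Gbar * Ibar)` with glucose in mg/dL and insulin
#' in uU/mL; `Gbar`, `Ibar` are time-weighted means (trapezoidal integral
#' divided by the window length) over `[0, window]` minutes.
#'
#' @param series An [ogtt_series()].
#' @param window Mean window in minutes (default 120, the index's classic
#'   formulation; the 3-h variant uses 180).
#' @return Dimensionless index (> 0).
#' @export
matsuda_index <- function(series, window = 120) {
  s <- series
  if (s$times[1] != 0) stop("fasting (t = 0) sample required")
  if (sum(s$times > 0 & s$times <= window) < 3)
    stop("need at least 3 post-load samples within the mean window")
  g0 <- s$glucose[1]
  i0 <- s$insulin[1] / PMOL_PER_UU
  gbar <- auc_trapezoid(s$times, s$glucose, 0, window) / window
  ibar <- auc_trapezoid(s$times, s$insulin / PMOL_PER_UU, 0, window) / window
  10000 / sqrt(g0 * i0 * gbar * ibar)
}

#' Hepatic insulin resistance index (HIRI)
#'
#' Product of the glucose and insulin areas under the curve over the first
#' 30 minutes of the OGTT: `AUC_G(0-30) * AUC_I(0-30)`, insulin in the
#' canonical pmol/L. Reported in raw product units; group comparisons of
#' HIRI are rank-based so the scale is immaterial.
#'
#' @param series An [ogtt_series()] with samples at 0, 10, 20 and 30 min.
#' @return HIRI in (mg/dL min) x (pmol/L min).
#' @export
hiri <- function(series) {
  s <- series
  if (!all(c(0, 10, 20, 30) %in% s$times))
    stop("HIRI undefined: early samples (0, 10, 20, 30 min) required")
  auc_trapezoid(s$times, s$glucose, 0, 30) *
    auc_trapezoid(s$times, s$insulin, 0, 30)
}

#' Fasting and post-load insulin clearance
#'
#' Fasting clearance `CL0 = ISR_fast / I(0)` and post-load clearance
#' `CL180 = AUC_ISR / AUC_I` over the profile window, both in
#' L min^-1 m^-2 (per-m^2 secretion over plasma insulin).
#'
#' @param profile An [isr_profile()].
#' @param series The matching [ogtt_series()] (insulin in pmol/L).
#' @return List with `cl_basal` and `cl_total`, L min^-1 m^-2.
#' @export
insulin_clearance <- function(profile, series) {
  i0 <- series$insulin[series$times == 0]
  if (!length(i0) || i0 <= 0) stop("fasting insulin must be positive")
  t0 <- profile$times[1]
  i_auc <- auc_trapezoid(series$times, series$insulin, t0,
                         min(profile$t_end, max(series$times)))
  if (i_auc <= 0) stop("insulin AUC must be positive")
  list(cl_basal = profile$fasting_isr / i0,
       cl_total = profile$isr_auc / i_auc)
}

#' Beta-cell glucose sensitivity (dose-response slope)
#'
#' Least-squares slope of the secretion rate against plasma glucose over
#' the OGTT: ISR segments are paired with glucose linearly interpolated to
#' the segment midpoints, glucose expressed in mmol/L. This is the
#' dose-response slope only; the rate-sensitivity and potentiation
#' components of full beta-cell models are out of scope and the output is
#' labelled accordingly.
#'
#' @param profile An [isr_profile()].
#' @param series The matching [ogtt_series()].
#' @return List with `slope` (pmol min^-1 m^-2 mM^-1) and `r2` of the fit.
#' @export
glucose_sensitivity <- function(profile, series) {
  widths <- diff(c(profile$times, profile$t_end))
  mids <- profile$times + widths / 2
  g <- stats::approx(series$times, series$glucose, xout = mids,
                     rule = 2)$y / MGDL_PER_MM
  if (stats::var(g) <= 0)
    stop("undefined slope: glucose has zero variance over the window")
  fit <- stats::lm.fit(cbind(1, g), profile$isr)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((profile$isr - mean(profile$isr))^2)
  list(slope = unname(fit$coefficients[2]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Stumvoll metabolic clearance rate
#'
#' Demographic Stumvoll MCR equation
#' `18.8 - 0.271 BMI - 0.0052 I120 - 0.27 G90` with insulin at 120 min in
#' pmol/L and glucose at 90 min in mmol/L; output in mL min^-1 kg^-1.
#'
#' @param series An [ogtt_series()] with samples at 90 and 120 min.
#' @param subject List or row with `bmi` (kg/m^2).
#' @return Clearance, mL min^-1 kg^-1.
#' @export
stumvoll_mcr <- function(series, subject) {
  bmi <- subject$bmi
  if (is.null(bmi) || is.na(bmi)) stop("bmi required")
  if (!all(c(90, 120) %in% series$times))
    stop("samples at 90 and 120 min required")
  i120 <- series$insulin[series$times == 120]
  g90 <- series$glucose[series$times == 90] / MGDL_PER_MM
  18.8 - 0.271 * bmi - 0.0052 * i120 - 0.27 * g90
}

#' Grade obstructive sleep apnea severity from the AHI
#'
#' AHI <= 1: no OSA (excluded from the two-group analysis); 1 < AHI <= 5:
#' mild; 5 < AHI < 10: moderate; AHI >= 10: severe. Moderate and severe
#' merge into the `moderate_severe` analysis group.
#'
#' @param ahi Apnea-hypopnea index, events/hour, `>= 0` (vectorized).
#' @return List of two character vectors: `label` in
#'   `none/mild/moderate/severe` and `analysis_group` in
#'   `excluded/mild/moderate_severe`.
#' @export
classify_osa <- function(ahi) {
  if (any(is.na(ahi)) || any(ahi < 0)) stop("ahi must be >= 0")
  label <- ifelse(ahi <= 1, "none",
           ifelse(ahi <= 5, "mild",
           ifelse(ahi < 10, "moderate", "severe")))
  group <- ifelse(label == "none", "excluded",
           ifelse(label == "mild", "mild", "moderate_severe"))
  list(label = label, analysis_group = group)
}

#' Compute the full index panel for every subject in a cohort
#'
#' Runs, per subject: kinetic standardization, C-peptide deconvolution, and
#' every scalar index. Subjects whose series lack the samples an index
#' needs get `NA` for that index (with a note collected in
#' `attr(, "index_notes")`); a failed deconvolution quarantines all
#' ISR-derived indices for that subject.
#'
#' @param cohort A `cohort_table` with a `series` list-column.
#' @param status Kinetic standardization class (`"obese"` default for a
#'   paediatric obesity cohort; see [standardize_params()]).
#' @param table Kinetic population table ([kinetic_table()]).
#' @param bsa_formula Passed to [bsa_m2()].
#' @param lambda,dt Passed to [deconvolve_isr()].
#' @param matsuda_window Passed to [matsuda_index()].
#' @return The cohort with an `isr` list-column of [isr_profile()]s and one
#'   numeric column per index: `homa_ir`, `matsuda_wbisi`, `stumvoll_mcr`,
#'   `hiri`, `cl_basal`, `cl_total`, `glucose_sensitivity`, `gs_r2`,
#'   `basal_isr`, `total_isr`, `isr_auc`, `glucose_2h`, `fit_rmse`.
#' @export
compute_indices <- function(cohort, status = "obese",
                            table = kinetic_table(),
                            bsa_formula = "mosteller", lambda = "auto",
                            dt = 5, matsuda_window = 120) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- nrow(cohort)
  cols <- c("homa_ir", "matsuda_wbisi", "stumvoll_mcr", "hiri", "cl_basal",
            "cl_total", "glucose_sensitivity", "gs_r2", "basal_isr",
            "total_isr", "isr_auc", "glucose_2h", "fit_rmse")
  out <- stats::setNames(
    as.data.frame(matrix(NA_real_, n, length(cols))), cols)
  profs <- vector("list", n)
  notes <- list()
  note <- function(id, msg)
    notes[[length(notes) + 1L]] <<- tibble::tibble(subject_id = id,
                                                   note = msg)
  for (i in seq_len(n)) {
    s <- cohort$series[[i]]
    sub <- as.list(cohort[i, setdiff(names(cohort), c("series", "isr"))])
    id <- cohort$subject_id[i]
    grab <- function(expr) tryCatch(expr, error = function(e) {
      note(id, conditionMessage(e)); NA_real_
    })
    out$homa_ir[i] <- grab(homa_ir(s$glucose[1], s$insulin[1]))
    out$matsuda_wbisi[i] <- grab(matsuda_index(s, matsuda_window))
    out$stumvoll_mcr[i] <- grab(stumvoll_mcr(s, sub))
    out$hiri[i] <- grab(hiri(s))
    out$glucose_2h[i] <-
      if (120 %in% s$times) s$glucose[s$times == 120] else NA_real_

    prof <- tryCatch({
      params <- standardize_params(sub, status, table, bsa_formula)
      deconvolve_isr(s, params = params, lambda = lambda, dt = dt)
    }, error = function(e) {
      note(id, paste("deconvolution failed:", conditionMessage(e)))
      NULL
    })
    profs[[i]] <- prof
    if (!is.null(prof)) {
      sm <- isr_summaries(prof)
      out$basal_isr[i] <- sm$fasting_isr
      out$total_isr[i] <- sm$total_isr
      out$isr_auc[i] <- sm$isr_auc
      out$fit_rmse[i] <- prof$fit_rmse
      cl <- grab(insulin_clearance(prof, s))
      if (is.list(cl)) {
        out$cl_basal[i] <- cl$cl_basal
        out$cl_total[i] <- cl$cl_total
      }
      gs <- grab(glucose_sensitivity(prof, s))
      if (is.list(gs)) {
        out$glucose_sensitivity[i] <- gs$slope
        out$gs_r2[i] <- gs$r2
      }
    }
  }
  res <- dplyr::bind_cols(cohort, tibble::as_tibble(out))
  res$isr <- profs
  class(res) <- class(cohort)
  attr(res, "rejects") <- attr(cohort, "rejects")
  attr(res, "index_notes") <- if (length(notes)) dplyr::bind_rows(notes)
  else tibble::tibble(subject_id = character(), note = character())
  res
}
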