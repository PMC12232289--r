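# Forward two-compartment C-peptide kinetic model.
#
# C-peptide is co-secreted with insulin 1:1 but not extracted by the liver,
# so its plasma concentration is the convolution of the pancreatic secretion
# rate with a biexponential impulse response whose parameters are taken from
# a population standardization (Van Cauter-type) keyed by clinical status and
# scaled to the subject's body-surface area. The same kernel is used to
# simulate C-peptide from a known secretion profile and, inverted, to
# estimate secretion from measured C-peptide (see deconvolve_isr).

#' Body-surface area
#'
#' @param weight Weight, kg.
#' @param height Height, cm.
#' @param formula `"mosteller"` (default, sqrt(w*h/3600)), `"dubois"`
#'   (0.007184 w^0.425 h^0.725) or `"haycock"` (0.024265 w^0.5378 h^0.3964).
#' @return BSA in m^2.
#' @export
bsa_m2 <- function(weight, height, formula = c("mosteller", "dubois",
                                               "haycock")) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  switch(match.arg(formula),
         mosteller = sqrt(weight * height / 3600),
         dubois    = 0.007184 * weight^0.425 * height^0.725,
         haycock   = 0.024265 * weight^0.5378 * height^0.3964)
}

#' Load the population kinetic parameter table
#'
#' The table ships as a versioned YAML file with one block per clinical
#' status (`normal`, `obese`, `diabetic`); see
#' `system.file("extdata", "cpeptide_kinetics.yaml", package = "ogttclear")`.
#'
#' @param path Optional path to an alternative YAML table.
#' @return Named list of status blocks, with the file's content hash in
#'   `attr(, "hash")` for run logs.
#' @export
kinetic_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cpeptide_kinetics.yaml",
                        package = "ogttclear")
  tab <- yaml::read_yaml(path)
  out <- tab$statuses
  attr(out, "hash") <- rlang::hash(tab)
  out
}

#' Two-compartment C-peptide kinetic parameters for one subject
#'
#' @param frac_short Fraction of the impulse response carried by the fast
#'   exponential, in (0, 1).
#' @param halflife_short,halflife_long Half-lives of the fast and slow
#'   exponentials, minutes; `halflife_long > halflife_short > 0`.
#' @param vd Distribution volume, litres.
#' @param bsa Body-surface area, m^2.
#' @return Object of class `cpeptide_params` with the five fields plus the
#'   derived rate constants `k_short`, `k_long` (1/min).
#' @export
cpeptide_params <- function(frac_short, halflife_short, halflife_long, vd,
                            bsa) {
  stopifnot(frac_short > 0, frac_short < 1,
            halflife_short > 0, halflife_long > halflife_short,
            vd > 0, bsa > 0)
  structure(list(frac_short = frac_short,
                 halflife_short = halflife_short,
                 halflife_long = halflife_long,
                 k_short = log(2) / halflife_short,
                 k_long = log(2) / halflife_long,
                 vd = vd, bsa = bsa),
            class = "cpeptide_params")
}

#' @export
print.cpeptide_params <- function(x, ...) {
  cat(sprintf(
    "<cpeptide_params f=%.2f t1/2=%.2f/%.1f min vd=%.2f L bsa=%.2f m2 MCR=%.3f L/min>\n",
    x$frac_short, x$halflife_short, x$halflife_long, x$vd, x$bsa,
    cpeptide_mcr(x)))
  invisible(x)
}

# time integral of vd*h(t) over [0, Inf): f/k1 + (1-f)/k2, minutes.
# C_ss = S_abs * .ss_minutes / vd for constant absolute secretion S_abs.
.ss_minutes <- function(p)
  p$frac_short / p$k_short + (1 - p$frac_short) / p$k_long

#' Metabolic clearance rate implied by the kinetic parameters
#'
#' At steady state a constant absolute secretion `S` (pmol/min) gives plasma
#' concentration `S / MCR`, so `MCR = vd / (f/k_short + (1-f)/k_long)`
#' (litres/min).
#'
#' @param params A [cpeptide_params()] object.
#' @return Clearance in L/min.
#' @export
cpeptide_mcr <- function(params) params$vd / .ss_minutes(params)

#' Standardize kinetic parameters to a subject
#'
#' Looks up the population block for `status` and scales the distribution
#' volume to the subject's body-surface area (computed from weight and
#' height).
#'
#' @param subject List or one-row data frame with `weight` (kg) and `height`
#'   (cm).
#' @param status `"normal"`, `"obese"` or `"diabetic"`.
#' @param table Population table from [kinetic_table()].
#' @param bsa_formula Passed to [bsa_m2()].
#' @return A [cpeptide_params()] object.
#' @export
standardize_params <- function(subject, status = "obese",
                               table = kinetic_table(),
                               bsa_formula = "mosteller") {
  if (!status %in% names(table))
    stop("unknown status '", status, "' (known: ",
         paste(names(table), collapse = ", "), ")")
  w <- subject$weight; h <- subject$height
  if (is.null(w) || is.null(h) || is.na(w) || is.na(h))
    stop("subject weight and height are required")
  blk <- table[[status]]
  bsa <- bsa_m2(w, h, bsa_formula)
  cpeptide_params(frac_short = blk$frac_short,
                  halflife_short = blk$halflife_short_min,
                  halflife_long = blk$halflife_long_min,
                  vd = blk$vd_slope_l_per_m2 * bsa + blk$vd_intercept_l,
                  bsa = bsa)
}

#' Impulse response of the two-compartment C-peptide model
#'
#' Plasma concentration at time `t` after an instantaneous injection of one
#' pmol: `h(t) = (1/vd) [f exp(-k_short t) + (1-f) exp(-k_long t)]`;
#' strictly positive, strictly decreasing, `h(0) = 1/vd`.
#'
#' @param params A [cpeptide_params()] object.
#' @param t Time since injection, minutes, `>= 0` (vectorized).
#' @return pmol/L per pmol injected.
#' @export
impulse_response <- function(params, t) {
  if (any(t < 0)) stop("t must be >= 0")
  f <- params$frac_short
  (f * exp(-params$k_short * t) + (1 - f) * exp(-params$k_long * t)) /
    params$vd
}

# vd * integral_0^t h(u) du (dimension: minutes); shared by the forward
# model and the deconvolution design matrix.
.cum_response <- function(params, t) {
  f <- params$frac_short
  f * (1 - exp(-params$k_short * t)) / params$k_short +
    (1 - f) * (1 - exp(-params$k_long * t)) / params$k_long
}

# normalized decay of the fasting steady-state pool: D(0)=1, D -> 0;
# C_pre(t) = c0 * D(t) when secretion before t=0 was constant at the fasting
# rate implied by c0.
.fasting_decay <- function(params, t) {
  f <- params$frac_short
  (f * exp(-params$k_short * t) / params$k_short +
     (1 - f) * exp(-params$k_long * t) / params$k_long) / .ss_minutes(params)
}

#' Fasting secretion rate implied by a fasting C-peptide level
#'
#' Under the steady-state assumption at t = 0, the fasting concentration
#' `c0` pins the fasting secretion rate:
#' `ISR_fast = c0 * MCR / bsa` (pmol min^-1 m^-2).
#'
#' @param c0 Fasting C-peptide, pmol/L.
#' @param params A [cpeptide_params()] object.
#' @return Fasting ISR, pmol min^-1 m^-2.
#' @export
fasting_isr_from_c0 <- function(c0, params)
  c0 * cpeptide_mcr(params) / params$bsa

#' Simulate C-peptide from a known secretion profile
#'
#' Evaluates the forward convolution
#' `C(t) = c0 D(t) + int_0^t h(t-s) ISR_abs(s) ds`
#' exactly (piecewise integration of the exponentials over the profile's
#' piecewise-constant segments; no quadrature error). `D(t)` is the decay of
#' the fasting pool under the steady-state-at-t=0 assumption, and
#' `ISR_abs = isr * bsa` converts the per-m^2 profile to pmol/min.
#'
#' @param isr An [isr_profile()] (per-m^2 piecewise-constant secretion).
#' @param params A [cpeptide_params()] object.
#' @param c0 Fasting C-peptide, pmol/L (`>= 0`).
#' @param out_times Times at which to evaluate, minutes (default: the
#'   canonical OGTT grid).
#' @return Numeric vector of C-peptide concentrations, pmol/L.
#' @export
forward_cpeptide <- function(isr, params, c0, out_times = ogtt_grid()) {
  stopifnot(inherits(isr, "isr_profile"), c0 >= 0)
  if (any(out_times < 0)) stop("output times must be >= 0")
  if (max(out_times) > isr$t_end + 1e-9)
    stop("grid error: requested times extend beyond the ISR profile (t_end = ",
         isr$t_end, ")")
  a <- isr$times
  b <- c(a[-1], isr$t_end)
  # contribution matrix: out_times x segments
  TT <- outer(out_times, a, "-")
  TB <- pmax(outer(out_times, b, "-"), 0)
  act <- TT > 0
  TT[!act] <- 0
  K <- (.cum_response(params, TT) - .cum_response(params, TB)) *
    (params$bsa / params$vd)
  K[!act] <- 0
  drop(K %*% isr$isr) + c0 * .fasting_decay(params, out_times)
}
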