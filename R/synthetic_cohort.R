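# Synthetic OGTT cohort generator with known ground truth.
#
# Emulates the structure the pipeline is designed to detect: a paediatric
# obesity cohort split into mild and moderate-severe OSA by AHI, where
# subject-specific insulin clearance falls with AHI
# (CL = cl_ref * exp(ahi_effect * log1p(AHI)) * subject factor) while
# beta-cell behaviour is AHI-independent. Glucose follows a template
# excursion; true ISR responds linearly to glucose above baseline
# (dose-response slope); C-peptide is the exact forward convolution of the
# true ISR; insulin follows a single post-hepatic pool with the
# subject-specific clearance. Lower clearance therefore raises insulin and
# HIRI without touching secretion — the generator's only AHI coupling is
# through clearance.
#
# All randomness flows from one seed through named substreams
# (anthropometry, ahi, curves, noise), so individual components can be held
# fixed across scenarios.

.derive_seed <- function(seed, name) {
  off <- sum(utf8ToInt(name)) * 7919
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483629 + 1)
}

#' Simulation configuration
#'
#' Defaults describe a 70-subject paediatric obesity cohort (36 mild, 34
#' moderate-severe OSA) with fasting glucose ~66 mg/dL, fasting insulin
#' ~90 pmol/L, basal secretion 100 pmol min^-1 m^-2, beta-cell
#' dose-response slope 140 pmol min^-1 m^-2 mM^-1 and reference clearance
#' 1.15 L min^-1 m^-2; `ahi_effect = -0.168` produces a ~20% median
#' clearance deficit between the default AHI ranges (see
#' [ahi_effect_for_deficit()]).
#'
#' @param n_mild,n_modsev Group sizes.
#' @param seed Master seed; every substream derives from it.
#' @param ahi_mild_range,ahi_modsev_range AHI ranges (events/hour); draws
#'   are log-uniform within each range (AHI is right-skewed).
#' @param glucose_template Mean excursion parameters: `baseline` and `peak`
#'   (mg/dL), `peak_time` (min), `return_rate` (1/min, post-peak
#'   exponential relaxation), plus between-subject variation
#'   (`baseline_sd` mg/dL, `amp_cv`, `peak_time_sd` min).
#' @param beta_cell `basal_isr` (pmol min^-1 m^-2), `glucose_slope`
#'   (pmol min^-1 m^-2 mM^-1), `cv` (between-subject, lognormal).
#' @param clearance_model `cl_ref` (L min^-1 m^-2), `ahi_effect` (per
#'   log1p(AHI) unit, `<= 0`), `cv` (between-subject, lognormal).
#' @param noise Assay coefficients of variation (multiplicative, lognormal)
#'   for the three analytes.
#' @param anthropometry Age (normal, years), BMI (lognormal, kg/m^2),
#'   height-for-age and BMI z-score parameters.
#' @param insulin_kinetics `post_hepatic_fraction` (hepatic first-pass
#'   survival, ~0.5; absorbed into the clearance scale so the recorded true
#'   clearance is the quantity the pipeline's CL180 ratio estimates) and
#'   `vd_per_kg` (insulin distribution volume, L/kg).
#' @param dt Simulation subgrid step, minutes.
#' @param sample_times Observation grid, minutes.
#' @param status Kinetic standardization class for the C-peptide kernel.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_mild = 36, n_modsev = 34, seed = 1,
                       ahi_mild_range = c(1, 5),
                       ahi_modsev_range = c(5, 25),
                       glucose_template = list(),
                       beta_cell = list(),
                       clearance_model = list(),
                       noise = list(),
                       anthropometry = list(),
                       insulin_kinetics = list(),
                       dt = 5, sample_times = ogtt_grid(),
                       status = "obese") {
  merge_def <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    n_mild = n_mild, n_modsev = n_modsev, seed = as.integer(seed),
    ahi_mild_range = ahi_mild_range, ahi_modsev_range = ahi_modsev_range,
    glucose_template = merge_def(glucose_template, list(
      baseline = 66, peak = 136, peak_time = 35, return_rate = 0.006,
      baseline_sd = 5, amp_cv = 0.2, peak_time_sd = 6)),
    beta_cell = merge_def(beta_cell, list(
      basal_isr = 100, glucose_slope = 140, cv = 0.25)),
    clearance_model = merge_def(clearance_model, list(
      cl_ref = 1.15, ahi_effect = -0.168, cv = 0.25)),
    noise = merge_def(noise, list(
      glucose = 0.02, insulin = 0.05, cpeptide = 0.04)),
    anthropometry = merge_def(anthropometry, list(
      age_mean = 11.7, age_sd = 2.8, age_range = c(6, 17.9),
      bmi_median = 34, bmi_log_sd = 0.12,
      height_intercept = 100, height_slope = 4.6, height_sd = 7,
      bmi_z_mean = 3.6, bmi_z_sd = 0.35, sld_prev = 0.77)),
    insulin_kinetics = merge_def(insulin_kinetics, list(
      post_hepatic_fraction = 0.5, vd_per_kg = 0.141)),
    dt = dt, sample_times = sample_times, status = status)
  stopifnot(cfg$n_mild >= 0, cfg$n_modsev >= 0,
            cfg$ahi_mild_range[1] >= 1, cfg$ahi_mild_range[2] <= 5,
            cfg$ahi_modsev_range[1] >= 5,
            cfg$clearance_model$cl_ref > 0,
            cfg$clearance_model$ahi_effect <= 0,
            cfg$glucose_template$baseline > 0,
            cfg$glucose_template$peak >= cfg$glucose_template$baseline,
            cfg$dt > 0, cfg$sample_times[1] == 0,
            all(cfg$sample_times %% cfg$dt == 0))
  structure(cfg, class = "sim_config")
}

#' AHI effect size producing a target median clearance deficit
#'
#' Solves `exp(a * (log1p(m_ms) - log1p(m_mild))) = 1 - deficit` for the
#' clearance model's `ahi_effect`, where `m_g` is the median of the
#' log-uniform AHI draw in group `g` (the geometric mean of the range).
#'
#' @param deficit Target relative deficit of the moderate-severe median
#'   clearance, e.g. `0.2` for a 20% deficit.
#' @param config A [sim_config()] supplying the AHI ranges.
#' @return The `ahi_effect` value (negative).
#' @export
ahi_effect_for_deficit <- function(deficit, config = sim_config()) {
  m_mild <- sqrt(prod(config$ahi_mild_range))
  m_ms <- sqrt(prod(config$ahi_modsev_range))
  log(1 - deficit) / (log1p(m_ms) - log1p(m_mild))
}

# template excursion shape: smooth rise to 1 at the peak time, exponential
# relaxation after it
.glucose_shape <- function(t, tp, rate) {
  ifelse(t <= tp, sin(pi * t / (2 * tp))^2, exp(-rate * (t - tp)))
}

# one substream-resolved draw table for n subjects
.draw_cohort <- function(config) {
  n1 <- config$n_mild; n2 <- config$n_modsev; n <- n1 + n2
  if (n == 0) stop("config error: zero total subjects")
  an <- config$anthropometry
  sdlog <- function(cv) sqrt(log(1 + cv^2))

  set.seed(.derive_seed(config$seed, "anthropometry"))
  age <- pmin(pmax(stats::rnorm(n, an$age_mean, an$age_sd),
                   an$age_range[1]), an$age_range[2])
  sex <- ifelse(stats::runif(n) < 0.5, "M", "F")
  bmi <- an$bmi_median * exp(stats::rnorm(n, 0, an$bmi_log_sd))
  height <- an$height_intercept + an$height_slope * age +
    stats::rnorm(n, 0, an$height_sd)
  weight <- bmi * (height / 100)^2
  bmi_z <- stats::rnorm(n, an$bmi_z_mean, an$bmi_z_sd)
  tanner <- ifelse(age < 10, "I", ifelse(age < 13, "II-III", "IV-V"))
  sld <- stats::runif(n) < an$sld_prev

  set.seed(.derive_seed(config$seed, "ahi"))
  lu <- function(k, r) exp(stats::runif(k, log(r[1]), log(r[2])))
  ahi <- c(pmin(pmax(lu(n1, config$ahi_mild_range),
                     config$ahi_mild_range[1] + 1e-9),
                config$ahi_mild_range[2]),
           pmin(pmax(lu(n2, config$ahi_modsev_range),
                     config$ahi_modsev_range[1] + 1e-9),
                config$ahi_modsev_range[2]))

  set.seed(.derive_seed(config$seed, "curves"))
  gt <- config$glucose_template; bc <- config$beta_cell
  cm <- config$clearance_model
  base_g <- gt$baseline + stats::rnorm(n, 0, gt$baseline_sd)
  amp <- (gt$peak - gt$baseline) * exp(stats::rnorm(n, 0, sdlog(gt$amp_cv)))
  tp <- pmax(gt$peak_time + stats::rnorm(n, 0, gt$peak_time_sd), 20)
  basal_isr <- bc$basal_isr * exp(stats::rnorm(n, 0, sdlog(bc$cv)))
  slope <- bc$glucose_slope * exp(stats::rnorm(n, 0, sdlog(bc$cv)))
  cl <- cm$cl_ref * exp(cm$ahi_effect * log1p(ahi)) *
    exp(stats::rnorm(n, 0, sdlog(cm$cv)))

  set.seed(.derive_seed(config$seed, "noise"))
  k <- length(config$sample_times)
  zg <- matrix(stats::rnorm(n * k), n, k)
  zi <- matrix(stats::rnorm(n * k), n, k)
  zc <- matrix(stats::rnorm(n * k), n, k)

  list(n = n,
       tab = tibble::tibble(
         subject_id = sprintf("S%03d", seq_len(n)),
         group = rep(c("mild", "moderate_severe"), c(n1, n2)),
         age = age, sex = sex, bmi = bmi, height = height, weight = weight,
         bmi_zscore = bmi_z, tanner = tanner, sld = sld, ahi = ahi,
         base_g = base_g, amp = amp, tp = tp, basal_isr = basal_isr,
         slope = slope, true_cl = cl),
       zg = zg, zi = zi, zc = zc)
}

# deterministic subject synthesis from one resolved draw row
.synthesize_subject <- function(config, d, zg, zi, zc, kin_table) {
  gt <- config$glucose_template
  ik <- config$insulin_kinetics
  dt <- config$dt
  t_end <- max(config$sample_times)
  sub <- list(subject_id = d$subject_id, age = d$age, sex = d$sex,
              weight = d$weight, height = d$height, bmi = d$bmi,
              bmi_zscore = d$bmi_zscore, tanner = d$tanner, ahi = d$ahi,
              sld = d$sld)
  params <- standardize_params(sub, config$status, kin_table)

  gfun <- function(t) d$base_g + d$amp * .glucose_shape(t, d$tp,
                                                        gt$return_rate)
  seg_a <- seq(0, t_end - dt, by = dt)
  mids <- seg_a + dt / 2
  isr_true <- pmax(d$basal_isr +
                     d$slope * (gfun(mids) - gfun(0)) / 18, 0)
  prof <- isr_profile(times = seg_a, isr = isr_true, bsa = params$bsa,
                      fasting_isr = d$basal_isr, t_end = t_end)

  c0 <- d$basal_isr * params$bsa * .ss_minutes(params) / params$vd
  cpep_clean <- forward_cpeptide(prof, params, c0,
                                 out_times = config$sample_times)

  # single post-hepatic insulin pool, solved exactly per subgrid segment
  V <- ik$vd_per_kg * d$weight
  fph <- ik$post_hepatic_fraction
  kel <- d$true_cl * fph * params$bsa / V
  S_abs <- isr_true * params$bsa
  subgrid <- seq(0, t_end, by = dt)
  I <- numeric(length(subgrid))
  I[1] <- d$basal_isr / d$true_cl
  ed <- exp(-kel * dt)
  for (j in seq_along(seg_a))
    I[j + 1] <- I[j] * ed + (fph * S_abs[j] / V / kel) * (1 - ed)
  ins_clean <- I[match(config$sample_times, subgrid)]
  g_clean <- gfun(config$sample_times)

  nz <- config$noise
  series <- ogtt_series(d$subject_id, config$sample_times,
                        glucose = g_clean * exp(nz$glucose * zg),
                        insulin = ins_clean * exp(nz$insulin * zi),
                        cpeptide = cpep_clean * exp(nz$cpeptide * zc))
  truth <- tibble::tibble(subject_id = d$subject_id, group = d$group,
                          ahi = d$ahi, true_cl = d$true_cl,
                          basal_isr = d$basal_isr, glucose_slope = d$slope,
                          bsa = params$bsa, c0 = c0,
                          fasting_insulin = I[1],
                          isr_auc_true = prof$isr_auc)
  list(subject = sub, series = series, truth = truth, isr_true = prof)
}

#' Simulate a single subject
#'
#' Draws one subject through the same substream machinery as
#' [simulate_cohort()] (a cohort of size one in the requested group).
#'
#' @param config A [sim_config()].
#' @param group `"mild"` or `"moderate_severe"`.
#' @return List with `subject` (demographics), `series` ([ogtt_series()]),
#'   `truth` (one-row tibble of generator parameters) and `isr_true` (the
#'   noiseless [isr_profile()]).
#' @export
simulate_subject <- function(config = sim_config(),
                             group = c("mild", "moderate_severe")) {
  group <- match.arg(group)
  cfg <- config
  cfg$n_mild <- if (group == "mild") 1L else 0L
  cfg$n_modsev <- if (group == "mild") 0L else 1L
  dr <- .draw_cohort(cfg)
  .synthesize_subject(cfg, dr$tab[1, ], dr$zg[1, ], dr$zi[1, ], dr$zc[1, ],
                      kinetic_table())
}

#' Simulate a full cohort with ground truth
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a `cohort_table` ready for
#'   [compute_indices()]) and `truth` (per-subject generator parameters,
#'   aligned by `subject_id`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dr <- .draw_cohort(config)
  kin <- kinetic_table()
  out <- lapply(seq_len(dr$n), function(i)
    .synthesize_subject(config, dr$tab[i, ], dr$zg[i, ], dr$zi[i, ],
                        dr$zc[i, ], kin))
  cohort <- dplyr::bind_rows(lapply(out, function(o)
    tibble::tibble(subject_id = o$subject$subject_id, age = o$subject$age,
                   sex = o$subject$sex, weight = o$subject$weight,
                   height = o$subject$height, bmi = o$subject$bmi,
                   bmi_zscore = o$subject$bmi_zscore,
                   tanner = o$subject$tanner, ahi = o$subject$ahi,
                   sld = o$subject$sld, series = list(o$series))))
  list(cohort = as_cohort_table(cohort),
       truth = dplyr::bind_rows(lapply(out, `[[`, "truth")))
}
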