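# Hand oracles for the toy series used across the index tests:
#   glucose {0:90, 10:120, 20:140, 30:150} -> trapezoid panels
#     (90+120)/2*10 + (120+140)/2*10 + (140+150)/2*10 = 3800
#   insulin {0:60, 10:90, 20:60, 30:30} ->
#     (60+90)/2*10 + (90+60)/2*10 + (60+30)/2*10 = 1950

test_that("trapezoidal AUC matches hand sums and is exact on lines", {
  expect_equal(auc_trapezoid(c(0, 10, 20, 30), c(90, 120, 140, 150), 0, 30),
               3800, tolerance = 1e-12)
  expect_equal(auc_trapezoid(c(0, 10, 20, 30), rep(7, 4), 0, 30), 210)
  tt <- c(0, 10, 20, 30, 60, 90)
  expect_equal(auc_trapezoid(tt, 2 * tt + 5, 0, 90),
               90^2 + 5 * 90, tolerance = 1e-12)  # integral of 2t+5
  # interior windows interpolate the ends, never extrapolate
  expect_equal(auc_trapezoid(c(0, 10), c(0, 10), 2, 8), 30)
  expect_error(auc_trapezoid(c(0, 10), c(1, 1), 0, 20), "window error")
  expect_error(auc_trapezoid(c(0, 10), c(1, 1), 10, 0), "t_start")
})

test_that("HOMA-IR reproduces its closed form and scales linearly", {
  expect_equal(homa_ir(90, 108), 4.0, tolerance = 1e-12)
  expect_equal(homa_ir(90, 216), 8.0, tolerance = 1e-12)
  expect_lt(homa_ir(90, 1e-4), 1e-5)
  expect_error(homa_ir(0, 108), "positive")
})

test_that("Matsuda index has the flat-curve closed form", {
  # flat curves: G = 90 mg/dL, I = 60 pmol/L = 10 uU/mL everywhere
  expect_equal(matsuda_index(flat_series(g = 90, ins = 60)),
               10000 / (90 * 10), tolerance = 1e-12)
  # scaling every insulin value by k scales sqrt(I0 * Ibar) by k, so the
  # index divides by k (here k = 4)
  s4 <- flat_series(g = 90, ins = 240)
  expect_equal(matsuda_index(s4), 10000 / (90 * 10) / 4, tolerance = 1e-12)
  expect_gt(matsuda_index(flat_series(g = 150, ins = 400)), 0)
})

test_that("HIRI composes the two early AUC oracles bilinearly", {
  tt <- ogtt_grid()
  g <- c(90, 120, 140, 150, 140, 120, 110, 100, 95)
  i1 <- c(60, 90, 60, 30, 30, 30, 30, 30, 30)
  s <- ogtt_series("t", tt, g, i1, rep(600, 9))
  expect_equal(hiri(s), 3800 * 1950, tolerance = 1e-9)
  s2 <- ogtt_series("t", tt, g, 2 * i1, rep(600, 9))
  expect_equal(hiri(s2), 2 * hiri(s), tolerance = 1e-12)
  const <- flat_series(g = 100, ins = 100)
  expect_equal(hiri(const), 3000 * 3000, tolerance = 1e-12)
  smiss <- ogtt_series("m", c(0, 30, 60, 90, 120), rep(90, 5), rep(60, 5),
                       rep(600, 5))
  expect_error(hiri(smiss), "early samples")
})

test_that("HIRI increases under pointwise increase of early inputs", {
  tt <- ogtt_grid()
  g <- c(90, 120, 140, 150, 140, 120, 110, 100, 95)
  i1 <- c(60, 90, 100, 110, 90, 70, 60, 50, 40)
  base <- hiri(ogtt_series("a", tt, g, i1, rep(600, 9)))
  g_up <- g + c(0, 5, 5, 5, rep(0, 5))
  i_up <- i1 + c(3, 3, 3, 3, rep(0, 5))
  expect_gt(hiri(ogtt_series("b", tt, g_up, i1, rep(600, 9))), base)
  expect_gt(hiri(ogtt_series("c", tt, g, i_up, rep(600, 9))), base)
})

test_that("insulin clearance ratios have unit closed forms", {
  p <- default_params()
  prof <- isr_profile(seq(0, 175, 5), rep(80, 36), p$bsa,
                      fasting_isr = 100, t_end = 180)
  s <- flat_series(ins = 80)
  cl <- insulin_clearance(prof, s)
  expect_equal(cl$cl_total, 1.0, tolerance = 1e-12)
  expect_equal(cl$cl_basal, 100 / 80, tolerance = 1e-12)
  half <- flat_series(ins = 40)
  cl2 <- insulin_clearance(prof, half)
  expect_equal(cl2$cl_total, 2 * cl$cl_total, tolerance = 1e-12)
  expect_equal(cl2$cl_basal, 2 * cl$cl_basal, tolerance = 1e-12)
})

test_that("glucose sensitivity recovers an exactly linear dose-response", {
  p <- default_params()
  tt <- ogtt_grid()
  g <- c(90, 110, 130, 150, 160, 140, 120, 105, 95)
  s <- ogtt_series("lin", tt, g, rep(60, 9), rep(600, 9))
  a <- seq(0, 175, by = 5)
  gmid <- stats::approx(tt, g, xout = a + 2.5, rule = 2)$y / 18
  prof <- isr_profile(a, 40 + 140 * gmid, p$bsa, t_end = 180)
  gs <- glucose_sensitivity(prof, s)
  expect_equal(gs$slope, 140, tolerance = 1e-9)
  expect_equal(gs$r2, 1, tolerance = 1e-9)
  flatp <- isr_profile(a, rep(75, 36), p$bsa, t_end = 180)
  expect_equal(glucose_sensitivity(flatp, s)$slope, 0, tolerance = 1e-9)
  expect_error(glucose_sensitivity(prof, flat_series()), "zero variance")
})

test_that("dose-response slope is recovered from noisy simulated subjects", {
  cfg <- sim_config(seed = 9, n_mild = 25, n_modsev = 25,
                    beta_cell = list(cv = 0))   # every subject has slope 140
  coh <- compute_indices(simulate_cohort(cfg)$cohort)
  med <- stats::median(coh$glucose_sensitivity, na.rm = TRUE)
  expect_lt(abs(med - 140) / 140, 0.15)
})

test_that("Stumvoll MCR reproduces its published formula", {
  tt <- ogtt_grid()
  ins <- rep(60, 9); ins[tt == 120] <- 600
  g <- rep(90, 9); g[tt == 90] <- 108            # 6 mmol/L
  s <- ogtt_series("st", tt, g, ins, rep(600, 9))
  expect_equal(stumvoll_mcr(s, list(bmi = 35)),
               18.8 - 0.271 * 35 - 0.0052 * 600 - 0.27 * 6,
               tolerance = 1e-12)
  expect_lt(stumvoll_mcr(s, list(bmi = 40)), stumvoll_mcr(s, list(bmi = 35)))
  expect_identical(stumvoll_mcr(s, list(bmi = 35)),
                   stumvoll_mcr(s, list(bmi = 35)))
})

test_that("Matsuda and HOMA-IR move oppositely under insulin scaling", {
  s1 <- flat_series(ins = 60); s2 <- flat_series(ins = 120)
  expect_gt(homa_ir(90, 120), homa_ir(90, 60))
  expect_lt(matsuda_index(s2), matsuda_index(s1))
})

test_that("OSA grading follows the AHI thresholds and partitions [0, Inf)", {
  expect_equal(classify_osa(3)$label, "mild")
  expect_equal(classify_osa(3)$analysis_group, "mild")
  expect_equal(classify_osa(5)$label, "mild")       # boundary inclusive
  expect_equal(classify_osa(5.01)$label, "moderate")
  expect_equal(classify_osa(10)$label, "severe")
  expect_equal(classify_osa(0.8)$label, "none")
  expect_equal(classify_osa(0.8)$analysis_group, "excluded")
  expect_equal(classify_osa(7)$analysis_group, "moderate_severe")
  expect_error(classify_osa(-0.1), ">= 0")
  # dense grid: exactly one label each, group mapping consistent
  grid <- seq(0, 40, by = 0.01)
  cls <- classify_osa(grid)
  expect_true(all(cls$label %in% c("none", "mild", "moderate", "severe")))
  expect_identical(cls$analysis_group == "excluded", cls$label == "none")
  expect_identical(cls$analysis_group == "moderate_severe",
                   cls$label %in% c("moderate", "severe"))
  # thresholds induce contiguous, non-overlapping intervals
  expect_identical(cls$label == "none", grid <= 1)
  expect_identical(cls$label == "mild", grid > 1 & grid <= 5)
  expect_identical(cls$label == "moderate", grid > 5 & grid < 10)
  expect_identical(cls$label == "severe", grid >= 10)
})

test_that("per-m2 clearance is invariant to joint BSA perturbation", {
  s <- smooth_subject(seed = 19)
  p1 <- s$params
  est1 <- deconvolve_isr(s$cpep, ogtt_grid(), p1)
  cl1 <- insulin_clearance(est1, s$series)
  # perturb BSA in forward and inverse jointly (vd unchanged)
  p2 <- cpeptide_params(p1$frac_short, p1$halflife_short, p1$halflife_long,
                        p1$vd, p1$bsa * 1.3)
  prof2 <- isr_profile(s$isr_true$times, s$isr_true$isr, p2$bsa,
                       fasting_isr = s$isr_true$fasting_isr, t_end = 180)
  cp2 <- forward_cpeptide(prof2, p2, s$truth$c0 * 1.3, ogtt_grid())
  est2 <- deconvolve_isr(cp2, ogtt_grid(), p2)
  cl2 <- insulin_clearance(est2, s$series)
  expect_equal(cl2$cl_total, cl1$cl_total, tolerance = 1e-6)
  expect_equal(cl2$cl_basal, cl1$cl_basal, tolerance = 1e-6)
})
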