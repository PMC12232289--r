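# Shared fixtures: everything is generated in code at test time.

default_params <- function(weight = 80, height = 155, status = "obese")
  standardize_params(list(weight = weight, height = height), status)

noiseless_config <- function(seed = 1, ...)
  sim_config(seed = seed,
             noise = list(glucose = 0, insulin = 0, cpeptide = 0), ...)

# noiseless simulated subject: smooth true ISR + exact forward C-peptide
smooth_subject <- function(seed = 7, group = "mild") {
  s <- simulate_subject(noiseless_config(seed), group)
  s$params <- standardize_params(s$subject, "obese")
  s$cpep <- forward_cpeptide(s$isr_true, s$params, s$truth$c0, ogtt_grid())
  s
}

# relative RMSE of an estimated profile against truth on [lo, hi] (segment
# midpoints), normalized by the mean true rate
rel_rmse_window <- function(est, truth, lo = 10, hi = 180) {
  mid <- est$times + diff(c(est$times, est$t_end)) / 2
  sel <- mid >= lo & mid <= hi
  sqrt(mean((est$isr[sel] - truth$isr[sel])^2)) / mean(truth$isr[sel])
}

# flat OGTT series: every analyte constant over the canonical grid
flat_series <- function(g = 90, ins = 60, cp = 600, id = "flat")
  ogtt_series(id, ogtt_grid(),
              glucose = rep(g, 9), insulin = rep(ins, 9),
              cpeptide = rep(cp, 9))

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# minimal cohort_table from per-subject insulin curves (shared glucose and
# C-peptide), for the statistics layer
curves_cohort <- function(insulin_by_subject, ahi) {
  n <- length(ahi)
  tb <- tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    ahi = ahi,
    series = lapply(seq_len(n), function(i)
      ogtt_series(sprintf("T%02d", i), ogtt_grid(),
                  glucose = rep(100, 9),
                  insulin = insulin_by_subject[[i]],
                  cpeptide = rep(600, 9))))
  as_cohort_table(tb)
}
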