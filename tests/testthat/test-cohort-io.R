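test_that("unit canonicalization uses the fixed factors and is idempotent", {
  expect_equal(convert_units(10, "insulin", "uU/mL"), 60)
  expect_equal(convert_units(5.5, "glucose", "mmol/L"), 99)
  expect_equal(convert_units(0.8, "cpeptide", "nmol/L"), 800)
  # canonical tags are identities, so converting twice equals converting once
  x <- c(0, 3.2, 700)
  once <- convert_units(x, "insulin", "uU/mL")
  expect_identical(convert_units(once, "insulin", "pmol/L"), once)
  expect_error(convert_units(1, "glucose", "furlongs"), "unknown unit")
})

test_that("ogtt_series enforces ordering, origin and positivity invariants", {
  expect_s3_class(flat_series(), "ogtt_series")
  expect_equal(flat_series()$grid_status, "canonical")
  expect_error(ogtt_series("x", c(0, 10, 10), 1:3, 1:3, 1:3),
               "strictly increasing")
  expect_error(ogtt_series("x", c(10, 20, 30), 1:3, 1:3, 1:3), "must be 0")
  expect_error(ogtt_series("x", c(0, 10, 20), c(1, -1, 1), 1:3, 1:3),
               "finite")
  expect_error(ogtt_series("x", c(0, 10), 1:2, 1:3, 1:2), "equal length")
  sub <- ogtt_series("x", c(0, 30, 60, 120, 180), rep(90, 5), rep(60, 5),
                     rep(600, 5))
  expect_equal(sub$grid_status, "subset")
  expect_warning(ogtt_series("x", c(0, 10, 20, 30, 60), rep(90, 5),
                             rep(60, 5), rep(2.7, 5)),
                 "implausibly low")
})

test_that("wide CSV reading conserves counts and applies unit conversion", {
  f <- withr::local_tempfile(fileext = ".csv")
  grid <- ogtt_grid()
  mk_row <- function(id, ahi) {
    g <- 90 + grid / 10; i <- 10 + grid / 20; cp <- 0.6 + grid / 1000
    stats::setNames(
      c(id, 12, "M", 80, 155, 33.3, 3.5, "II-III", ahi,
        g, i, cp),
      c("subject_id", "age", "sex", "weight", "height", "bmi", "bmi_zscore",
        "tanner", "ahi", paste0("g", grid), paste0("i", grid),
        paste0("c", grid)))
  }
  df <- as.data.frame(rbind(mk_row("A", 3), mk_row("B", 12)),
                      stringsAsFactors = FALSE)
  utils::write.csv(df, f, row.names = FALSE)
  sch <- cohort_schema(units = c(glucose = "mg/dL", insulin = "uU/mL",
                                 cpeptide = "nmol/L"))
  co <- read_cohort(f, sch)
  expect_equal(nrow(co), 2)
  expect_equal(length(co$series[[1]]$times), 9)
  # 10 uU/mL at t=0 -> 60 pmol/L; 0.6 nmol/L -> 600 pmol/L
  expect_equal(co$series[[1]]$insulin[1], 60)
  expect_equal(co$series[[1]]$cpeptide[1], 600)
  expect_equal(co$osa_group, c("mild", "moderate_severe"))
})

test_that("invariant violations land in the rejects report, not the cohort", {
  f <- withr::local_tempfile(fileext = ".csv")
  grid <- ogtt_grid()
  base <- data.frame(subject_id = c("OK", "NEG", "FAT"),
                     age = 12, sex = "F", weight = 80, height = 155,
                     bmi = c(33.3, 33.3, 60), bmi_zscore = 3.5,
                     tanner = "II-III", ahi = c(3, -1, 3))
  for (tt in grid) base[[paste0("g", tt)]] <- 90
  for (tt in grid) base[[paste0("i", tt)]] <- 60
  for (tt in grid) base[[paste0("c", tt)]] <- 600
  utils::write.csv(base, f, row.names = FALSE)
  co <- read_cohort(f)
  rej <- attr(co, "rejects")
  expect_equal(nrow(co), 1)
  expect_equal(sort(rej$subject_id), c("FAT", "NEG"))
  expect_match(rej$reason[rej$subject_id == "NEG"], "ahi >= 0 violated")
  expect_match(rej$reason[rej$subject_id == "FAT"], "inconsistent")
})

test_that("structural file problems raise named errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(idz = 1), f, row.names = FALSE)
  expect_error(read_cohort(f), "missing mandatory column 'subject_id'")
  f2 <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(subject_id = c("A", "A"), time = c(0, 0), glucose = 90,
                  insulin = 60, cpeptide = 600, ahi = 3)
  utils::write.csv(d, f2, row.names = FALSE)
  expect_error(read_cohort(f2, cohort_schema(format = "long")),
               "integrity error: duplicate")
  f3 <- withr::local_tempfile(fileext = ".csv")
  d$time <- c(0, "ten")
  d$subject_id <- c("A", "B")
  utils::write.csv(d, f3, row.names = FALSE)
  expect_error(read_cohort(f3, cohort_schema(format = "long")),
               "parse error")
})

test_that("cohort round-trips through the wide CSV within 1e-9", {
  sim <- simulate_cohort(sim_config(n_mild = 3, n_modsev = 3, seed = 42))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), 6)
  for (i in seq_len(6)) {
    a <- sim$cohort$series[[i]]; b <- back$series[[i]]
    expect_equal(b$glucose, a$glucose, tolerance = 1e-9)
    expect_equal(b$insulin, a$insulin, tolerance = 1e-9)
    expect_equal(b$cpeptide, a$cpeptide, tolerance = 1e-9)
  }
  expect_equal(back$ahi, sim$cohort$ahi, tolerance = 1e-12)
})

test_that("write_results emits a stable, deterministic file set", {
  sim <- simulate_cohort(sim_config(n_mild = 4, n_modsev = 4, seed = 2))
  coh <- compute_indices(sim$cohort)
  st <- cohort_stats_report(coh, group_vars = c("age", "cl_total"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_results(coh, st, d1, config = list(a = 1), seed = 2)
  f2 <- write_results(coh, st, d2, config = list(a = 1), seed = 2)
  expect_true(all(file.exists(f1)))
  idx <- utils::read.csv(file.path(d1, "index_table.csv"))
  expect_equal(nrow(idx), 8)
  expect_true(all(c("homa_ir", "matsuda_wbisi", "cl_total", "hiri")
                  %in% names(idx)))
  # byte-identical across runs with the same inputs
  for (nm in basename(f1)) {
    expect_identical(readLines(file.path(d1, nm)),
                     readLines(file.path(d2, nm)))
  }
})
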