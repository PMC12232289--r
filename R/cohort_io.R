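# Domain types, unit conventions and tabular I/O shared by all other modules.
#
# Canonical units: glucose mg/dL, insulin pmol/L, C-peptide pmol/L, time in
# minutes since the oral glucose load. Everything downstream assumes these.

#' Canonical OGTT sampling grid
#'
#' Sampling times (minutes) of the 3-hour oral glucose tolerance test with
#' 10-minute sampling over the first half hour and 30-minute sampling
#' thereafter.
#'
#' @return Integer vector of minutes since the glucose load.
#' @export
ogtt_grid <- function() c(0, 10, 20, 30, 60, 90, 120, 150, 180)

# conversion factors into canonical units, keyed by quantity then unit tag
.unit_table <- list(
  glucose  = c("mg/dL" = 1, "mmol/L" = 18),
  insulin  = c("pmol/L" = 1, "uU/mL" = 6, "µU/mL" = 6, "mU/L" = 6),
  cpeptide = c("pmol/L" = 1, "nmol/L" = 1000),
  time     = c("min" = 1, "h" = 60)
)

#' Convert a concentration or time vector to canonical units
#'
#' Canonical units are mg/dL (glucose), pmol/L (insulin, via
#' 1 uU/mL = 6.0 pmol/L), pmol/L (C-peptide) and minutes (time).
#' Conversion is a fixed multiplicative factor, so canonicalization is
#' idempotent: converting a value already in canonical units is the identity.
#'
#' @param x Numeric vector.
#' @param quantity One of `"glucose"`, `"insulin"`, `"cpeptide"`, `"time"`.
#' @param unit Unit tag of `x`, e.g. `"uU/mL"` or `"mmol/L"`.
#' @return `x` expressed in canonical units.
#' @export
convert_units <- function(x, quantity, unit) {
  quantity <- match.arg(quantity, names(.unit_table))
  fac <- .unit_table[[quantity]][unit]
  if (is.na(fac)) {
    stop(sprintf("unknown unit '%s' for %s (known: %s)",
                 unit, quantity,
                 paste(names(.unit_table[[quantity]]), collapse = ", ")))
  }
  unname(fac) * x
}

#' One subject's sampled OGTT trajectories
#'
#' Container for the glucose, insulin and C-peptide series of a single
#' subject, with validation of the ordering and positivity invariants.
#' All concentrations must already be in canonical units.
#'
#' @param subject_id Subject identifier.
#' @param times Sampling times, minutes; strictly increasing, starting at 0.
#' @param glucose,insulin,cpeptide Concentrations at `times` (mg/dL, pmol/L,
#'   pmol/L).
#' @return An object of class `ogtt_series`: a list with the five fields plus
#'   a `grid_status` flag (`"canonical"`, `"subset"`, `"superset"`, `"other"`)
#'   comparing `times` with [ogtt_grid()], and a `complete` flag (t = 0
#'   present and at least 5 samples).
#' @export
ogtt_series <- function(subject_id, times, glucose, insulin, cpeptide) {
  times <- as.numeric(times)
  glucose <- as.numeric(glucose); insulin <- as.numeric(insulin)
  cpeptide <- as.numeric(cpeptide)
  n <- length(times)
  if (length(glucose) != n || length(insulin) != n || length(cpeptide) != n)
    stop("glucose, insulin, cpeptide and times must have equal length")
  if (n < 2) stop("need at least 2 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] != 0) stop("first sampling time must be 0 (fasting sample)")
  vals <- c(glucose, insulin, cpeptide)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all concentrations must be finite and >= 0")
  grid <- ogtt_grid()
  grid_status <-
    if (length(times) == length(grid) && all(times == grid)) "canonical"
    else if (all(times %in% grid)) "subset"
    else if (all(grid %in% times)) "superset"
    else "other"
  if (cpeptide[1] > 0 && cpeptide[1] < 30)
    warning(sprintf(
      "subject %s: fasting C-peptide %.3g pmol/L is implausibly low; ",
      subject_id, cpeptide[1]),
      "values reported in nmol/L should be read with unit tag 'nmol/L'",
      call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), times = times,
         glucose = glucose, insulin = insulin, cpeptide = cpeptide,
         grid_status = grid_status,
         complete = n >= 5),
    class = "ogtt_series")
}

#' @export
print.ogtt_series <- function(x, ...) {
  cat(sprintf("<ogtt_series %s: %d timepoints (%s grid), G0=%.0f mg/dL, I0=%.0f pmol/L, C0=%.0f pmol/L>\n",
              x$subject_id, length(x$times), x$grid_status,
              x$glucose[1], x$insulin[1], x$cpeptide[1]))
  invisible(x)
}

#' Validate a subject's demographic record
#'
#' Checks the invariants on one row of demographics: positive weight and
#' height, non-negative AHI, and BMI consistent with weight/height within 5%
#' when all three are present.
#'
#' @param rec A list or one-row data frame with (at least) `subject_id`,
#'   `age`, `sex`, `weight`, `height`, `ahi`; optionally `bmi`,
#'   `bmi_zscore`, `tanner`, `sld`.
#' @return `NULL` if valid, otherwise a character vector of violation
#'   messages.
#' @export
validate_subject <- function(rec) {
  bad <- character()
  num <- function(f) suppressWarnings(as.numeric(rec[[f]]))
  if (!is.null(rec$weight) && (is.na(num("weight")) || num("weight") <= 0))
    bad <- c(bad, "weight > 0 violated")
  if (!is.null(rec$height) && (is.na(num("height")) || num("height") <= 0))
    bad <- c(bad, "height > 0 violated")
  if (!is.null(rec$ahi) && (is.na(num("ahi")) || num("ahi") < 0))
    bad <- c(bad, "ahi >= 0 violated")
  if (!is.null(rec$bmi) && !is.null(rec$weight) && !is.null(rec$height) &&
      !anyNA(c(num("bmi"), num("weight"), num("height"))) &&
      num("height") > 0) {
    implied <- num("weight") / (num("height") / 100)^2
    if (abs(num("bmi") - implied) > 0.05 * implied)
      bad <- c(bad, sprintf("bmi %.1f inconsistent with weight/height (implied %.1f)",
                            num("bmi"), implied))
  }
  if (length(bad)) bad else NULL
}

#' Describe the layout and units of a cohort file
#'
#' @param format `"wide"` (one row per subject, analyte columns `g0,g10,...`)
#'   or `"long"` (one row per subject per timepoint).
#' @param id Name of the subject identifier column.
#' @param time Name of the time column (long format), minutes.
#' @param analytes Named character vector mapping
#'   `c(glucose=, insulin=, cpeptide=)` to column names (long format).
#' @param prefixes Named character vector of column prefixes for wide format;
#'   wide columns are `<prefix><minutes>`, e.g. `g0, g10, ..., i0, ..., c0`.
#' @param units Named character vector of unit tags for the three analytes;
#'   see [convert_units()].
#' @param demographics Named character vector mapping canonical demographic
#'   field names to file column names.
#' @return A `cohort_schema` list used by [read_cohort()].
#' @export
cohort_schema <- function(format = c("wide", "long"),
                          id = "subject_id",
                          time = "time",
                          analytes = c(glucose = "glucose", insulin = "insulin",
                                       cpeptide = "cpeptide"),
                          prefixes = c(glucose = "g", insulin = "i",
                                       cpeptide = "c"),
                          units = c(glucose = "mg/dL", insulin = "pmol/L",
                                    cpeptide = "pmol/L"),
                          demographics = c(age = "age", sex = "sex",
                                           weight = "weight", height = "height",
                                           bmi = "bmi",
                                           bmi_zscore = "bmi_zscore",
                                           tanner = "tanner", ahi = "ahi",
                                           sld = "sld")) {
  structure(list(format = match.arg(format), id = id, time = time,
                 analytes = analytes, prefixes = prefixes, units = units,
                 demographics = demographics),
            class = "cohort_schema")
}

.read_delim_guess <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

.as_num_col <- function(x, col) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                 x[bad[1]], col, bad[1]))
  out
}

#' Read a cohort of OGTT subjects from delimited text
#'
#' Reads a CSV/TSV file in the wide or long dialect declared by `schema`,
#' converts analyte columns to canonical units, and validates every subject.
#' Rows failing invariants (negative AHI, inconsistent BMI, missing fasting
#' sample, fewer than 5 timepoints) are collected into a rejects report
#' attached as `attr(, "rejects")` rather than silently dropped; structural
#' problems (missing mandatory column, non-numeric cell, duplicated
#' subject/time) raise errors.
#'
#' @param path File path.
#' @param schema A [cohort_schema()].
#' @return A `cohort_table`: a tibble with one row per valid subject holding
#'   demographics, AHI, OSA class (via [classify_osa()]) and a `series`
#'   list-column of [ogtt_series()] objects; rejects report in
#'   `attr(, "rejects")`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- .read_delim_guess(path)
  if (!schema$id %in% names(raw))
    stop("schema error: missing mandatory column '", schema$id, "'")

  if (schema$format == "long") {
    need <- c(schema$time, unname(schema$analytes))
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("schema error: missing mandatory column '", miss[1], "'")
    raw[[schema$time]] <- .as_num_col(raw[[schema$time]], schema$time)
    key <- paste(raw[[schema$id]], raw[[schema$time]])
    if (anyDuplicated(key))
      stop("integrity error: duplicate (subject, time) pair: ",
           key[duplicated(key)][1])
    per_subject <- split(raw, raw[[schema$id]])
    grid_of <- function(d) sort(d[[schema$time]])
  } else {
    gcols <- function(prefix) {
      hit <- grep(paste0("^", prefix, "[0-9]+$"), names(raw), value = TRUE)
      hit[order(as.numeric(sub(paste0("^", prefix), "", hit)))]
    }
    wg <- gcols(schema$prefixes[["glucose"]])
    wi <- gcols(schema$prefixes[["insulin"]])
    wc <- gcols(schema$prefixes[["cpeptide"]])
    if (!length(wg))
      stop("schema error: missing mandatory column '",
           schema$prefixes[["glucose"]], "<time>'")
    if (anyDuplicated(raw[[schema$id]]))
      stop("integrity error: duplicate subject_id: ",
           raw[[schema$id]][duplicated(raw[[schema$id]])][1])
  }

  demo_get <- function(row, field) {
    col <- schema$demographics[[field]]
    if (is.null(col) || !col %in% names(raw)) return(NA)
    row[[col]]
  }

  subjects <- list(); rejects <- list()
  ids <- if (schema$format == "long") names(per_subject) else raw[[schema$id]]
  for (i in seq_along(ids)) {
    sid <- ids[i]
    res <- tryCatch({
      if (schema$format == "long") {
        d <- per_subject[[sid]]
        d <- d[order(d[[schema$time]]), ]
        times <- d[[schema$time]]
        g <- .as_num_col(d[[schema$analytes[["glucose"]]]], "glucose")
        ins <- .as_num_col(d[[schema$analytes[["insulin"]]]], "insulin")
        cp <- .as_num_col(d[[schema$analytes[["cpeptide"]]]], "cpeptide")
        row <- d[1, ]
      } else {
        row <- raw[i, ]
        times <- as.numeric(sub(paste0("^", schema$prefixes[["glucose"]]),
                                "", wg))
        pick <- function(cols) vapply(cols, function(cl)
          .as_num_col(row[[cl]], cl), numeric(1))
        g <- pick(wg); ins <- pick(wi); cp <- pick(wc)
      }
      keep <- !is.na(g) & !is.na(ins) & !is.na(cp)
      times <- times[keep]; g <- g[keep]; ins <- ins[keep]; cp <- cp[keep]
      g <- convert_units(g, "glucose", schema$units[["glucose"]])
      ins <- convert_units(ins, "insulin", schema$units[["insulin"]])
      cp <- convert_units(cp, "cpeptide", schema$units[["cpeptide"]])
      rec <- list(subject_id = sid,
                  age = as.numeric(demo_get(row, "age")),
                  sex = as.character(demo_get(row, "sex")),
                  weight = as.numeric(demo_get(row, "weight")),
                  height = as.numeric(demo_get(row, "height")),
                  bmi = as.numeric(demo_get(row, "bmi")),
                  bmi_zscore = as.numeric(demo_get(row, "bmi_zscore")),
                  tanner = as.character(demo_get(row, "tanner")),
                  ahi = as.numeric(demo_get(row, "ahi")),
                  sld = demo_get(row, "sld"))
      bad <- validate_subject(rec)
      if (length(times) < 5) bad <- c(bad, "fewer than 5 timepoints")
      if (!length(times) || times[1] != 0)
        bad <- c(bad, "fasting (t = 0) sample missing")
      if (length(bad)) {
        list(reject = paste(bad, collapse = "; "))
      } else {
        rec$series <- list(ogtt_series(sid, times, g, ins, cp))
        list(subject = rec)
      }
    }, error = function(e) {
      if (grepl("^(parse error|schema error|integrity error)", conditionMessage(e)))
        stop(e)
      list(reject = conditionMessage(e))
    })
    if (!is.null(res$reject)) {
      rejects[[length(rejects) + 1L]] <-
        tibble::tibble(subject_id = sid, reason = res$reject)
    } else {
      subjects[[length(subjects) + 1L]] <- res$subject
    }
  }

  cohort <- if (length(subjects)) {
    dplyr::bind_rows(lapply(subjects, function(s)
      tibble::tibble(subject_id = s$subject_id, age = s$age, sex = s$sex,
                     weight = s$weight, height = s$height, bmi = s$bmi,
                     bmi_zscore = s$bmi_zscore, tanner = s$tanner,
                     ahi = s$ahi,
                     sld = if (is.logical(s$sld) || is.numeric(s$sld))
                       as.logical(s$sld) else NA,
                     series = s$series)))
  } else {
    tibble::tibble(subject_id = character(), age = numeric(),
                   sex = character(), weight = numeric(), height = numeric(),
                   bmi = numeric(), bmi_zscore = numeric(),
                   tanner = character(), ahi = numeric(), sld = logical(),
                   series = list())
  }
  as_cohort_table(cohort,
                  rejects = if (length(rejects)) dplyr::bind_rows(rejects)
                  else tibble::tibble(subject_id = character(),
                                      reason = character()))
}

#' Stamp a subject tibble as a cohort table
#'
#' Adds OSA classification columns derived from `ahi` (see [classify_osa()])
#' and the `cohort_table` class. Every cohort's `osa_label`/`osa_group`
#' columns are always recomputed from `ahi`, so they cannot drift from the
#' classification rule.
#'
#' @param x Tibble with at least `subject_id` and `ahi` columns.
#' @param rejects Optional rejects report to attach.
#' @return `x` with `osa_label` and `osa_group` columns, class `cohort_table`.
#' @export
as_cohort_table <- function(x, rejects = NULL) {
  if (anyDuplicated(x$subject_id))
    stop("integrity error: duplicate subject_id")
  cls <- classify_osa(x$ahi)
  x$osa_label <- cls$label
  x$osa_group <- cls$analysis_group
  if (!is.null(rejects)) attr(x, "rejects") <- rejects
  class(x) <- unique(c("cohort_table", class(x)))
  x
}

#' Write pipeline result files
#'
#' Writes, under `outdir`: `index_table.csv` (one row per subject, one column
#' per derived index), `group_table.csv`, `curve_table.csv` and
#' `corr_table.csv` (the three statistics reports), `isr_profiles.csv`
#' (tidy per-segment secretion estimates), `rejects.csv` when a rejects
#' report is attached, and `run_log.json` (config hash, seed, package
#' version, per-subject regularization weights). Output is deterministic:
#' rerunning with an identical cohort and stats report reproduces the files
#' byte for byte.
#'
#' @param cohort A `cohort_table`, typically after [compute_indices()].
#' @param stats A `cohort_stats_report` from [cohort_stats_report()], or
#'   `NULL`.
#' @param outdir Output directory (created if needed).
#' @param config Optional configuration object recorded (hashed) in the log.
#' @param seed Optional seed recorded in the log.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(cohort, stats, outdir, config = NULL, seed = NULL) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("I/O error: output directory not writable: ", outdir)
  files <- character()
  wcsv <- function(d, name) {
    p <- file.path(outdir, name)
    utils::write.csv(d, p, row.names = FALSE)
    files <<- c(files, p)
  }

  flat <- cohort[, !vapply(cohort, is.list, logical(1))]
  wcsv(flat, "index_table.csv")

  if ("isr" %in% names(cohort)) {
    prof <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
      p <- cohort$isr[[i]]
      if (is.null(p)) return(NULL)
      tibble::tibble(subject_id = cohort$subject_id[i],
                     segment_start = p$times, isr = p$isr,
                     lambda = p$regularization_weight, fit_rmse = p$fit_rmse)
    }))
    wcsv(prof, "isr_profiles.csv")
  }

  if (!is.null(stats)) {
    wcsv(stats$group_table, "group_table.csv")
    wcsv(stats$curve_table, "curve_table.csv")
    wcsv(stats$corr_table, "corr_table.csv")
  } else {
    # header-only placeholders keep the file set stable for consumers
    wcsv(tibble::tibble(variable = character(), p = numeric()),
         "group_table.csv")
    wcsv(tibble::tibble(analyte = character(), time = numeric(),
                        p = numeric()), "curve_table.csv")
    wcsv(tibble::tibble(index = character(), spearman_r = numeric(),
                        p = numeric(), n = integer()), "corr_table.csv")
  }

  rej <- attr(cohort, "rejects")
  if (!is.null(rej)) wcsv(rej, "rejects.csv")

  log <- list(
    package = "ogttclear",
    version = as.character(utils::packageVersion("ogttclear")),
    seed = seed,
    config_hash = if (!is.null(config)) {
      cfg <- unclass(config)
      cfg$outdir <- NULL      # hash the analysis config, not the run paths
      rlang::hash(cfg)
    } else NULL,
    n_subjects = nrow(cohort),
    n_rejected = if (!is.null(rej)) nrow(rej) else 0L,
    lambda = if ("isr" %in% names(cohort))
      stats::setNames(
        vapply(cohort$isr, function(p)
          if (is.null(p)) NA_real_ else p$regularization_weight, numeric(1)),
        cohort$subject_id)
    else NULL)
  p <- file.path(outdir, "run_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}

#' Write a cohort (demographics + series) back to a wide CSV
#'
#' Inverse of [read_cohort()] for the wide dialect on a shared grid; used to
#' round-trip simulated cohorts through the text interface.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(nrow(cohort) > 0)
  times <- cohort$series[[1]]$times
  for (s in cohort$series)
    if (!identical(s$times, times))
      stop("write_cohort_csv requires a shared sampling grid")
  grid_cols <- function(prefix, field) {
    m <- t(vapply(cohort$series, function(s) s[[field]],
                  numeric(length(times))))
    colnames(m) <- paste0(prefix, times)
    as.data.frame(m)
  }
  flat <- cohort[, intersect(c("subject_id", "age", "sex", "weight", "height",
                               "bmi", "bmi_zscore", "tanner", "ahi", "sld"),
                             names(cohort))]
  out <- cbind(as.data.frame(flat),
               grid_cols("g", "glucose"),
               grid_cols("i", "insulin"),
               grid_cols("c", "cpeptide"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
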