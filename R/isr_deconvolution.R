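# Insulin secretion rate by regularized C-peptide deconvolution.
#
# The forward model (forward_cpeptide) is linear in the piecewise-constant
# secretion profile, so estimating ISR(t) from sampled C-peptide is a
# finite-dimensional linear inverse problem. It is ill-posed at OGTT
# sampling density (9 samples, ~36 unknown segments), and is solved as
#
#   min_{x >= 0}  sum_t (C_model(t) - C_obs(t))^2 + lambda * ||D2 x||^2
#
# where D2 takes second differences (curvature) of the secretion profile
# including the fasting steady-state segment pinned by C_obs(0). The
# non-negativity is a hard constraint (Lawson-Hanson active set, compiled);
# lambda is chosen by generalized cross-validation over a fixed log-spaced
# ladder, ties broken toward the smoother solution.

#' Piecewise-constant insulin secretion profile
#'
#' @param times Segment start times, minutes, strictly increasing (first
#'   element 0).
#' @param isr Secretion rate per segment, pmol min^-1 m^-2, all `>= 0`.
#' @param bsa Body-surface area, m^2 (converts to absolute pmol/min).
#' @param fasting_isr Steady-state secretion before the load,
#'   pmol min^-1 m^-2.
#' @param t_end End of the last segment, minutes; defaults to extending the
#'   last segment by the previous segment width.
#' @param regularization_weight,fit_rmse Fit diagnostics recorded by
#'   [deconvolve_isr()] (`NA` for profiles built directly).
#' @return Object of class `isr_profile`, with `isr_auc` (exact integral of
#'   the step function over `[times[1], t_end]`, pmol m^-2) precomputed.
#' @export
isr_profile <- function(times, isr, bsa, fasting_isr = isr[1], t_end = NULL,
                        regularization_weight = NA_real_,
                        fit_rmse = NA_real_) {
  stopifnot(length(times) == length(isr), length(times) >= 1,
            all(diff(times) > 0), bsa > 0)
  if (any(isr < 0) || fasting_isr < 0)
    stop("isr must be non-negative everywhere")
  if (is.null(t_end)) {
    w <- if (length(times) > 1) diff(times)[length(times) - 1] else 1
    t_end <- times[length(times)] + w
  }
  stopifnot(t_end > times[length(times)])
  widths <- diff(c(times, t_end))
  structure(list(times = times, isr = isr, bsa = bsa,
                 fasting_isr = fasting_isr,
                 t_end = t_end,
                 isr_auc = sum(isr * widths),
                 regularization_weight = regularization_weight,
                 fit_rmse = fit_rmse),
            class = "isr_profile")
}

#' @export
print.isr_profile <- function(x, ...) {
  cat(sprintf(
    "<isr_profile: %d segments on [%g,%g] min, fasting %.1f, AUC %.0f pmol/m2, lambda %.3g, rmse %.3g>\n",
    length(x$times), x$times[1], x$t_end, x$fasting_isr, x$isr_auc,
    x$regularization_weight, x$fit_rmse))
  invisible(x)
}

#' Non-negative least squares
#'
#' Solves `min ||A x - b||` subject to `x >= 0` with the Lawson-Hanson
#' active-set algorithm (compiled). Deterministic; no random initialization.
#'
#' @param A Design matrix.
#' @param b Response vector.
#' @return Solution vector `x`.
#' @export
nnls_solve <- function(A, b) as.numeric(nnls_cpp(A, as.numeric(b)))

# design matrix mapping per-m^2 segment rates to C-peptide increments at the
# observation times (the t = 0 row is excluded: it is matched exactly by the
# fasting anchor). The subject enters only through the scalar bsa/vd, so the
# shape matrix (scale = 1) is shared across subjects with the same kinetic
# rate constants and grids.
.deconv_design <- function(tt, a, b, params, scale = params$bsa / params$vd) {
  TT <- outer(tt, a, "-")
  TB <- pmax(outer(tt, b, "-"), 0)
  act <- TT > 0
  TT[!act] <- 0
  K <- (.cum_response(params, TT) - .cum_response(params, TB)) * scale
  K[!act] <- 0
  K
}

.deconv_cache <- new.env(parent = emptyenv())

# Shared-across-subjects precomputation for the GCV ladder. Working in the
# scaled problem ||A0 x - y/c||^2 + (lambda/c^2) ||L x - d||^2 with
# c = bsa/vd, the data-scaled reference weight lambda_ref = c^2 * r0
# (r0 = ||A0||_F^2 / ||L||_F^2) makes the scaled ladder r0 * 10^g identical
# for every subject, so the Cholesky factors of the ridge normal matrices
# and the smoother's effective degrees of freedom are computed once per
# (kinetic shape, grid, ladder) key.
.deconv_precompute <- function(params, tt, a, b, n_lambda, lambda_span) {
  key <- paste(
    paste(format(c(params$frac_short, params$k_short, params$k_long),
                 digits = 15), collapse = ","),
    paste(tt, collapse = ","), paste(a, collapse = ","),
    n_lambda, lambda_span[1], lambda_span[2], sep = "|")
  hit <- .deconv_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(a)
  A0 <- .deconv_design(tt, a, b, params, scale = 1)
  L <- matrix(0, n - 1, n)
  L[1, 1:2] <- c(-2, 1)
  for (r in seq_len(n - 1)[-1]) L[r, (r - 1):(r + 1)] <- c(1, -2, 1)
  r0 <- sum(A0^2) / sum(L^2)
  ladder <- r0 * 10^seq(log10(lambda_span[1]), log10(lambda_span[2]),
                        length.out = n_lambda)
  AtA <- crossprod(A0); LtL <- crossprod(L)
  pre <- lapply(ladder, function(lam) {
    M <- AtA + lam * LtL
    R <- tryCatch(chol(M), error = function(e)
      chol(M + diag(1e-10 * mean(diag(M)), n)))
    V <- backsolve(R, backsolve(R, t(A0), transpose = TRUE))
    list(R = R, edf = sum(A0 * t(V)))
  })
  out <- list(A0 = A0, L = L, r0 = r0, ladder = ladder,
              chol = lapply(pre, `[[`, "R"),
              edf = vapply(pre, `[[`, numeric(1), "edf"))
  .deconv_cache[[key]] <- out
  out
}

#' Estimate the insulin secretion rate from sampled C-peptide
#'
#' Inverts the two-compartment forward model on a piecewise-constant subgrid
#' (default 5-minute segments). The fasting steady state is anchored to
#' `C(0)`: the pre-load secretion rate is fixed at
#' [fasting_isr_from_c0()]`(C(0))` and enters the curvature penalty as the
#' left boundary value, so the estimated profile departs smoothly from the
#' fasting rate. Non-negativity is enforced as a hard constraint.
#'
#' With `lambda = "auto"`, the smoothness weight is selected by generalized
#' cross-validation over `n_lambda` log-spaced multiples (spanning
#' `lambda_span`) of a data-scaled reference weight (the ratio of the
#' squared Frobenius norms of the design and penalty blocks); exact ties
#' resolve toward the larger weight. GCV is evaluated on the linear ridge
#' smoother (where its effective-degrees-of-freedom form applies); the
#' non-negativity constraint is then imposed by a single NNLS solve at the
#' selected weight.
#'
#' @param cpeptide C-peptide concentrations (pmol/L) at `times`, or an
#'   [ogtt_series()] (in which case `times` is ignored).
#' @param times Sampling times, minutes, including 0.
#' @param params A [cpeptide_params()] object.
#' @param lambda `"auto"` (GCV) or a non-negative numeric weight.
#' @param dt Segment width of the reconstruction subgrid, minutes.
#' @param t_end End of the reconstruction window; defaults to the last
#'   sampling time.
#' @param n_lambda,lambda_span GCV ladder: `n_lambda` log-spaced values over
#'   `lambda_span` (multiples of the data-scaled reference).
#' @return An [isr_profile()]; the GCV ladder (weight, edf, rss, gcv) is in
#'   `attr(, "gcv")` when `lambda = "auto"`.
#' @export
deconvolve_isr <- function(cpeptide, times = NULL, params, lambda = "auto",
                           dt = 5, t_end = NULL, n_lambda = 21,
                           lambda_span = c(1e-3, 1e3)) {
  if (inherits(cpeptide, "ogtt_series")) {
    times <- cpeptide$times
    cpeptide <- cpeptide$cpeptide
  }
  stopifnot(length(cpeptide) == length(times))
  if (length(times) < 5 || times[1] != 0)
    stop("need at least 5 C-peptide samples including t = 0")
  if (all(cpeptide == 0))
    stop("degenerate input: all C-peptide values are zero")
  if (is.null(t_end)) t_end <- max(times)

  C0 <- cpeptide[times == 0]
  s_fast <- fasting_isr_from_c0(C0, params)

  a <- seq(0, t_end - dt, by = dt)
  b <- a + dt
  n <- length(a)
  tt <- times[times > 0]
  yy <- cpeptide[times > 0] - C0 * .fasting_decay(params, tt)

  pre <- .deconv_precompute(params, tt, a, b, n_lambda, lambda_span)
  A0 <- pre$A0; L <- pre$L
  cc <- params$bsa / params$vd     # subject scale: A = cc * A0
  ys <- yy / cc
  # second-difference penalty over the augmented vector
  # (s_fast, x_1, ..., x_n); the fasting term moves to the right-hand side
  d <- c(-s_fast, rep(0, n - 2))
  Ltd <- drop(crossprod(L, d))
  A0ty <- drop(crossprod(A0, ys))

  nnls_at <- function(lam_s)    # lam_s: weight in the scaled problem
    nnls_solve(rbind(A0, sqrt(lam_s) * L), c(ys, sqrt(lam_s) * d))

  gcv_tab <- NULL
  if (identical(lambda, "auto")) {
    m <- length(ys)
    gcv_vals <- rss_vals <- numeric(length(pre$ladder))
    for (k in seq_along(pre$ladder)) {
      R <- pre$chol[[k]]
      x_u <- backsolve(R, backsolve(R, A0ty + pre$ladder[k] * Ltd,
                                    transpose = TRUE))
      rss_vals[k] <- sum((A0 %*% x_u - ys)^2)
      gcv_vals[k] <- m * rss_vals[k] / max(m - pre$edf[k], 1e-8)^2
    }
    best <- max(which(gcv_vals <= min(gcv_vals) * (1 + 1e-12)))
    lambda <- pre$ladder[best] * cc^2     # report on the original scale
    x <- nnls_at(pre$ladder[best])
    gcv_tab <- structure(
      list(lambda = pre$ladder * cc^2, edf = pre$edf,
           rss = rss_vals * cc^2, gcv = gcv_vals),
      class = "data.frame", row.names = seq_along(pre$ladder))
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0)
    x <- nnls_at(max(lambda / cc^2, 1e-12 * pre$r0))
  }

  prof <- isr_profile(times = a, isr = as.numeric(x), bsa = params$bsa,
                      fasting_isr = s_fast, t_end = t_end,
                      regularization_weight = lambda)
  C_model <- forward_cpeptide(prof, params, C0, out_times = times)
  prof$fit_rmse <- sqrt(mean((C_model - cpeptide)^2))
  if (!is.null(gcv_tab)) attr(prof, "gcv") <- gcv_tab
  prof
}

#' Scalar summaries of a secretion profile
#'
#' @param profile An [isr_profile()].
#' @return List with `fasting_isr` (steady-state segment,
#'   pmol min^-1 m^-2), `total_isr` (time-averaged secretion over the
#'   profile window, pmol min^-1 m^-2) and `isr_auc` (exact integral,
#'   pmol m^-2).
#' @export
isr_summaries <- function(profile) {
  stopifnot(inherits(profile, "isr_profile"))
  span <- profile$t_end - profile$times[1]
  list(fasting_isr = profile$fasting_isr,
       total_isr = profile$isr_auc / span,
       isr_auc = profile$isr_auc)
}
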