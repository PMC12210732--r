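## heat_tolerance: four-parameter sigmoidal damage curve for Fv/Fm vs. target
## temperature, closed-form LT_d inversion, and the 3-sample / 250-repetition
## subsampling bootstrap.

#' The sigmoidal damage function
#'
#' Evaluates `y = A2 + (A1 - A2) / (1 + (x / x0)^p)` in log-space for
#' numerical stability. For `p > 0` this decreases from `A1` (no damage) to
#' `A2` (full damage) with inflection at `x0` (the LT_50).
#'
#' @param x Temperature in degC; must be positive (the ratio form is
#'   undefined at or below zero).
#' @param A1,A2 Upper and lower asymptotes in Fv/Fm units.
#' @param x0 Inflection temperature (degC).
#' @param p Slope parameter (dimensionless).
#' @return Fv/Fm values.
#' @examples
#' damage_sigmoid(50, A1 = 0.8, A2 = 0.05, x0 = 50, p = 40)  # (A1+A2)/2
#' @export
damage_sigmoid <- function(x, A1, A2, x0, p) {
  if (any(x <= 0)) tt_domain_error("temperature x must be positive")
  if (!all(is.finite(p))) tt_domain_error("p must be finite")
  # 1/(1 + (x/x0)^p) = plogis(-p * log(x/x0)) without overflow
  A2 + (A1 - A2) * stats::plogis(-p * (log(x) - log(x0)))
}

#' Fit the damage sigmoid to a viability assay
#'
#' Nonlinear least squares of Fv/Fm on target temperature using the
#' four-parameter ratio sigmoid. Default starting values: `A1` = highest and
#' `A2` = lowest per-temperature mean response, `x0` = temperature whose mean
#' response is closest to the mid-response, `p` = 30 (typical steepness of a
#' thermal damage curve dropping over ~5 K). Bounds: `A1, A2 >= 0`,
#' `p` in (0, 500], `x0` within the data span +/- 10 K.
#'
#' @param assay A `viability_assay` (or a data.frame with `temperature` and
#'   `fvfm` columns).
#' @param init Optional named list overriding starting values
#'   (`A1`, `A2`, `x0`, `p`).
#' @return A `sigmoid_fit` with elements `A1`, `A2`, `x0`, `p`,
#'   `residual_sse`, `converged`, `n`, `span`.
#' @export
fit_sigmoid <- function(assay, init = NULL) {
  d <- if (inherits(assay, "viability_assay")) assay$data else as.data.frame(assay)
  if (!all(c("temperature", "fvfm") %in% names(d)))
    tt_value_error("assay must provide temperature and fvfm")
  temps <- sort(unique(d$temperature))
  if (length(temps) < 4L)
    tt_value_error("at least 4 distinct temperatures are required (4 free parameters)")
  means <- tapply(d$fvfm, d$temperature, mean)
  start <- list(
    A1 = max(means), A2 = min(means),
    x0 = as.numeric(names(means))[which.min(abs(means - (max(means) + min(means)) / 2))],
    p = 30
  )
  if (!is.null(init)) start[names(init)] <- init
  span <- range(d$temperature)
  lower <- c(A1 = 0, A2 = 0, x0 = span[1] - 10, p = 1e-3)
  upper <- c(A1 = 2, A2 = 2, x0 = span[2] + 10, p = 500)
  start <- lapply(start, function(v) unname(v))
  start$x0 <- min(max(start$x0, lower[["x0"]]), upper[["x0"]])
  fit <- tryCatch(
    stats::nls(fvfm ~ A2 + (A1 - A2) * stats::plogis(-p * (log(temperature) - log(x0))),
               data = d, start = start, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) tt_fit_error(paste0("sigmoid fit failed: ", conditionMessage(e))))
  cf <- stats::coef(fit)
  structure(
    list(A1 = unname(cf["A1"]), A2 = unname(cf["A2"]),
         x0 = unname(cf["x0"]), p = unname(cf["p"]),
         residual_sse = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE,
         n = nrow(d), span = span),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit: A1 = %.4f, A2 = %.4f, x0 = %.3f degC, p = %.2f (SSE %.4g, n = %d)\n",
              x$A1, x$A2, x$x0, x$p, x$residual_sse, x$n))
  invisible(x)
}

#' Lethal temperature for a given damage fraction
#'
#' Inverts the damage sigmoid at `y = A1 - d * (A1 - A2)`, giving the closed
#' form `LT_d = x0 * (d / (1 - d))^(1/p)`. `d = 0.5` returns `x0` exactly
#' (the LT_50); `d = 0.1` gives the LT_10.
#'
#' @param fit A `sigmoid_fit` (or list with `x0` and `p`).
#' @param d Damage fraction in (0, 1).
#' @return Temperature in degC.
#' @export
lt_from_fit <- function(fit, d) {
  if (any(d <= 0 | d >= 1)) tt_domain_error("damage fraction d must lie in (0, 1)")
  if (fit$p <= 0) tt_value_error("LT is only defined for p > 0")
  fit$x0 * (d / (1 - d))^(1 / fit$p)
}

#' Bootstrap LT_10 / LT_50 by repeated subsampling
#'
#' The published resampling scheme: per repetition, draw `per_temp` replicate
#' Fv/Fm values at every target temperature (without replacement by default),
#' fit the damage sigmoid, and record LT_10 and LT_50; repeat `reps` times.
#' Failed repetitions are recorded as `NA` and excluded from the percentile
#' confidence intervals, with their count reported.
#'
#' @param assay A `viability_assay`.
#' @param per_temp Replicates drawn per temperature per repetition
#'   (default 3).
#' @param reps Number of repetitions (default 250).
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @param replace Sample with replacement instead (default `FALSE`).
#' @param damage Damage fractions to track (default 0.1 and 0.5).
#' @return An `lt_result` with point estimates `lt10`/`lt50` (from the fit
#'   on all data), the point fit, bootstrap vectors (length `reps`, `NA` for
#'   failures), bootstrap medians and means, percentile 95% CIs, `n_failed`
#'   and the seed.
#' @export
bootstrap_lt <- function(assay, per_temp = 3, reps = 250, seed = NULL,
                         replace = FALSE, damage = c(0.1, 0.5)) {
  stopifnot(inherits(assay, "viability_assay"))
  d <- assay$data
  counts <- table(d$temperature)
  if (!replace && any(counts < per_temp))
    tt_value_error(sprintf(
      "sampling %d without replacement needs >= %d replicates at every temperature (min is %d)",
      per_temp, per_temp, min(counts)))
  if (!is.null(seed)) set.seed(seed)
  point <- fit_sigmoid(assay)
  lt_point <- lt_from_fit(point, damage)
  groups <- split(seq_len(nrow(d)), d$temperature)
  boot <- matrix(NA_real_, nrow = reps, ncol = length(damage))
  for (r in seq_len(reps)) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), per_temp, replace = replace)]), use.names = FALSE)
    fit <- tryCatch(fit_sigmoid(d[idx, , drop = FALSE]),
                    thermotol_error = function(e) NULL)
    if (!is.null(fit) && fit$p > 0 && fit$A1 > fit$A2)
      boot[r, ] <- lt_from_fit(fit, damage)
  }
  n_failed <- sum(is.na(boot[, 1L]))
  if (n_failed > reps / 2)
    tt_bootstrap_error(sprintf("%d of %d bootstrap repetitions failed", n_failed, reps))
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(
    list(lt10 = lt_point[match(0.1, damage)], lt50 = lt_point[match(0.5, damage)],
         damage = damage, point_fit = point,
         bootstrap_lt10 = boot[, match(0.1, damage)],
         bootstrap_lt50 = boot[, match(0.5, damage)],
         boot_median = apply(boot, 2L, stats::median, na.rm = TRUE),
         boot_mean = colMeans(boot, na.rm = TRUE),
         ci95 = ci, n_failed = n_failed, reps = reps, per_temp = per_temp,
         seed = seed),
    class = "lt_result"
  )
}

#' @export
print.lt_result <- function(x, ...) {
  cat(sprintf("LT result (%d reps, %d samples/temperature, %d failed):\n",
              x$reps, x$per_temp, x$n_failed))
  i10 <- match(0.1, x$damage); i50 <- match(0.5, x$damage)
  if (!is.na(i10))
    cat(sprintf("  LT_10 = %.2f degC (boot median %.2f, 95%% CI %.2f-%.2f)\n",
                x$lt10, x$boot_median[i10], x$ci95[1, i10], x$ci95[2, i10]))
  if (!is.na(i50))
    cat(sprintf("  LT_50 = %.2f degC (boot median %.2f, 95%% CI %.2f-%.2f)\n",
                x$lt50, x$boot_median[i50], x$ci95[1, i50], x$ci95[2, i50]))
  invisible(x)
}
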