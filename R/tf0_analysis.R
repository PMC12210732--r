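## tf0_analysis: PSII thermotolerance thresholds T_c, T_p, T_pII from basic
## chlorophyll fluorescence (F0) vs. leaf temperature curves.  The classical
## graphical determination is formalized as a two-line construction: a
## baseline line through the flat low-temperature region and a maximal-slope
## line through the steep rise; T_c is their intersection.

#' T-F0 analysis configuration
#'
#' @param grid_step Uniform resampling step in K.
#' @param baseline_width Width (K) of the baseline band.
#' @param rise_width Width (K) of the rise band.
#' @param prominence_frac Peak prominence threshold as a fraction of the F0
#'   range (boundary inclusive: prominence equal to the threshold counts).
#' @param baseline_method `"min_slope"` picks the flattest low-temperature
#'   band (robust when the baseline is genuinely flat and noisy);
#'   `"max_r2"` picks the best-fitting band.
#' @param min_rise_frac The rise line's slope must exceed this fraction of
#'   the F0 range per K, otherwise the curve is called flat. Scales with F0
#'   so that thresholds are invariant under rescaling of the fluorescence
#'   signal.
#' @param rise_cap_frac The rise-band search is capped at the temperature
#'   where F0 first climbs this fraction of the way from the baseline level
#'   to the first peak, so the maximal-slope band tracks the initial steep
#'   rise rather than the flank of the T_p peak itself.
#' @param band_step Band search step in K.
#' @param smooth_k Centered moving-mean window (points) before peak
#'   detection; 0 disables (default).
#' @param parallel_tol Minimum |slope difference| for the T_c intersection.
#' @return A list of class `tf0_config`.
#' @export
tf0_config <- function(grid_step = 0.1, baseline_width = 5, rise_width = 3,
                       prominence_frac = 0.05,
                       baseline_method = c("min_slope", "max_r2"),
                       min_rise_frac = 0.01, rise_cap_frac = 0.5,
                       band_step = 0.1, smooth_k = 0L, parallel_tol = 1e-6) {
  structure(list(grid_step = grid_step, baseline_width = baseline_width,
                 rise_width = rise_width, prominence_frac = prominence_frac,
                 baseline_method = match.arg(baseline_method),
                 min_rise_frac = min_rise_frac, rise_cap_frac = rise_cap_frac,
                 band_step = band_step,
                 smooth_k = as.integer(smooth_k), parallel_tol = parallel_tol),
            class = "tf0_config")
}

prepare_f0 <- function(c, config) {
  if (is.null(c$grid_step) || !isTRUE(all.equal(c$grid_step, config$grid_step)))
    c <- resample_uniform(c, step = config$grid_step)
  c
}

f0_peaks <- function(c, config) {
  y <- c$data$f0
  if (config$smooth_k > 1L) y <- moving_mean(y, config$smooth_k)
  pk <- find_peaks(y)
  rng <- diff(range(y))
  thr <- config$prominence_frac * rng
  # boundary-inclusive (>=) up to numerical noise in the threshold product
  pk[pk$prominence >= thr - 1e-9 * max(rng, 1), , drop = FALSE]
}

#' Detect the critical temperature T_c of a T-F0 curve
#'
#' Fits a baseline line through the flat low-temperature region (band chosen
#' below the global F0 maximum) and a rise line through the band of maximal
#' positive slope between the baseline and the first F0 peak; T_c is the
#' temperature where the two lines intersect.
#'
#' @param c An `f0_curve`.
#' @param config A [tf0_config()].
#' @return A list with `t_c`, `baseline_line` and `rise_line`.
#' @export
detect_tc <- function(c, config = tf0_config()) {
  stopifnot(inherits(c, "f0_curve"))
  span <- diff(range(c$data$temperature))
  if (span < 15)
    tt_value_error(sprintf("T-F0 curve must span at least 15 K (got %.1f K)", span))
  c <- prepare_f0(c, config)
  temp <- c$data$temperature
  y <- c$data$f0
  rng <- diff(range(y))
  if (rng <= 0)
    tt_detection_error("no F0 rise exceeding the slope threshold; curve appears flat")
  t_max <- max(temp[which.max(y)], min(temp) + config$baseline_width)

  baseline <- band_search(temp, y, width = config$baseline_width,
                          lo = min(temp), hi = t_max, step = config$band_step,
                          select = if (config$baseline_method == "min_slope")
                            "min_abs_slope" else "max_r2")

  pk <- f0_peaks(c, config)
  first_peak_t <- if (nrow(pk)) temp[min(pk$index)] else t_max
  first_peak_y <- if (nrow(pk)) y[min(pk$index)] else max(y)
  base_level <- baseline$intercept + baseline$slope * baseline$band[2]
  half <- base_level + config$rise_cap_frac * (first_peak_y - base_level)
  crossed <- which(temp > baseline$band[2] & y >= half)
  t_half <- if (length(crossed)) temp[min(crossed)] else first_peak_t
  rise_hi <- max(min(t_half, first_peak_t), baseline$band[2] + config$rise_width)
  rise <- band_search(temp, y, width = config$rise_width,
                      lo = baseline$band[2], hi = rise_hi,
                      step = config$band_step, select = "max_slope")
  if (!(rise$slope > config$min_rise_frac * rng))
    tt_detection_error("no F0 rise exceeding the slope threshold; curve appears flat")
  t_c <- intersect_lines(baseline, rise, tol = config$parallel_tol)
  list(t_c = t_c, baseline_line = baseline, rise_line = rise)
}

#' Detect the first F0 peak temperature T_p
#'
#' @param c An `f0_curve`.
#' @param t_c The critical temperature from [detect_tc()]; only peaks above
#'   it are considered.
#' @param config A [tf0_config()].
#' @return T_p in degC.
#' @export
detect_tp <- function(c, t_c, config = tf0_config()) {
  stopifnot(inherits(c, "f0_curve"))
  c <- prepare_f0(c, config)
  pk <- f0_peaks(c, config)
  pk <- pk[c$data$temperature[pk$index] > t_c, , drop = FALSE]
  if (!nrow(pk))
    tt_detection_error("no prominent F0 peak above T_c (first peak missing)")
  c$data$temperature[min(pk$index)]
}

#' Detect the second F0 peak temperature T_pII
#'
#' @param c An `f0_curve`.
#' @param t_p The first peak temperature; only peaks above it are considered.
#' @param config A [tf0_config()].
#' @return T_pII in degC, or `NA` when no further prominent peak exists
#'   (a valid outcome, not an error).
#' @export
detect_tpII <- function(c, t_p, config = tf0_config()) {
  stopifnot(inherits(c, "f0_curve"))
  c <- prepare_f0(c, config)
  pk <- f0_peaks(c, config)
  pk <- pk[c$data$temperature[pk$index] > t_p + config$grid_step / 2, ,
           drop = FALSE]
  if (!nrow(pk)) return(NA_real_)
  c$data$temperature[min(pk$index)]
}

#' Full T-F0 curve analysis
#'
#' Runs [detect_tc()], [detect_tp()] and [detect_tpII()] on one curve,
#' turning stage failures into explicit `NA` results with diagnostics.
#'
#' @param c An `f0_curve`.
#' @param config A [tf0_config()].
#' @return A `tf0_thresholds` object with `t_c`, `t_p`, `t_pII`, the two
#'   fitted lines and `diagnostics`.
#' @export
analyze_f0 <- function(c, config = tf0_config()) {
  stopifnot(inherits(c, "f0_curve"))
  diag <- character(0)
  tc <- tryCatch(detect_tc(c, config),
                 thermotol_error = function(e) {
                   diag <<- c(diag, paste0("T_c: ", conditionMessage(e)))
                   NULL
                 })
  t_p <- t_pII <- NA_real_
  if (!is.null(tc)) {
    t_p <- tryCatch(detect_tp(c, tc$t_c, config),
                    tt_detection_error = function(e) {
                      diag <<- c(diag, paste0("T_p: ", conditionMessage(e)))
                      NA_real_
                    })
    if (!is.na(t_p)) t_pII <- detect_tpII(c, t_p, config)
  }
  structure(
    list(sample_id = c$sample_id,
         t_c = if (is.null(tc)) NA_real_ else tc$t_c,
         t_p = t_p, t_pII = t_pII,
         baseline_line = if (is.null(tc)) NULL else tc$baseline_line,
         rise_line = if (is.null(tc)) NULL else tc$rise_line,
         diagnostics = diag),
    class = "tf0_thresholds"
  )
}

#' @export
print.tf0_thresholds <- function(x, ...) {
  cat(sprintf("T-F0 thresholds for '%s': T_c = %s, T_p = %s, T_pII = %s degC\n",
              x$sample_id, format(round(x$t_c, 2)), format(round(x$t_p, 2)),
              format(round(x$t_pII, 2))))
  if (length(x$diagnostics))
    cat("  diagnostics:\n", paste0("   - ", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}
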