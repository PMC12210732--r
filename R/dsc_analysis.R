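## dsc_analysis: extract T_exo, T_endo and T_init from a normalized
## thermogram and classify curves as vital vs. heat-killed.
##
## The thermogram convention throughout is exothermic-positive ("exo-up"):
## the endotherm is a local minimum (the "jag"), the exotherm a local maximum.

#' DSC analysis configuration
#'
#' Collects the tunable constants of the thermogram analysis. Defaults follow
#' the published procedure where one is stated (10 K / 3 K band widths, band
#' start 29 degC) and field-reasonable values elsewhere.
#'
#' @param grid_step Uniform resampling step in K.
#' @param band_width_first,band_width_second Sliding-band widths (K) for the
#'   baseline line and the steep-decline line.
#' @param band_start Lower limit (degC) of the first band search.
#' @param search_min_exo Exotherm search region starts here (degC).
#' @param search_min_endo Endotherm search region starts here (degC) when no
#'   exotherm constrains it.
#' @param prominence_frac Peak/dip prominence threshold as a fraction of the
#'   curve's total heat-flow range.
#' @param linearity_r2 Full-span linear R-squared at or above which a curve
#'   with neither dip nor peak is called heat-killed.
#' @param parallel_tol Minimum |slope difference| (mW/g/K) for a valid line
#'   intersection.
#' @param second_lower How the lower edge of the second-line search is taken
#'   from the first fit: `"tied"` (upper edge of the highest-starting band
#'   among R-squared ties; robust on noiseless piecewise-linear curves) or
#'   `"selected"` (upper edge of the returned band).
#' @param endo_ref_offset Two offsets (K) below a candidate endotherm
#'   minimum delimiting the reference window for its preceding-decline
#'   trend; see [detect_endotherm()].
#' @param band_step Band search step in K.
#' @param smooth_k Centered moving-mean window (points) applied before
#'   extremum detection; the default 5 points (0.5 K at the default grid)
#'   suppresses spurious single-point noise extrema while leaving the much
#'   wider endotherm/exotherm features in place. 0 disables smoothing.
#' @param endo_up Input sign convention flag, passed through to readers.
#' @return A list of class `dsc_config`.
#' @export
dsc_config <- function(grid_step = 0.1,
                       band_width_first = 10, band_width_second = 3,
                       band_start = 29,
                       search_min_exo = 50, search_min_endo = 40,
                       prominence_frac = 0.05, linearity_r2 = 0.98,
                       parallel_tol = 1e-6,
                       second_lower = c("tied", "selected"),
                       band_step = 0.1, smooth_k = 5L,
                       endo_ref_offset = c(4, 2), endo_up = FALSE) {
  structure(list(grid_step = grid_step, band_width_first = band_width_first,
                 band_width_second = band_width_second, band_start = band_start,
                 search_min_exo = search_min_exo, search_min_endo = search_min_endo,
                 prominence_frac = prominence_frac, linearity_r2 = linearity_r2,
                 parallel_tol = parallel_tol,
                 second_lower = match.arg(second_lower),
                 band_step = band_step, smooth_k = as.integer(smooth_k),
                 endo_ref_offset = endo_ref_offset, endo_up = isTRUE(endo_up)),
            class = "dsc_config")
}

# Normalize + resample on demand so every stage sees the same uniform grid.
prepare_thermogram <- function(t, config) {
  if (!t$normalized) t <- normalize_heat_flow(t)
  if (is.null(t$grid_step) || !isTRUE(all.equal(t$grid_step, config$grid_step)))
    t <- resample_uniform(t, step = config$grid_step)
  t
}

signal_of <- function(t, config) {
  y <- t$data$heat_flow
  if (config$smooth_k > 1L) y <- moving_mean(y, config$smooth_k)
  y
}

#' Detect the exotherm peak
#'
#' Finds the most prominent local maximum of heat flow at temperatures at or
#' above `search_min`, with prominence measured topographically against the
#' whole curve. Returns an "absent" result rather than failing when no
#' maximum reaches the prominence threshold, since heat-killed material shows
#' no exotherm.
#'
#' @param t A `thermogram` (raw thermograms are normalized and resampled
#'   internally).
#' @param search_min Lower temperature bound of the search (degC).
#' @param config A [dsc_config()].
#' @return A list with `present`, `t_exo`, `prominence` and `onset` (the
#'   temperature of the peak's left base, used to bound the endotherm search).
#' @export
detect_exotherm <- function(t, search_min = config$search_min_exo,
                            config = dsc_config()) {
  t <- prepare_thermogram(t, config)
  temp <- t$data$temperature
  if (max(temp) < search_min + 2 * config$grid_step)
    tt_value_error(sprintf("curve ends below the exotherm search region (>= %g degC)",
                           search_min))
  y <- signal_of(t, config)
  pk <- find_peaks(y)
  rng <- diff(range(y))
  thr <- config$prominence_frac * rng - 1e-9 * max(rng, 1)
  pk <- pk[temp[pk$index] >= search_min & pk$prominence >= thr, , drop = FALSE]
  if (!nrow(pk))
    return(list(present = FALSE, t_exo = NA_real_, prominence = NA_real_,
                onset = NA_real_))
  best <- pk[which.max(pk$prominence), ]
  list(present = TRUE, t_exo = temp[best$index], prominence = best$prominence,
       onset = temp[best$left_base])
}

#' Detect the endotherm dip
#'
#' Finds the deepest local minimum of heat flow (the endothermic "jag").
#' When an exotherm was detected the search is restricted to temperatures at
#' or below the exotherm's onset; otherwise the whole curve above
#' `search_min` is searched.
#'
#' A candidate minimum only counts as an endotherm if the curve drops below
#' the ordinary continuation of the decline that precedes it: its depth is
#' measured against a short line fitted 2-4 K to its left and extrapolated
#' to the minimum. This distinguishes the real jag from the corner that any
#' decline-then-exotherm curve necessarily has just before the peak, which
#' is topographically prominent but is not an endothermic event.
#'
#' @param t A `thermogram`.
#' @param exo Result of [detect_exotherm()], or `NULL`.
#' @param search_min Lower temperature bound (degC).
#' @param config A [dsc_config()]; `config$endo_ref_offset` gives the left
#'   reference window as offsets (K) below the candidate minimum.
#' @return A list with `t_endo`, `prominence` (the drop below the preceding
#'   trend) and `onset` (the left base of the dip).
#' @export
detect_endotherm <- function(t, exo = NULL,
                             search_min = config$search_min_endo,
                             config = dsc_config()) {
  t <- prepare_thermogram(t, config)
  temp <- t$data$temperature
  y <- signal_of(t, config)
  hi <- if (!is.null(exo) && isTRUE(exo$present)) exo$onset else max(temp)
  pk <- find_peaks(-y)                      # minima of y are maxima of -y
  rng <- diff(range(y))
  thr <- config$prominence_frac * rng - 1e-9 * max(rng, 1)
  pk <- pk[temp[pk$index] >= search_min & temp[pk$index] <= hi + 1e-9 &
             pk$prominence >= thr, , drop = FALSE]
  if (nrow(pk)) {
    pk$drop <- vapply(pk$index, function(i) {
      sel <- temp >= temp[i] - config$endo_ref_offset[1] - 1e-9 &
             temp <= temp[i] - config$endo_ref_offset[2] + 1e-9
      if (sum(sel) < 5L) return(NA_real_)
      ref <- ols_line(temp[sel], y[sel])
      (ref$intercept + ref$slope * temp[i]) - y[i]
    }, numeric(1))
    pk <- pk[!is.na(pk$drop) & pk$drop >= thr, , drop = FALSE]
  }
  if (!nrow(pk))
    tt_detection_error("no endotherm dip found above the prominence threshold (curve may be heat-killed)")
  best <- pk[which.max(pk$drop), ]
  list(t_endo = temp[best$index], prominence = best$drop,
       onset = temp[best$left_base])
}

#' Fit the first (baseline) line by a sliding 10 K band
#'
#' Slides a `band_width` K temperature band from `start` up to `t_endo` and
#' returns the ordinary-least-squares line of heat flow on temperature with
#' the highest R-squared; ties go to the lowest band start. The fit also
#' records `t_high_tied`, the top edge of the highest-starting band among the
#' R-squared ties, which delimits the second-line search.
#'
#' @param t A `thermogram`.
#' @param t_endo Endotherm peak temperature (degC); the band must fit between
#'   `start` and `t_endo`.
#' @param band_width Band width in K (default 10).
#' @param start Lower search limit in degC (default 29).
#' @param step Band step in K.
#' @param config A [dsc_config()].
#' @return A `line_segment`.
#' @export
fit_first_line <- function(t, t_endo, band_width = config$band_width_first,
                           start = config$band_start, step = config$band_step,
                           config = dsc_config()) {
  t <- prepare_thermogram(t, config)
  if (t_endo - start < band_width)
    tt_value_error(sprintf(
      "first-line fit needs t_endo - start >= %g K (got %.2f - %.2f = %.2f K)",
      band_width, t_endo, start, t_endo - start))
  band_search(t$data$temperature, signal_of(t, config),
              width = band_width, lo = start, hi = t_endo, step = step,
              select = "max_r2")
}

#' Fit the second (steep-decline) line by a sliding 3 K band
#'
#' Searches `band_width` K bands lying above the first line's upper edge and
#' below `t_endo` for the highest-R-squared line; ties go to the lowest band
#' start.
#'
#' @param t A `thermogram`.
#' @param first The `line_segment` from [fit_first_line()].
#' @param t_endo Endotherm peak temperature (degC).
#' @param band_width Band width in K (default 3).
#' @param step Band step in K.
#' @param config A [dsc_config()]; `config$second_lower` selects whether the
#'   search starts at `first$t_high_tied` (default) or `first$band[2]`.
#' @return A `line_segment`.
#' @export
fit_second_line <- function(t, first, t_endo,
                            band_width = config$band_width_second,
                            step = config$band_step, config = dsc_config()) {
  t <- prepare_thermogram(t, config)
  lo <- if (config$second_lower == "tied") first$t_high_tied %||% first$band[2]
        else first$band[2]
  if (t_endo - lo < band_width)
    tt_detection_error(sprintf(
      "no admissible second band: t_endo (%.2f) - first-line top (%.2f) < %g K",
      t_endo, lo, band_width))
  band_search(t$data$temperature, signal_of(t, config),
              width = band_width, lo = lo, hi = t_endo, step = step,
              select = "max_r2")
}

#' Intersect two fitted lines
#'
#' @param l1,l2 `line_segment` objects (or lists with `slope`, `intercept`).
#' @param tol Minimum |slope difference| below which the lines are treated as
#'   parallel (degenerate).
#' @return The temperature (degC) at which the lines cross.
#' @export
intersect_lines <- function(l1, l2, tol = 1e-6) {
  ds <- l1$slope - l2$slope
  if (abs(ds) < tol)
    tt_degeneracy_error(sprintf(
      "lines are near-parallel (|slope difference| = %.3g < %.3g)", abs(ds), tol))
  (l2$intercept - l1$intercept) / ds
}

#' Classify a thermogram as vital, heat-killed or indeterminate
#'
#' Vital curves show both an endotherm dip and an exotherm peak above the
#' prominence threshold. Curves with neither feature that are well described
#' by a single line over the full span (R-squared at or above
#' `config$linearity_r2`) are heat-killed; anything else is indeterminate.
#'
#' @param t A `thermogram`.
#' @param config A [dsc_config()].
#' @return One of `"vital"`, `"heat_killed"`, `"indeterminate"`.
#' @export
classify_vitality <- function(t, config = dsc_config()) {
  t <- prepare_thermogram(t, config)
  exo <- detect_exotherm(t, config = config)
  endo <- tryCatch(detect_endotherm(t, exo = exo, config = config),
                   tt_detection_error = function(e) NULL)
  has_dip <- !is.null(endo)
  has_peak <- isTRUE(exo$present)
  if (has_dip && has_peak) return("vital")
  if (!has_dip && !has_peak) {
    full <- ols_line(t$data$temperature, t$data$heat_flow)
    if (full$r_squared >= config$linearity_r2) return("heat_killed")
  }
  "indeterminate"
}

#' Full thermogram analysis
#'
#' Runs the whole pipeline on one thermogram: normalization (if needed),
#' uniform resampling, exotherm and endotherm detection, the 10 K and 3 K
#' sliding-band line fits, the line intersection (T_init) and vitality
#' classification. Stages that cannot run on a heat-killed-type curve are
#' reported as explicit `NA` results with the failure message kept in
#' `diagnostics`; nothing is silently defaulted.
#'
#' @param t A `thermogram`, raw or normalized.
#' @param config A [dsc_config()].
#' @return A `thermal_thresholds` object: `t_init`, `t_endo`, `t_exo`,
#'   `first_line`, `second_line`, `vitality`, `exo_prominence`,
#'   `endo_prominence`, `diagnostics`, plus the sample metadata.
#' @export
analyze_thermogram <- function(t, config = dsc_config()) {
  stopifnot(inherits(t, "thermogram"))
  t <- prepare_thermogram(t, config)
  diag <- character(0)
  vitality <- classify_vitality(t, config)

  exo <- detect_exotherm(t, config = config)
  if (!exo$present) diag <- c(diag, "exotherm: no peak above the prominence threshold")

  endo <- tryCatch(detect_endotherm(t, exo = exo, config = config),
                   tt_detection_error = function(e) {
                     diag <<- c(diag, paste0("endotherm: ", conditionMessage(e)))
                     NULL
                   })

  first <- second <- NULL
  t_init <- NA_real_
  if (!is.null(endo)) {
    first <- tryCatch(fit_first_line(t, endo$t_endo, config = config),
                      thermotol_error = function(e) {
                        diag <<- c(diag, paste0("first line: ", conditionMessage(e)))
                        NULL
                      })
    if (!is.null(first)) {
      second <- tryCatch(fit_second_line(t, first, endo$t_endo, config = config),
                         thermotol_error = function(e) {
                           diag <<- c(diag, paste0("second line: ", conditionMessage(e)))
                           NULL
                         })
    }
    if (!is.null(first) && !is.null(second)) {
      t_init <- tryCatch(intersect_lines(first, second, tol = config$parallel_tol),
                         tt_degeneracy_error = function(e) {
                           diag <<- c(diag, paste0("intersection: ", conditionMessage(e)))
                           NA_real_
                         })
      if (!is.na(t_init) && (t_init < min(t$data$temperature) ||
                             t_init > max(t$data$temperature))) {
        diag <- c(diag, sprintf("intersection at %.2f degC lies outside the curve; discarded", t_init))
        t_init <- NA_real_
      }
    }
  }

  structure(
    list(sample_id = t$sample_id, species = t$species, run_kind = t$run_kind,
         t_init = t_init,
         t_endo = if (is.null(endo)) NA_real_ else endo$t_endo,
         t_exo = exo$t_exo,
         exo_prominence = exo$prominence,
         endo_prominence = if (is.null(endo)) NA_real_ else endo$prominence,
         first_line = first, second_line = second,
         vitality = vitality, diagnostics = diag),
    class = "thermal_thresholds"
  )
}

#' @export
print.thermal_thresholds <- function(x, ...) {
  cat(sprintf("thermal thresholds for '%s' (%s):\n", x$sample_id, x$vitality))
  cat(sprintf("  T_init = %s degC\n  T_endo = %s degC\n  T_exo  = %s degC\n",
              format(round(x$t_init, 2)), format(round(x$t_endo, 2)),
              format(round(x$t_exo, 2))))
  if (length(x$diagnostics))
    cat("  diagnostics:\n", paste0("   - ", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

#' Thresholds from a thermal_thresholds object as a one-row data.frame
#'
#' @param x A `thermal_thresholds` object.
#' @return A one-row data.frame suitable for rbind-ing into a results table.
#' @export
as.data.frame.thermal_thresholds <- function(x, ...) {
  data.frame(sample_id = x$sample_id, species = x$species,
             run_kind = x$run_kind,
             t_init = x$t_init, t_endo = x$t_endo, t_exo = x$t_exo,
             vitality = x$vitality,
             first_band_lo = if (is.null(x$first_line)) NA_real_ else x$first_line$band[1],
             first_band_hi = if (is.null(x$first_line)) NA_real_ else x$first_line$band[2],
             first_r2 = if (is.null(x$first_line)) NA_real_ else x$first_line$r_squared,
             second_band_lo = if (is.null(x$second_line)) NA_real_ else x$second_line$band[1],
             second_band_hi = if (is.null(x$second_line)) NA_real_ else x$second_line$band[2],
             second_r2 = if (is.null(x$second_line)) NA_real_ else x$second_line$r_squared,
             stringsAsFactors = FALSE)
}
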