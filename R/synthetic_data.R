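## synthetic_data: generators for thermograms, T-F0 curves and viability
## assays with recorded ground truth, so every analysis stage can be tested
## by parameter recovery without instrument data.

gauss <- function(x, center, amp, width) amp * exp(-(x - center)^2 / (2 * width^2))

## ground-truth constructors -------------------------------------------------

#' Ground truth for a synthetic vital thermogram
#'
#' Describes the analytic shape of a vital-leaf DSC trace (normalized,
#' exo-up): a continuous two-segment piecewise-linear decline joined at
#' `breakpoint`, minus a Gaussian endotherm dip, plus a Gaussian exotherm
#' peak. Defaults place the breakpoint at 52 degC, the endotherm near
#' 57.5 degC and the exotherm near 60.5 degC — inside the temperature ranges
#' reported for summer-active mountain-plant leaves — with noise sd equal to
#' 2% of the exotherm height.
#'
#' Because the dip and peak ride on a sloped baseline, the actual extremum of
#' the noiseless curve is displaced slightly from the Gaussian center; the
#' constructor therefore also records `t_endo_true` and `t_exo_true`, the
#' analytic extremum locations, which are the recovery targets for the
#' detectors. The recovery target for T_init is `breakpoint`.
#'
#' @param baseline_intercept Normalized heat flow (mW/g) at `t_min`.
#' @param baseline_slope First-segment slope (mW/g/K), negative
#'   (endothermic decline).
#' @param breakpoint Temperature (degC) where the decline steepens; the
#'   T_init ground truth.
#' @param post_slope Second-segment slope (mW/g/K).
#' @param endo_center,endo_depth,endo_width Gaussian endotherm dip
#'   parameters (degC, mW/g, K).
#' @param exo_center,exo_height,exo_width Gaussian exotherm peak parameters.
#' @param noise_sd Homoscedastic Gaussian noise sd (mW/g).
#' @param t_min,t_max,grid_step Temperature grid (degC, K).
#' @param rate Heating rate (K/min), used to derive the time column.
#' @param fresh_mass Fresh mass (mg) used to de-normalize into raw mW.
#' @param seed RNG seed; generation is a pure function of (truth, seed).
#' @return A list of class `dsc_truth`.
#' @export
dsc_truth <- function(baseline_intercept = 0, baseline_slope = -0.5,
                      breakpoint = 52, post_slope = -3,
                      endo_center = 57.5, endo_depth = 12, endo_width = 1.0,
                      exo_center = 60.5, exo_height = 25, exo_width = 0.8,
                      noise_sd = 0.02 * exo_height,
                      t_min = 25, t_max = 65, grid_step = 0.1, rate = 1,
                      fresh_mass = 20, seed = 1L) {
  if (!(breakpoint < endo_center && endo_center < exo_center))
    tt_value_error("need breakpoint < endo_center < exo_center")
  if (endo_width <= 0 || exo_width <= 0)
    tt_value_error("peak widths must be positive")
  if (noise_sd < 0) tt_value_error("noise_sd must be non-negative")
  truth <- structure(
    list(baseline_intercept = baseline_intercept, baseline_slope = baseline_slope,
         breakpoint = breakpoint, post_slope = post_slope,
         endo_center = endo_center, endo_depth = endo_depth, endo_width = endo_width,
         exo_center = exo_center, exo_height = exo_height, exo_width = exo_width,
         noise_sd = noise_sd, t_min = t_min, t_max = t_max,
         grid_step = grid_step, rate = rate, fresh_mass = fresh_mass,
         seed = as.integer(seed)),
    class = "dsc_truth")
  truth$t_endo_true <- stats::optimize(
    function(x) dsc_shape(x, truth),
    c(endo_center - 3 * endo_width, endo_center + 3 * endo_width),
    maximum = FALSE, tol = 1e-10)$minimum
  truth$t_exo_true <- stats::optimize(
    function(x) dsc_shape(x, truth),
    c(exo_center - 3 * exo_width, exo_center + 3 * exo_width),
    maximum = TRUE, tol = 1e-10)$maximum
  truth
}

# Noiseless analytic thermogram shape (normalized heat flow, mW/g).
dsc_shape <- function(temp, truth) {
  base <- ifelse(
    temp <= truth$breakpoint,
    truth$baseline_intercept + truth$baseline_slope * (temp - truth$t_min),
    truth$baseline_intercept + truth$baseline_slope * (truth$breakpoint - truth$t_min) +
      truth$post_slope * (temp - truth$breakpoint))
  base -
    gauss(temp, truth$endo_center, truth$endo_depth, truth$endo_width) +
    gauss(temp, truth$exo_center, truth$exo_height, truth$exo_width)
}

#' Ground truth for a synthetic reheat (heat-killed) thermogram
#'
#' The reheated heat-killed control shows a near-linear decline with no
#' endotherm dip and no exotherm peak.
#'
#' @param intercept,slope Line parameters (mW/g at `t_min`, mW/g/K).
#' @param noise_sd Gaussian noise sd (mW/g).
#' @param t_min,t_max,grid_step,rate,fresh_mass,seed As in [dsc_truth()].
#' @return A list of class `reheat_truth`.
#' @export
reheat_truth <- function(intercept = 0, slope = -0.5, noise_sd = 0.5,
                         t_min = 25, t_max = 65, grid_step = 0.1, rate = 1,
                         fresh_mass = 20, seed = 1L) {
  structure(
    list(intercept = intercept, slope = slope, noise_sd = noise_sd,
         t_min = t_min, t_max = t_max, grid_step = grid_step, rate = rate,
         fresh_mass = fresh_mass, seed = as.integer(seed)),
    class = "reheat_truth")
}

temp_grid <- function(truth) {
  seq(truth$t_min, by = truth$grid_step,
      length.out = floor((truth$t_max - truth$t_min) / truth$grid_step + 1e-9) + 1L)
}

make_raw_thermogram <- function(temp, flow_norm, truth, sample_id, run_kind) {
  raw <- flow_norm * (truth$fresh_mass / 1000)   # back to mW so readers see raw data
  d <- data.frame(time = (temp - truth$t_min) / truth$rate,
                  temperature = temp, heat_flow = raw)
  new_thermogram(d, sample_id = sample_id, species = "synthetic",
                 fresh_mass = truth$fresh_mass, normalized = FALSE,
                 run_kind = run_kind)
}

#' Generate a synthetic vital thermogram
#'
#' Evaluates the analytic shape of [dsc_truth()] on the temperature grid,
#' adds seeded Gaussian noise, and de-normalizes by fresh mass so the result
#' is a raw (mW) thermogram as a reader would produce.
#'
#' @param truth A [dsc_truth()].
#' @param sample_id Sample identifier.
#' @return A list with `thermogram` and the `truth` that generated it.
#' @export
generate_thermogram <- function(truth = dsc_truth(), sample_id = "synthetic_vital") {
  stopifnot(inherits(truth, "dsc_truth"))
  temp <- temp_grid(truth)
  flow <- dsc_shape(temp, truth)
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    flow <- flow + stats::rnorm(length(flow), 0, truth$noise_sd)
  }
  list(thermogram = make_raw_thermogram(temp, flow, truth, sample_id, "initial"),
       truth = truth)
}

#' Generate a synthetic reheat (heat-killed) thermogram
#'
#' @param truth A [reheat_truth()].
#' @param sample_id Sample identifier.
#' @return A list with `thermogram` and `truth`.
#' @export
generate_reheat_thermogram <- function(truth = reheat_truth(),
                                       sample_id = "synthetic_reheat") {
  stopifnot(inherits(truth, "reheat_truth"))
  temp <- temp_grid(truth)
  flow <- truth$intercept + truth$slope * (temp - truth$t_min)
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    flow <- flow + stats::rnorm(length(flow), 0, truth$noise_sd)
  }
  list(thermogram = make_raw_thermogram(temp, flow, truth, sample_id, "reheat"),
       truth = truth)
}

## T-F0 ----------------------------------------------------------------------

#' Ground truth for a synthetic T-F0 curve
#'
#' Flat F0 baseline up to `t_c`, linear rise to a plateau at `plateau_end`,
#' then Gaussian peaks at `tp_center` and (optionally) `tpII_center`.
#' Defaults put T_c at 43 degC, T_p at 52 degC and T_pII at 58.5 degC,
#' matching the pooled ranges reported for summer leaves.
#'
#' @param baseline Baseline F0 level (relative units).
#' @param t_c Temperature (degC) where F0 starts rising; the T_c truth.
#' @param rise_slope F0 rise per K above `t_c`.
#' @param plateau_end Temperature where the rise saturates.
#' @param tp_center,tp_height,tp_width First-peak Gaussian parameters;
#'   `tp_center` is the T_p truth.
#' @param tpII_center,tpII_height,tpII_width Second-peak parameters;
#'   `tpII_center` is the T_pII truth.
#' @param include_tpII Generate the second peak? (`FALSE` makes T_pII absent.)
#' @param noise_sd Gaussian noise sd (F0 units).
#' @param t_min,t_max,grid_step Temperature grid.
#' @param seed RNG seed.
#' @return A list of class `f0_truth`.
#' @export
f0_truth <- function(baseline = 100, t_c = 43, rise_slope = 40,
                     plateau_end = 50,
                     tp_center = 52, tp_height = 150, tp_width = 1.0,
                     tpII_center = 58.5, tpII_height = 120, tpII_width = 1.2,
                     include_tpII = TRUE, noise_sd = 2,
                     t_min = 25, t_max = 65, grid_step = 0.1, seed = 1L) {
  if (!(t_c < plateau_end && plateau_end <= tp_center))
    tt_value_error("need t_c < plateau_end <= tp_center")
  if (include_tpII && tpII_center <= tp_center)
    tt_value_error("tpII_center must exceed tp_center")
  structure(
    list(baseline = baseline, t_c = t_c, rise_slope = rise_slope,
         plateau_end = plateau_end,
         tp_center = tp_center, tp_height = tp_height, tp_width = tp_width,
         tpII_center = tpII_center, tpII_height = tpII_height,
         tpII_width = tpII_width, include_tpII = isTRUE(include_tpII),
         noise_sd = noise_sd, t_min = t_min, t_max = t_max,
         grid_step = grid_step, seed = as.integer(seed)),
    class = "f0_truth")
}

f0_shape <- function(temp, truth) {
  y <- truth$baseline + truth$rise_slope *
    pmin(pmax(temp - truth$t_c, 0), truth$plateau_end - truth$t_c)
  y <- y + gauss(temp, truth$tp_center, truth$tp_height, truth$tp_width)
  if (truth$include_tpII)
    y <- y + gauss(temp, truth$tpII_center, truth$tpII_height, truth$tpII_width)
  y
}

#' Generate a synthetic T-F0 curve
#'
#' @param truth An [f0_truth()].
#' @param sample_id Sample identifier.
#' @return A list with `curve` (an `f0_curve`) and `truth`.
#' @export
generate_f0_curve <- function(truth = f0_truth(), sample_id = "synthetic_f0") {
  stopifnot(inherits(truth, "f0_truth"))
  temp <- temp_grid(truth)
  y <- f0_shape(temp, truth)
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    y <- y + stats::rnorm(length(y), 0, truth$noise_sd)
  }
  y <- pmax(y, 0)
  list(curve = new_f0_curve(data.frame(temperature = temp, f0 = y), sample_id),
       truth = truth)
}

## viability assays ----------------------------------------------------------

#' Ground truth for a synthetic viability assay
#'
#' Fv/Fm drawn from the damage sigmoid at the target temperatures with
#' replicate Gaussian noise, clipped to the unit interval. The default design follows
#' the classical test layout: ten targets 2 K apart from 38 to 56 degC, an
#' unheated control near `A1` and one full-damage sample at 65 degC.
#'
#' @param A1,A2,x0,p Sigmoid parameters (see [damage_sigmoid()]).
#' @param temperatures Target temperatures (degC).
#' @param replicates Replicates per target temperature.
#' @param noise_sd Replicate noise sd (Fv/Fm units).
#' @param include_control Include an unheated control value near `A1`?
#' @param full_damage_temp Temperature of the single full-damage sample
#'   (`NA` to omit).
#' @param seed RNG seed.
#' @return A list of class `assay_truth`.
#' @export
assay_truth <- function(A1 = 0.8, A2 = 0.05, x0 = 50, p = 40,
                        temperatures = seq(38, 56, by = 2), replicates = 8,
                        noise_sd = 0.03, include_control = TRUE,
                        full_damage_temp = 65, seed = 1L) {
  if (A1 <= A2) tt_value_error("need A1 > A2 for a damage curve")
  if (p <= 0) tt_value_error("p must be positive")
  structure(
    list(A1 = A1, A2 = A2, x0 = x0, p = p, temperatures = temperatures,
         replicates = as.integer(replicates), noise_sd = noise_sd,
         include_control = isTRUE(include_control),
         full_damage_temp = full_damage_temp, seed = as.integer(seed)),
    class = "assay_truth")
}

#' Generate a synthetic viability assay
#'
#' @param truth An [assay_truth()].
#' @return A list with `assay` (a `viability_assay`) and `truth`.
#' @export
generate_viability_assay <- function(truth = assay_truth()) {
  stopifnot(inherits(truth, "assay_truth"))
  set.seed(truth$seed)
  tt <- rep(truth$temperatures, each = truth$replicates)
  mu <- damage_sigmoid(tt, truth$A1, truth$A2, truth$x0, truth$p)
  noise <- if (truth$noise_sd > 0) stats::rnorm(length(mu), 0, truth$noise_sd) else 0
  d <- data.frame(
    temperature = tt,
    replicate = paste0("r", sequence(rep(truth$replicates, length(truth$temperatures)))),
    fvfm = pmin(pmax(mu + noise, 0), 1),
    stringsAsFactors = FALSE)
  if (!is.na(truth$full_damage_temp)) {
    y65 <- damage_sigmoid(truth$full_damage_temp, truth$A1, truth$A2,
                          truth$x0, truth$p)
    if (truth$noise_sd > 0) y65 <- y65 + stats::rnorm(1, 0, truth$noise_sd)
    d <- rbind(d, data.frame(temperature = truth$full_damage_temp,
                             replicate = "r1", fvfm = pmin(pmax(y65, 0), 1)))
  }
  control <- NULL
  if (truth$include_control) {
    control <- truth$A1
    if (truth$noise_sd > 0) control <- control + stats::rnorm(1, 0, truth$noise_sd)
    control <- pmin(pmax(control, 0), 1)
  }
  list(assay = new_viability_assay(d, control_fvfm = control), truth = truth)
}
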