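## thermo_io: curve data model, reading, validation, normalization,
## resampling and aggregation of the three curve/table types.

#' Default DSC heating protocol
#'
#' Models the two-run temperature program used for leaf thermograms: heat from
#' `t_min` to `t_max` at `rate` (K per minute), cool back at the same rate,
#' and repeat for `runs` runs (the second run reheats the now heat-killed
#' sample).
#'
#' @param t_min,t_max Temperature window in degrees Celsius.
#' @param rate Heating (and cooling) rate in K per minute.
#' @param runs Number of heat--cool runs.
#' @return A list with `heat_min` (one heating segment), `per_run_min`
#'   (heat + cool) and `total_min` (all runs).
#' @examples
#' dsc_protocol()$total_min  # 160 minutes for the default 25--65 degC program
#' @export
dsc_protocol <- function(t_min = 25, t_max = 65, rate = 1, runs = 2) {
  if (t_max <= t_min) tt_value_error("t_max must exceed t_min")
  if (rate <= 0) tt_value_error("rate must be positive")
  heat <- (t_max - t_min) / rate
  list(heat_min = heat, per_run_min = 2 * heat, total_min = runs * 2 * heat)
}

## constructors --------------------------------------------------------------

new_thermogram <- function(data, sample_id, species = NA_character_,
                           fresh_mass = NA_real_, normalized = FALSE,
                           run_kind = c("initial", "reheat")) {
  run_kind <- match.arg(run_kind)
  structure(
    list(sample_id = as.character(sample_id), species = as.character(species),
         fresh_mass = as.numeric(fresh_mass),
         data = data, normalized = isTRUE(normalized), run_kind = run_kind),
    class = "thermogram"
  )
}

validate_thermogram <- function(t) {
  d <- t$data
  if (!nrow(d)) tt_data_error("thermogram has no points")
  if (!is.na(t$fresh_mass) && t$fresh_mass <= 0)
    tt_value_error("fresh_mass must be positive")
  if (any(diff(d$temperature) <= 0))
    tt_data_error("temperature must be strictly increasing along the heating ramp")
  invisible(t)
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("thermogram '%s'%s: %d points, %.1f-%.1f degC, mass %.2f mg, %s, %s\n",
              x$sample_id,
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              nrow(x$data), min(x$data$temperature), max(x$data$temperature),
              x$fresh_mass,
              if (x$normalized) "normalized (mW/g)" else "raw (mW)",
              x$run_kind))
  invisible(x)
}

new_f0_curve <- function(data, sample_id) {
  structure(list(sample_id = as.character(sample_id), data = data),
            class = "f0_curve")
}

#' @export
print.f0_curve <- function(x, ...) {
  cat(sprintf("T-F0 curve '%s': %d points, %.1f-%.1f degC\n", x$sample_id,
              nrow(x$data), min(x$data$temperature), max(x$data$temperature)))
  invisible(x)
}

new_viability_assay <- function(data, control_fvfm = NULL) {
  structure(list(data = data, control_fvfm = control_fvfm),
            class = "viability_assay")
}

#' @export
print.viability_assay <- function(x, ...) {
  cat(sprintf("viability assay: %d records at %d target temperatures%s\n",
              nrow(x$data), length(unique(x$data$temperature)),
              if (is.null(x$control_fvfm)) "" else
                sprintf(", unheated control Fv/Fm = %.3f", x$control_fvfm)))
  invisible(x)
}

## public in-code constructors -----------------------------------------------

#' Construct curve objects from vectors
#'
#' Programmatic counterparts of the file readers, for building curves in
#' code. The same validation applies.
#'
#' @param time,temperature,heat_flow,f0,fvfm,replicate Data vectors.
#' @param sample_id,species,fresh_mass,normalized,run_kind Metadata as in
#'   [read_thermogram()].
#' @param control_fvfm Optional unheated-control Fv/Fm.
#' @return A `thermogram`, `f0_curve` or `viability_assay`.
#' @name thermotol-constructors
NULL

#' @rdname thermotol-constructors
#' @export
thermogram <- function(time, temperature, heat_flow, sample_id = "sample",
                       species = NA, fresh_mass = NA, normalized = FALSE,
                       run_kind = c("initial", "reheat")) {
  d <- data.frame(time = as.numeric(time),
                  temperature = as.numeric(temperature),
                  heat_flow = as.numeric(heat_flow))
  d <- d[order(d$time), , drop = FALSE]
  t <- new_thermogram(d, sample_id = sample_id, species = species,
                      fresh_mass = fresh_mass, normalized = normalized,
                      run_kind = match.arg(run_kind))
  validate_thermogram(t)
  t
}

#' @rdname thermotol-constructors
#' @export
f0_curve <- function(temperature, f0, sample_id = "sample") {
  d <- data.frame(temperature = as.numeric(temperature), f0 = as.numeric(f0))
  d <- d[order(d$temperature), , drop = FALSE]
  if (any(diff(d$temperature) <= 0))
    tt_data_error("temperature must be strictly increasing")
  if (any(d$f0 < 0)) tt_value_error("F0 must be non-negative")
  new_f0_curve(d, sample_id)
}

#' @rdname thermotol-constructors
#' @export
viability_assay <- function(temperature, replicate, fvfm, control_fvfm = NULL) {
  if (any(fvfm < 0 | fvfm > 1))
    tt_value_error("Fv/Fm values must lie within [0, 1]")
  if (length(unique(temperature)) < 2L)
    tt_value_error("at least 2 distinct target temperatures are required")
  new_viability_assay(
    data.frame(temperature = as.numeric(temperature),
               replicate = as.character(replicate),
               fvfm = as.numeric(fvfm), stringsAsFactors = FALSE),
    control_fvfm = control_fvfm)
}

## delimited reading ---------------------------------------------------------

# Comma or tab separator auto-detected from the header line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) tt_format_error(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(unname(cols), names(df))
  if (length(missing))
    tt_format_error(sprintf("%s: missing column(s) %s", path,
                            paste(missing, collapse = ", ")))
}

# Collapse duplicate temperatures (instrument jitter) to their mean response.
dedupe_by_temperature <- function(df, value_cols) {
  if (!anyDuplicated(df$temperature)) return(df)
  sp <- split(df, df$temperature)
  out <- do.call(rbind, lapply(sp, function(g) {
    r <- g[1L, , drop = FALSE]
    for (v in value_cols) r[[v]] <- mean(g[[v]])
    r
  }))
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a DSC thermogram from delimited text
#'
#' Reads a comma- or tab-separated file with time, sample temperature and raw
#' heat-flow columns, sorts by time, trims to the protocol temperature window,
#' collapses duplicate temperatures and validates the heating ramp.
#'
#' @param path Path to the delimited text file (separator auto-detected).
#' @param fresh_mass Fresh mass of the leaf sample in mg; must be positive.
#'   Masses outside `mass_range` only raise a warning (plausibility check
#'   against the observed working range of the method, not a hard limit).
#' @param sample_id,species,run_kind Sample metadata; `run_kind` is
#'   `"initial"` (vital leaf) or `"reheat"` (heat-killed control run).
#' @param columns Named character vector mapping the canonical names `time`,
#'   `temperature`, `heat_flow` to the column names in the file.
#' @param window Temperature trimming window in degC (the heating protocol).
#' @param endo_up Set `TRUE` if the instrument writes endothermic-positive
#'   heat flow; the sign is then flipped so that the package-wide convention
#'   (exothermic-positive, "exo-up") holds.
#' @param mass_range Soft plausibility bounds for `fresh_mass` in mg.
#' @return A `thermogram` object (raw units, `normalized = FALSE`).
#' @seealso [normalize_heat_flow()], [resample_uniform()], [analyze_thermogram()]
#' @export
read_thermogram <- function(path, fresh_mass,
                            sample_id = basename(path), species = NA,
                            run_kind = c("initial", "reheat"),
                            columns = c(time = "time",
                                        temperature = "temperature",
                                        heat_flow = "heat_flow"),
                            window = c(25, 65), endo_up = FALSE,
                            mass_range = c(9.40, 33.46)) {
  run_kind <- match.arg(run_kind)
  if (!is.numeric(fresh_mass) || length(fresh_mass) != 1L || fresh_mass <= 0)
    tt_value_error("fresh_mass must be a single positive number (mg)")
  if (fresh_mass < mass_range[1] || fresh_mass > mass_range[2])
    warning(sprintf(
      "fresh_mass %.2f mg is outside the usual working range [%.2f, %.2f] mg",
      fresh_mass, mass_range[1], mass_range[2]), call. = FALSE)
  df <- read_delim_auto(path)
  require_columns(df, columns, path)
  d <- data.frame(time        = as.numeric(df[[columns[["time"]]]]),
                  temperature = as.numeric(df[[columns[["temperature"]]]]),
                  heat_flow   = as.numeric(df[[columns[["heat_flow"]]]]))
  if (anyNA(d)) tt_data_error(sprintf("%s: non-numeric or missing values", path))
  d <- d[order(d$time), , drop = FALSE]
  d <- d[d$temperature >= window[1] - 1e-9 & d$temperature <= window[2] + 1e-9, ,
         drop = FALSE]
  if (!nrow(d))
    tt_data_error(sprintf("%s: no points within the [%g, %g] degC window",
                          path, window[1], window[2]))
  if (any(diff(d$temperature) < 0))
    tt_data_error(sprintf("%s: temperature decreases along the run; only the heating ramp is supported",
                          path))
  d <- dedupe_by_temperature(d, c("time", "heat_flow"))
  if (endo_up) d$heat_flow <- -d$heat_flow
  rownames(d) <- NULL
  t <- new_thermogram(d, sample_id = sample_id, species = species,
                      fresh_mass = fresh_mass, normalized = FALSE,
                      run_kind = run_kind)
  validate_thermogram(t)
  t
}

#' Normalize heat flow by fresh mass
#'
#' Divides raw heat flow (mW) by fresh mass expressed in grams, giving
#' mW per g fresh weight. Normalizing twice is an error.
#'
#' @param t A `thermogram`.
#' @return The normalized `thermogram`.
#' @export
normalize_heat_flow <- function(t) {
  stopifnot(inherits(t, "thermogram"))
  if (t$normalized) tt_state_error("thermogram is already normalized")
  if (is.na(t$fresh_mass) || t$fresh_mass <= 0)
    tt_value_error("fresh_mass must be positive to normalize")
  t$data$heat_flow <- t$data$heat_flow / (t$fresh_mass / 1000)
  t$normalized <- TRUE
  t
}

## resampling ----------------------------------------------------------------

#' Resample a curve onto a uniform temperature grid
#'
#' Linear interpolation of the response onto a grid running from
#' `ceiling(min T)` to `floor(max T)` in steps of `step` K. The band-fit
#' searches require this regular grid.
#'
#' @param x A `thermogram` (must be normalized) or `f0_curve`.
#' @param step Grid step in K (default 0.1).
#' @return An object of the same class on the uniform grid.
#' @export
resample_uniform <- function(x, step = 0.1) UseMethod("resample_uniform")

resample_xy <- function(temp, value, step) {
  if (step <= 0) tt_value_error("step must be positive")
  # snap the grid ends inward to multiples of the step
  lo_i <- ceiling(min(temp) / step - 1e-9)
  hi_i <- floor(max(temp) / step + 1e-9)
  if (hi_i <= lo_i)
    tt_value_error(sprintf("step %.3g K exceeds the curve span of %.3g K",
                           step, diff(range(temp))))
  grid <- (lo_i:hi_i) * step
  list(temperature = grid,
       value = stats::approx(temp, value, xout = grid, ties = "ordered")$y)
}

#' @export
resample_uniform.thermogram <- function(x, step = 0.1) {
  if (!x$normalized)
    tt_state_error("resample_uniform expects a normalized thermogram")
  g <- resample_xy(x$data$temperature, x$data$heat_flow, step)
  time <- stats::approx(x$data$temperature, x$data$time,
                        xout = g$temperature, ties = "ordered")$y
  x$data <- data.frame(time = time, temperature = g$temperature,
                       heat_flow = g$value)
  x$grid_step <- step
  x
}

#' @export
resample_uniform.f0_curve <- function(x, step = 0.1) {
  g <- resample_xy(x$data$temperature, x$data$f0, step)
  x$data <- data.frame(temperature = g$temperature, f0 = g$value)
  x$grid_step <- step
  x
}

## aggregation ---------------------------------------------------------------

#' Aggregate normalized thermograms over a rounded temperature grid
#'
#' Pools several leaves of the same species the way mean curves are drawn:
#' temperatures are rounded to `rounding` decimals, each curve contributes its
#' within-bin mean, and across curves the mean, sample standard deviation
#' (reported only where at least two curves contribute) and n are returned
#' per bin. Bins covered by no curve are omitted.
#'
#' @param curves List of normalized `thermogram` objects.
#' @param rounding Decimals for the temperature bins (default 1).
#' @return A data.frame of class `aggregate_curve` with columns
#'   `temperature`, `mean`, `sd`, `n`.
#' @export
aggregate_curves <- function(curves, rounding = 1) {
  if (inherits(curves, "thermogram")) curves <- list(curves)
  if (!length(curves)) tt_value_error("aggregate_curves needs at least one curve")
  ok <- vapply(curves, function(c) inherits(c, "thermogram") && c$normalized,
               logical(1))
  if (!all(ok)) tt_value_error("all curves must be normalized thermograms")
  per <- lapply(curves, function(c) {
    bin <- round(c$data$temperature, rounding)
    v <- tapply(c$data$heat_flow, bin, mean)
    data.frame(temperature = as.numeric(names(v)), value = as.numeric(v))
  })
  all_t <- sort(unique(unlist(lapply(per, `[[`, "temperature"))))
  m <- sapply(per, function(p) p$value[match(all_t, p$temperature)])
  m <- matrix(m, nrow = length(all_t))
  n <- rowSums(!is.na(m))
  out <- data.frame(
    temperature = all_t,
    mean = rowMeans(m, na.rm = TRUE),
    sd = apply(m, 1L, function(r) if (sum(!is.na(r)) >= 2L) stats::sd(r, na.rm = TRUE) else NA_real_),
    n = n
  )
  structure(out[out$n >= 1L, , drop = FALSE],
            class = c("aggregate_curve", "data.frame"))
}

## F0 curves and viability tables --------------------------------------------

#' Read a T-F0 curve from delimited text
#'
#' @param path Path to the file; separator auto-detected.
#' @param sample_id Sample identifier.
#' @param columns Named vector mapping `temperature` and `f0` to file columns.
#' @return An `f0_curve`.
#' @export
read_f0_curve <- function(path, sample_id = basename(path),
                          columns = c(temperature = "temperature", f0 = "f0")) {
  df <- read_delim_auto(path)
  require_columns(df, columns, path)
  d <- data.frame(temperature = as.numeric(df[[columns[["temperature"]]]]),
                  f0 = as.numeric(df[[columns[["f0"]]]]))
  if (anyNA(d)) tt_data_error(sprintf("%s: non-numeric or missing values", path))
  d <- d[order(d$temperature), , drop = FALSE]
  d <- dedupe_by_temperature(d, "f0")
  if (any(diff(d$temperature) <= 0))
    tt_data_error("temperature must be strictly increasing")
  if (any(d$f0 < 0)) tt_value_error("F0 must be non-negative")
  rownames(d) <- NULL
  new_f0_curve(d, sample_id)
}

#' Read a viability (Fv/Fm) assay table from delimited text
#'
#' @param path Path to the file; separator auto-detected.
#' @param columns Named vector mapping `temperature`, `replicate`, `fvfm` to
#'   file columns.
#' @param control_fvfm Optional unheated-control Fv/Fm value.
#' @return A `viability_assay`.
#' @export
read_viability_table <- function(path,
                                 columns = c(temperature = "temperature",
                                             replicate = "replicate",
                                             fvfm = "fvfm"),
                                 control_fvfm = NULL) {
  df <- read_delim_auto(path)
  require_columns(df, columns, path)
  d <- data.frame(temperature = as.numeric(df[[columns[["temperature"]]]]),
                  replicate = as.character(df[[columns[["replicate"]]]]),
                  fvfm = as.numeric(df[[columns[["fvfm"]]]]),
                  stringsAsFactors = FALSE)
  if (anyNA(d$temperature) || anyNA(d$fvfm))
    tt_data_error(sprintf("%s: non-numeric or missing values", path))
  if (any(d$fvfm < 0 | d$fvfm > 1))
    tt_value_error("Fv/Fm values must lie within [0, 1]")
  if (length(unique(d$temperature)) < 2L)
    tt_value_error("at least 2 distinct target temperatures are required")
  new_viability_assay(d, control_fvfm = control_fvfm)
}

## writing -------------------------------------------------------------------

fmt_full <- function(x) sprintf("%.17g", x)

write_delim_full <- function(df, path, sep = "\t") {
  out <- df
  for (nm in names(out)) if (is.numeric(out[[nm]])) out[[nm]] <- fmt_full(out[[nm]])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write curves and tables back to delimited text
#'
#' `write_thermogram`, `write_f0_curve` and `write_viability_table` preserve
#' full numeric precision so that a read/write/read cycle reproduces the
#' object exactly. `write_aggregate_curve` writes a report-style table with
#' temperatures to 2 decimals and flows to 4 significant digits.
#'
#' @param x The object to write.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return The path, invisibly.
#' @name thermotol-writers
NULL

#' @rdname thermotol-writers
#' @export
write_thermogram <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "thermogram"))
  write_delim_full(x$data, path, sep)
}

#' @rdname thermotol-writers
#' @export
write_f0_curve <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "f0_curve"))
  write_delim_full(x$data, path, sep)
}

#' @rdname thermotol-writers
#' @export
write_viability_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "viability_assay"))
  write_delim_full(x$data, path, sep)
}

#' @rdname thermotol-writers
#' @export
write_aggregate_curve <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "aggregate_curve"))
  out <- data.frame(temperature = sprintf("%.2f", x$temperature),
                    mean = signif(x$mean, 4),
                    sd = ifelse(is.na(x$sd), "", as.character(signif(x$sd, 4))),
                    n = x$n)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
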