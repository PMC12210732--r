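# Shared fixtures: all test data is built in code.

# Write a delimited curve file and return its path.
write_fixture <- function(df, sep = ",", ext = if (sep == ",") "csv" else "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# A simple raw thermogram table on a coarse grid: linear decline, no features.
linear_thermo_df <- function(t_min = 25, t_max = 65, step = 0.5,
                             slope = -0.01, intercept = 0.5) {
  temp <- seq(t_min, t_max, by = step)
  data.frame(time = temp - t_min, temperature = temp,
             heat_flow = intercept + slope * (temp - t_min))
}

# Piecewise-linear normalized thermogram (no dip/peak), built in code.
# Used for the band-fit contract tests where T_endo is supplied explicitly.
piecewise_thermogram <- function(break_t = 45, slope1 = -0.5, slope2 = -3,
                                 t_min = 25, t_max = 65, step = 0.1) {
  temp <- seq(t_min, t_max, by = step)
  flow <- ifelse(temp <= break_t,
                 slope1 * (temp - t_min),
                 slope1 * (break_t - t_min) + slope2 * (temp - break_t))
  thermogram(time = temp - t_min, temperature = temp, heat_flow = flow,
             sample_id = "piecewise", fresh_mass = 20, normalized = TRUE)
}

# Independent brute-force oracle for the sliding-band searches: evaluate
# every candidate band with lm() and pick max R^2, ties to the lowest start.
oracle_band <- function(temp, y, width, lo, hi, step = 0.1) {
  starts <- seq(lo, hi - width + 1e-9, by = step)
  r2 <- vapply(starts, function(a) {
    sel <- temp >= a - 1e-9 & temp <= a + width + 1e-9
    fit <- stats::lm(y[sel] ~ temp[sel])
    s <- summary(fit)$r.squared
    if (is.nan(s)) { if (sum(stats::resid(fit)^2) < 1e-12) 1 else 0 } else s
  }, numeric(1))
  best <- which(r2 >= max(r2) - 1e-9)[1L]
  sel <- temp >= starts[best] - 1e-9 & temp <= starts[best] + width + 1e-9
  fit <- stats::lm(y[sel] ~ temp[sel])
  list(band = c(starts[best], starts[best] + width),
       slope = unname(stats::coef(fit)[2L]), r2 = r2[best])
}

# Independent centered moving mean (plain loop) matching a k-point window.
oracle_smooth <- function(y, k) {
  if (k <= 1L) return(y)
  half <- (k - 1L) %/% 2L
  sapply(seq_along(y), function(i)
    mean(y[max(1L, i - half):min(length(y), i + half)]))
}
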