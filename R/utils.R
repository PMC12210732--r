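#' @keywords internal
"_PACKAGE"

## condition helpers ---------------------------------------------------------

tt_stop <- function(msg, class, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "thermotol_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

tt_format_error     <- function(msg) tt_stop(msg, "tt_format_error")
tt_data_error       <- function(msg) tt_stop(msg, "tt_data_error")
tt_value_error      <- function(msg) tt_stop(msg, "tt_value_error")
tt_state_error      <- function(msg) tt_stop(msg, "tt_state_error")
tt_detection_error  <- function(msg) tt_stop(msg, "tt_detection_error")
tt_degeneracy_error <- function(msg) tt_stop(msg, "tt_degeneracy_error")
tt_fit_error        <- function(msg) tt_stop(msg, "tt_fit_error")
tt_domain_error     <- function(msg) tt_stop(msg, "tt_domain_error")
tt_bootstrap_error  <- function(msg) tt_stop(msg, "tt_bootstrap_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

## ordinary least squares on a vector pair -----------------------------------

# Plain OLS of y on x returning slope/intercept/R^2.  A perfectly flat,
# perfectly fitted segment (SS_tot ~ 0, SS_res ~ 0) gets R^2 = 1 so that
# noiseless plateaus are treated as perfect lines rather than NaN.
ols_line <- function(x, y) {
  n <- length(x)
  if (n < 3L) tt_value_error("need at least 3 points for a line fit")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - (intercept + slope * x)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - my)^2)
  eps <- max(1e-24, 1e-18 * max(ss_tot, 1))
  r2 <- if (ss_tot <= eps) {
    if (ss_res <= eps) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  list(slope = slope, intercept = intercept, r_squared = r2, n_points = n)
}

new_line_segment <- function(fit, band) {
  structure(
    list(slope = fit$slope, intercept = fit$intercept,
         band = as.numeric(band), r_squared = fit$r_squared,
         n_points = fit$n_points),
    class = "line_segment"
  )
}

#' @export
print.line_segment <- function(x, ...) {
  cat(sprintf("line segment on [%.2f, %.2f] degC: slope %.4g, intercept %.4g, R2 %.5f (n = %d)\n",
              x$band[1], x$band[2], x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

## sliding-band search -------------------------------------------------------

# Slide a fixed-width temperature band over (x, y) and fit OLS in every band.
# `select` picks the winner: maximal R^2, minimal |slope| or maximal slope.
# Ties (within tie_tol of the optimum) are broken toward the lowest band start
# for reproducibility; `t_high_tied` records the highest band top among the
# tied candidates, which the second-line search uses as its lower edge.
band_search <- function(x, y, width, lo, hi, step = 0.1,
                        select = c("max_r2", "min_abs_slope", "max_slope"),
                        tie_tol = 1e-9) {
  select <- match.arg(select)
  if (hi - lo < width - 1e-9)
    tt_value_error(sprintf(
      "band search needs a span of at least %.3g K but [%.3g, %.3g] provides %.3g K",
      width, lo, hi, hi - lo))
  starts <- seq(lo, hi - width + 1e-9, by = step)
  crit <- rep(NA_real_, length(starts))
  fits <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]
    sel <- x >= a - 1e-9 & x <= a + width + 1e-9
    if (sum(sel) < 3L) next
    f <- ols_line(x[sel], y[sel])
    fits[[i]] <- f
    crit[i] <- switch(select,
      max_r2        = f$r_squared,
      min_abs_slope = -abs(f$slope),
      max_slope     = f$slope)
  }
  if (all(is.na(crit))) tt_value_error("no candidate band contains 3 points")
  best <- max(crit, na.rm = TRUE)
  tied <- which(!is.na(crit) & crit >= best - tie_tol)
  win <- tied[1L]
  seg <- new_line_segment(fits[[win]], c(starts[win], starts[win] + width))
  # among ties, only bands that reproduce the winning line (colinear within
  # numerical tolerance) extend the equation's observed range
  colin <- tied[vapply(tied, function(i) {
    f <- fits[[i]]
    abs(f$slope - seg$slope) <= 1e-6 * max(1, abs(seg$slope)) &&
      abs(f$intercept - seg$intercept) <= 1e-6 * max(1, abs(seg$intercept))
  }, logical(1))]
  seg$t_high_tied <- max(starts[colin]) + width
  seg$criterion <- crit[win]
  seg
}

## peak detection ------------------------------------------------------------

# Local maxima of a 1-D signal with topographic prominence.  Plateaus are
# collapsed to their midpoint.  For each peak the bases are the minima between
# the peak and the nearest higher point on each side (whole side if none is
# higher); prominence = peak height - the higher of the two base values.
find_peaks <- function(y) {
  n <- length(y)
  peaks <- integer(0)
  if (n >= 3L) {
    i <- 2L
    while (i <= n - 1L) {
      if (y[i] > y[i - 1L]) {
        j <- i
        while (j < n && y[j + 1L] == y[j]) j <- j + 1L
        if (j < n && y[j + 1L] < y[j]) peaks <- c(peaks, as.integer(floor((i + j) / 2)))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (!length(peaks)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0),
                      left_base = integer(0), right_base = integer(0)))
  }
  prom <- numeric(length(peaks))
  lb <- integer(length(peaks)); rb <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; h <- y[p]
    il <- p - 1L
    while (il >= 1L && y[il] <= h) il <- il - 1L
    lseg <- (il + 1L):(p - 1L)
    lb[k] <- lseg[which.min(y[lseg])]
    ir <- p + 1L
    while (ir <= n && y[ir] <= h) ir <- ir + 1L
    rseg <- (p + 1L):(ir - 1L)
    rb[k] <- rseg[which.min(y[rseg])]
    prom[k] <- h - max(y[lb[k]], y[rb[k]])
  }
  data.frame(index = peaks, height = y[peaks], prominence = prom,
             left_base = lb, right_base = rb)
}

moving_mean <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(y[lo:hi])
  }
  out
}
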