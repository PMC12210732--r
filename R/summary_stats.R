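## summary_stats: pool per-leaf thresholds into species-level and overall
## summaries and compute cross-method correlations.

PARAMETER_NAMES <- c("T_c", "T_p", "T_pII", "T_init", "T_endo", "T_exo",
                     "LT_10", "LT_50")

#' Build a long parameter table
#'
#' @param sample_id,species,parameter,value Equal-length vectors; `parameter`
#'   must come from the closed set `T_c, T_p, T_pII, T_init, T_endo, T_exo,
#'   LT_10, LT_50` and each (sample, parameter) pair may appear once.
#' @return A data.frame of class `parameter_table`.
#' @export
parameter_table <- function(sample_id, species, parameter, value) {
  bad <- setdiff(unique(parameter), PARAMETER_NAMES)
  if (length(bad))
    tt_value_error(paste0("unknown parameter name(s): ", paste(bad, collapse = ", ")))
  d <- data.frame(sample_id = as.character(sample_id),
                  species = as.character(species),
                  parameter = as.character(parameter),
                  value = as.numeric(value), stringsAsFactors = FALSE)
  if (anyDuplicated(d[c("sample_id", "parameter")]))
    tt_value_error("duplicate (sample_id, parameter) rows")
  structure(d, class = c("parameter_table", "data.frame"))
}

#' Pool parameters into group summaries
#'
#' Per parameter (and species, when `by = "species"`): n, mean, sample
#' standard deviation (n - 1 denominator, absent for n = 1), median and the
#' 25/75 percentiles, mirroring how pooled boxplot summaries are reported.
#'
#' @param t A `parameter_table`.
#' @param by `"all"` pools every species together; `"species"` groups by
#'   species.
#' @return A data.frame with one row per (group, parameter).
#' @export
pool_parameters <- function(t, by = c("all", "species")) {
  by <- match.arg(by)
  if (!nrow(t)) tt_value_error("empty parameter table")
  t <- t[!is.na(t$value), , drop = FALSE]
  key <- if (by == "species") interaction(t$parameter, t$species, drop = TRUE)
         else t$parameter
  sp <- split(t, key)
  out <- do.call(rbind, lapply(sp, function(g) {
    q <- stats::quantile(g$value, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(parameter = g$parameter[1L],
               group = if (by == "species") g$species[1L] else "all",
               n = nrow(g), mean = mean(g$value),
               sd = if (nrow(g) >= 2L) stats::sd(g$value) else NA_real_,
               median = q[2L], q25 = q[1L], q75 = q[3L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$parameter, PARAMETER_NAMES), out$group), , drop = FALSE]
}

#' Cross-method parameter correlations
#'
#' Correlates parameters pairwise using only values measured on the same
#' sample (pairwise-complete). Pairs with fewer than 3 complete observations
#' get `NA` with the pair count still reported. Pearson is the default;
#' Spearman is offered because rank correlation is sometimes meant.
#'
#' @param t A `parameter_table`.
#' @param scope `"pooled"` uses all samples together; `"within_species"`
#'   returns one matrix per species.
#' @param method `"pearson"` or `"spearman"`.
#' @param informative Threshold on |r| flagged as informative in the output.
#' @return For `"pooled"`, a list of class `parameter_correlation` with
#'   matrices `r` and `n`, the `method`, and `informative` (logical matrix
#'   |r| > threshold). For `"within_species"`, a named list of such objects.
#' @export
correlate_parameters <- function(t, scope = c("pooled", "within_species"),
                                 method = c("pearson", "spearman"),
                                 informative = 0.5) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (scope == "within_species") {
    sp <- split(as.data.frame(t), t$species)
    return(lapply(sp, function(g)
      correlate_parameters(structure(g, class = c("parameter_table", "data.frame")),
                           scope = "pooled", method = method,
                           informative = informative)))
  }
  pars <- intersect(PARAMETER_NAMES, unique(t$parameter))
  wide <- stats::reshape(as.data.frame(t)[c("sample_id", "parameter", "value")],
                         idvar = "sample_id", timevar = "parameter",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  m <- as.matrix(wide[, pars, drop = FALSE])
  k <- length(pars)
  r <- matrix(NA_real_, k, k, dimnames = list(pars, pars))
  n <- matrix(0L, k, k, dimnames = list(pars, pars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(m[, c(i, j)])
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; next }
    if (n[i, j] >= 3L)
      r[i, j] <- stats::cor(m[ok, i], m[ok, j], method = method)
  }
  structure(list(r = r, n = n, method = method,
                 informative = abs(r) > informative),
            class = "parameter_correlation")
}

#' @export
print.parameter_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("parameter correlations (%s, pairwise-complete):\n", x$method))
  print(round(x$r, digits))
  invisible(x)
}
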