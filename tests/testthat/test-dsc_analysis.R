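# dsc_analysis: peak detection, sliding-band fits, intersection, vitality.

test_that("detect_exotherm finds an injected peak and ignores lines", {
  # Gaussian peak on a flat baseline: center recovered to the grid step
  temp <- seq(25, 65, by = 0.1)
  t <- thermogram(temp - 25, temp, 10 * exp(-(temp - 60.5)^2 / (2 * 0.8^2)),
                  fresh_mass = 20, normalized = TRUE)
  ex <- detect_exotherm(t, config = dsc_config(smooth_k = 0))
  expect_true(ex$present)
  expect_lte(abs(ex$t_exo - 60.5), 0.1)
  expect_lt(ex$onset, ex$t_exo)

  # strictly linear curve: absent, not an error
  lin <- thermogram(temp - 25, temp, -0.5 * (temp - 25), fresh_mass = 20,
                    normalized = TRUE)
  expect_false(detect_exotherm(lin)$present)

  # curve that ends below the search region
  short <- thermogram(0:40, seq(25, 45, by = 0.5), rnorm(41), fresh_mass = 20,
                      normalized = TRUE)
  expect_error(detect_exotherm(short), class = "tt_value_error")
})

test_that("detect_endotherm finds the dip and respects the exotherm onset", {
  g <- generate_thermogram(dsc_truth(noise_sd = 0))
  t <- normalize_heat_flow(g$thermogram)
  cfg <- dsc_config()
  ex <- detect_exotherm(t, config = cfg)
  en <- detect_endotherm(t, exo = ex, config = cfg)
  expect_lte(abs(en$t_endo - g$truth$t_endo_true), cfg$grid_step)

  # reheated-type linear curve: detection error
  rh <- generate_reheat_thermogram(reheat_truth(noise_sd = 0))$thermogram
  expect_error(detect_endotherm(normalize_heat_flow(rh)),
               class = "tt_detection_error")

  # overlapping dip and peak: endotherm stays at/below the exotherm onset,
  # matching a brute-force minimum search restricted to that region
  tr <- dsc_truth(endo_center = 59.3, endo_width = 0.5, exo_center = 60.5,
                  exo_width = 0.6, noise_sd = 0)
  tt <- normalize_heat_flow(generate_thermogram(tr)$thermogram)
  cfg0 <- dsc_config(smooth_k = 0)
  ex2 <- detect_exotherm(tt, config = cfg0)
  en2 <- detect_endotherm(tt, exo = ex2, config = cfg0)
  expect_lte(en2$t_endo, ex2$onset)
  tt_r <- resample_uniform(tt, 0.1)
  region <- tt_r$data$temperature >= 40 & tt_r$data$temperature <= ex2$onset
  brute <- tt_r$data$temperature[region][which.min(tt_r$data$heat_flow[region])]
  expect_equal(en2$t_endo, brute)
})

test_that("fit_first_line selects the best 10 K band with low-start ties", {
  cfg0 <- dsc_config(smooth_k = 0)  # no smoothing: probe pure band logic
  t <- piecewise_thermogram(break_t = 45)
  first <- fit_first_line(t, t_endo = 55, config = cfg0)
  expect_s3_class(first, "line_segment")
  expect_lte(first$band[2], 45)
  expect_gte(first$band[1], 29)
  expect_equal(first$r_squared, 1, tolerance = 1e-12)
  expect_equal(first$slope, -0.5, tolerance = 1e-9)
  # tie-break: lowest admissible start
  expect_equal(first$band, c(29, 39))
  # the highest tied band touches the breakpoint
  expect_equal(first$t_high_tied, 45)

  # perfectly linear whole curve: R^2 = 1 everywhere, band [29, 39]
  temp <- seq(25, 65, by = 0.1)
  lin <- thermogram(temp - 25, temp, 3 - 0.2 * temp, fresh_mass = 20,
                    normalized = TRUE)
  fl <- fit_first_line(lin, t_endo = 57, config = cfg0)
  expect_equal(fl$band, c(29, 39))

  # insufficient range below T_endo
  expect_error(fit_first_line(t, t_endo = 37), class = "tt_value_error")
})

test_that("fit_second_line searches above the first band, below T_endo", {
  cfg0 <- dsc_config(smooth_k = 0)
  t <- piecewise_thermogram(break_t = 45)
  first <- fit_first_line(t, t_endo = 55, config = cfg0)
  second <- fit_second_line(t, first, t_endo = 55, config = cfg0)
  expect_gte(second$band[1], 45)
  expect_lte(second$band[2], 55)
  expect_equal(second$slope, -3, tolerance = 1e-9)
  expect_equal(second$r_squared, 1, tolerance = 1e-12)

  # no admissible band when T_endo sits 1 K above the first line's top
  expect_error(fit_second_line(t, first, t_endo = 46, config = cfg0),
               class = "tt_detection_error")

  # reproducible on a fixed noisy input
  g <- generate_thermogram(dsc_truth(seed = 99))
  tn <- resample_uniform(normalize_heat_flow(g$thermogram), 0.1)
  en <- detect_endotherm(tn, exo = detect_exotherm(tn))
  f1a <- fit_first_line(tn, en$t_endo); f1b <- fit_first_line(tn, en$t_endo)
  s1a <- fit_second_line(tn, f1a, en$t_endo)
  s1b <- fit_second_line(tn, f1b, en$t_endo)
  expect_identical(s1a, s1b)
})

test_that("band selection equals the exhaustive brute-force oracle", {
  cfg <- dsc_config()
  for (seed in c(3, 17, 29)) {
    g <- generate_thermogram(dsc_truth(seed = seed))
    t <- resample_uniform(normalize_heat_flow(g$thermogram), cfg$grid_step)
    en <- detect_endotherm(t, exo = detect_exotherm(t, config = cfg), config = cfg)
    ys <- oracle_smooth(t$data$heat_flow, cfg$smooth_k)

    first <- fit_first_line(t, en$t_endo, config = cfg)
    ob <- oracle_band(t$data$temperature, ys, width = 10, lo = 29, hi = en$t_endo)
    expect_equal(first$band, ob$band)
    expect_equal(first$slope, ob$slope, tolerance = 1e-8)

    second <- fit_second_line(t, first, en$t_endo, config = cfg)
    ob2 <- oracle_band(t$data$temperature, ys, width = 3,
                       lo = first$t_high_tied, hi = en$t_endo)
    expect_equal(second$band, ob2$band)
    expect_equal(second$slope, ob2$slope, tolerance = 1e-8)
  }
})

test_that("intersect_lines computes the crossing and flags degeneracy", {
  l1 <- list(slope = 1, intercept = 0)
  l2 <- list(slope = -1, intercept = 2)
  expect_equal(intersect_lines(l1, l2), 1.0)
  expect_error(intersect_lines(l1, list(slope = 1, intercept = 5)),
               class = "tt_degeneracy_error")

  # lines fitted to a two-segment curve intersect at the breakpoint
  cfg0 <- dsc_config(smooth_k = 0)
  t <- piecewise_thermogram(break_t = 45)
  first <- fit_first_line(t, t_endo = 55, config = cfg0)
  second <- fit_second_line(t, first, t_endo = 55, config = cfg0)
  expect_lte(abs(intersect_lines(first, second) - 45), 0.2)
})

test_that("analyze_thermogram orders thresholds and reports failures", {
  g <- generate_thermogram(dsc_truth(noise_sd = 0))
  res <- analyze_thermogram(g$thermogram)
  expect_identical(res$vitality, "vital")
  expect_true(res$t_init < res$t_endo && res$t_endo < res$t_exo)

  rh <- generate_reheat_thermogram(reheat_truth(seed = 2))
  res_rh <- analyze_thermogram(rh$thermogram)
  expect_identical(res_rh$vitality, "heat_killed")
  expect_true(is.na(res_rh$t_endo))
  expect_true(is.na(res_rh$t_init))
  expect_gt(length(res_rh$diagnostics), 0)

  df <- as.data.frame(res)
  expect_identical(nrow(df), 1L)
  expect_true(all(c("t_init", "t_endo", "t_exo", "vitality") %in% names(df)))
})

test_that("thresholds are invariant to fresh mass and flow offsets", {
  g <- generate_thermogram(dsc_truth(seed = 12))
  t1 <- g$thermogram
  res1 <- analyze_thermogram(t1)
  # doubling the mass of the same raw curve changes nothing after normalization
  t2 <- t1
  t2$data$heat_flow <- t2$data$heat_flow * 2
  t2$fresh_mass <- t2$fresh_mass * 2
  res2 <- analyze_thermogram(t2)
  expect_equal(res2$t_init, res1$t_init)
  expect_equal(res2$t_endo, res1$t_endo)
  expect_equal(res2$t_exo, res1$t_exo)

  # constant offset: all temperatures unchanged
  t3 <- normalize_heat_flow(t1)
  t3$data$heat_flow <- t3$data$heat_flow + 11
  res3 <- analyze_thermogram(t3)
  expect_equal(res3$t_endo, res1$t_endo)
  expect_equal(res3$t_exo, res1$t_exo)
  expect_equal(res3$t_init, res1$t_init, tolerance = 1e-8)
  expect_equal(res3$first_line$band, res1$first_line$band)
  expect_equal(res3$second_line$band, res1$second_line$band)
})

test_that("noiseless recovery respects the stated grid tolerances", {
  for (i in 1:5) {
    tr <- dsc_truth(noise_sd = 0, breakpoint = 50 + 0.5 * i,
                    endo_center = 56 + 0.3 * i, exo_center = 59.7 + 0.2 * i)
    res <- analyze_thermogram(generate_thermogram(tr)$thermogram)
    expect_lte(abs(res$t_endo - tr$t_endo_true), 0.1)
    expect_lte(abs(res$t_exo - tr$t_exo_true), 0.1)
    expect_lte(abs(res$t_init - tr$breakpoint), 0.2)
  }
})

test_that("classify_vitality separates vital, heat-killed and borderline", {
  expect_identical(
    classify_vitality(generate_thermogram(dsc_truth(noise_sd = 0))$thermogram),
    "vital")
  expect_identical(
    classify_vitality(generate_reheat_thermogram(reheat_truth(noise_sd = 0))$thermogram),
    "heat_killed")
  # a clear exotherm but a dip far below the prominence threshold: neither
  # vital (one feature missing) nor heat-killed (the peak breaks linearity)
  tr <- dsc_truth(endo_depth = 0.3, noise_sd = 0)
  expect_identical(classify_vitality(generate_thermogram(tr)$thermogram),
                   "indeterminate")
})
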