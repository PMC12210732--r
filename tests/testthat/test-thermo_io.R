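# thermo_io: reading, validation, normalization, resampling, aggregation.

test_that("read_thermogram validates and passes data through", {
  df <- linear_thermo_df()
  path <- write_fixture(df)
  t <- read_thermogram(path, fresh_mass = 20, sample_id = "s1")
  expect_s3_class(t, "thermogram")
  expect_equal(t$data$temperature, df$temperature)
  expect_equal(t$data$heat_flow, df$heat_flow)
  expect_false(t$normalized)
  expect_identical(t$run_kind, "initial")

  # trimming to the protocol window
  wide <- rbind(data.frame(time = -5, temperature = 20, heat_flow = 1),
                df,
                data.frame(time = 99, temperature = 70, heat_flow = -1))
  t2 <- read_thermogram(write_fixture(wide), fresh_mass = 20)
  expect_equal(range(t2$data$temperature), c(25, 65))

  # endo-up convention flips the sign
  t3 <- read_thermogram(path, fresh_mass = 20, endo_up = TRUE)
  expect_equal(t3$data$heat_flow, -df$heat_flow)

  # tab separation is auto-detected
  t4 <- read_thermogram(write_fixture(df, sep = "\t"), fresh_mass = 20)
  expect_equal(t4$data, t$data)
})

test_that("read_thermogram rejects bad files and masses", {
  df <- linear_thermo_df()
  expect_error(read_thermogram(write_fixture(df[c("time", "temperature")]),
                               fresh_mass = 20),
               class = "tt_format_error")
  dec <- df
  dec$temperature[40:45] <- rev(dec$temperature[40:45])  # decreasing mid-run
  expect_error(read_thermogram(write_fixture(dec), fresh_mass = 20),
               class = "tt_data_error")
  expect_error(read_thermogram(write_fixture(df), fresh_mass = -1),
               class = "tt_value_error")
  # masses outside the observed working range warn but succeed
  expect_warning(t <- read_thermogram(write_fixture(df), fresh_mass = 5),
                 "outside the usual working range")
  expect_s3_class(t, "thermogram")
  expect_warning(read_thermogram(write_fixture(df), fresh_mass = 40),
                 "outside the usual working range")
})

test_that("normalize_heat_flow divides by mass in grams, once", {
  t1 <- thermogram(0:2, c(30, 31, 32), c(2, 2, 2), fresh_mass = 1000)
  expect_equal(normalize_heat_flow(t1)$data$heat_flow, c(2, 2, 2))
  t2 <- thermogram(0:2, c(30, 31, 32), c(2, 2, 2), fresh_mass = 20)
  n2 <- normalize_heat_flow(t2)
  expect_equal(n2$data$heat_flow, c(100, 100, 100))
  expect_true(n2$normalized)
  expect_error(normalize_heat_flow(n2), class = "tt_state_error")
})

test_that("normalization is linear in 1/mass", {
  df <- linear_thermo_df()
  for (c_scale in c(0.5, 2, 7.3)) {
    a <- normalize_heat_flow(thermogram(df$time, df$temperature, df$heat_flow,
                                        fresh_mass = 20))
    b <- normalize_heat_flow(thermogram(df$time, df$temperature, df$heat_flow,
                                        fresh_mass = 20 * c_scale))
    expect_equal(b$data$heat_flow, a$data$heat_flow / c_scale)
  }
})

test_that("resample_uniform interpolates linearly onto the grid", {
  t <- thermogram(c(0, 0.2), c(25.0, 25.2), c(0, 2), fresh_mass = 1000,
                  normalized = TRUE)
  # grid from ceiling(25)=25; span 0.2 K, step 0.1 -> one midpoint
  r <- resample_uniform(t, step = 0.1)
  expect_equal(r$data$heat_flow[r$data$temperature == 25.1], 1)

  # identity on an already-uniform grid
  temp <- seq(25, 65, by = 0.1)
  t2 <- thermogram(temp - 25, temp, sin(temp / 3), fresh_mass = 20,
                   normalized = TRUE)
  r2 <- resample_uniform(t2, step = 0.1)
  expect_equal(r2$data$heat_flow, sin(temp / 3), tolerance = 1e-12)

  # values at coinciding grid points are preserved even on irregular input
  irr_t <- sort(c(seq(25, 65, by = 0.25), 40.05))
  t3 <- thermogram(irr_t - 25, irr_t, irr_t^2, fresh_mass = 20,
                   normalized = TRUE)
  r3 <- resample_uniform(t3, step = 0.25)
  shared <- intersect(r3$data$temperature, irr_t)
  expect_gt(length(shared), 100)
  expect_equal(r3$data$heat_flow[match(shared, r3$data$temperature)],
               shared^2, tolerance = 1e-12)

  expect_error(resample_uniform(t2, step = 50), class = "tt_value_error")
  raw <- thermogram(0:2, c(30, 31, 32), 1:3, fresh_mass = 20)
  expect_error(resample_uniform(raw, 0.1), class = "tt_state_error")
})

test_that("aggregate_curves pools per rounded-temperature bin", {
  temp <- seq(30, 40, by = 0.1)
  mk <- function(level) thermogram(temp - 25, temp, rep(level, length(temp)),
                                   fresh_mass = 20, normalized = TRUE)
  one <- aggregate_curves(list(mk(1)))
  expect_equal(one$mean, rep(1, nrow(one)))
  expect_true(all(is.na(one$sd)))
  expect_true(all(one$n == 1))

  two <- aggregate_curves(list(mk(1), mk(3)))
  expect_equal(two$mean, rep(2, nrow(two)))
  expect_equal(two$sd, rep(sd(c(1, 3)), nrow(two)))  # sqrt(2)

  # k identical curves: sd exactly 0, mean equal to the curve
  tg <- generate_thermogram(dsc_truth(noise_sd = 0))$thermogram
  tg <- normalize_heat_flow(tg)
  many <- aggregate_curves(list(tg, tg, tg))
  expect_equal(many$sd, rep(0, nrow(many)))
  expect_equal(many$mean, tapply(tg$data$heat_flow, round(tg$data$temperature, 1), mean),
               ignore_attr = TRUE)

  # disjoint ranges: union of bins with n = 1 in the non-overlap
  lo <- thermogram(0:10, seq(30, 35, by = 0.5), rep(1, 11), fresh_mass = 20,
                   normalized = TRUE)
  hi <- thermogram(0:10, seq(40, 45, by = 0.5), rep(3, 11), fresh_mass = 20,
                   normalized = TRUE)
  dis <- aggregate_curves(list(lo, hi))
  expect_true(all(dis$n == 1))
  expect_equal(sort(unique(dis$mean)), c(1, 3))

  expect_error(aggregate_curves(list()), class = "tt_value_error")
})

test_that("read/write/read round-trips are exact for all three table types", {
  g <- generate_thermogram(dsc_truth(seed = 42))
  t1 <- g$thermogram
  p1 <- tempfile(fileext = ".tsv"); write_thermogram(t1, p1)
  t2 <- read_thermogram(p1, fresh_mass = t1$fresh_mass, sample_id = t1$sample_id,
                        species = t1$species)
  expect_identical(t2$data$heat_flow, t1$data$heat_flow)
  expect_identical(t2$data$temperature, t1$data$temperature)
  p1b <- tempfile(fileext = ".tsv"); write_thermogram(t2, p1b)
  expect_identical(readLines(p1), readLines(p1b))

  f <- generate_f0_curve(f0_truth(seed = 42))$curve
  p2 <- tempfile(fileext = ".tsv"); write_f0_curve(f, p2)
  f2 <- read_f0_curve(p2, sample_id = f$sample_id)
  expect_identical(f2$data, f$data)

  a <- generate_viability_assay(assay_truth(seed = 42))$assay
  p3 <- tempfile(fileext = ".tsv"); write_viability_table(a, p3)
  a2 <- read_viability_table(p3)
  expect_identical(a2$data, a$data)
})

test_that("F0 and viability readers validate their contracts", {
  fdf <- data.frame(temperature = seq(25, 65, by = 0.5), f0 = 100)
  f <- read_f0_curve(write_fixture(fdf))
  expect_s3_class(f, "f0_curve")

  vdf <- expand.grid(temperature = seq(38, 56, by = 2), replicate = paste0("r", 1:3))
  vdf$fvfm <- 0.5
  v <- read_viability_table(write_fixture(vdf))
  expect_s3_class(v, "viability_assay")
  expect_length(unique(v$data$temperature), 10)  # ten 2-K-spaced targets accepted

  bad <- vdf; bad$fvfm[1] <- 1.3
  expect_error(read_viability_table(write_fixture(bad)), class = "tt_value_error")
  neg <- fdf; neg$f0[3] <- -1
  expect_error(read_f0_curve(write_fixture(neg)), class = "tt_value_error")
})

test_that("the two-run heating protocol lasts 160 minutes", {
  p <- dsc_protocol(t_min = 25, t_max = 65, rate = 1, runs = 2)
  expect_equal(p$heat_min, 40)
  expect_equal(p$total_min, 160)
  expect_error(dsc_protocol(rate = 0), class = "tt_value_error")
})
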