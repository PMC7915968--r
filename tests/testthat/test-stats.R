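test_that("coefficient of variation matches hand calculations", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), 100 * sqrt(2) / 3)
  expect_equal(round(coefficient_of_variation(c(2, 4)), 2), 47.14)
  expect_equal(round(coefficient_of_variation(c(98, 100)), 4), 1.4285)
  expect_error(coefficient_of_variation(7), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("CV is invariant under positive scaling", {
  set.seed(21)
  for (i in 1:10) {
    x <- runif(20, 1, 10)
    a <- runif(1, 0.1, 100)
    expect_equal(coefficient_of_variation(a * x), coefficient_of_variation(x),
                 tolerance = 1e-10)
  }
})

test_that("spatial CV recovers an injected trap-to-trap volume spread", {
  # 150 traps with 4.2% multiplicative volume noise; average CV over seeds
  est <- vapply(1:100, function(s) {
    set.seed(s)
    vol <- 83.47 * (1 + rnorm(150, 0, 0.042))
    tab <- data.frame(frame = 1L, trap_id = 1:150, optical_volume_um3 = vol,
                      occupied = FALSE)
    spatial_cv(tab)
  }, numeric(1))
  expect_lt(abs(mean(est) - 4.2), 0.5)
})

test_that("temporal CV is the CV of per-frame mean empty-trap volume", {
  tab <- data.frame(frame = rep(1:2, each = 2), trap_id = rep(1:2, 2),
                    optical_volume_um3 = c(97, 99, 99, 101),
                    occupied = FALSE)
  expect_equal(temporal_cv(tab), coefficient_of_variation(c(98, 100)))
  pt <- temporal_cv_per_trap(tab)
  expect_equal(pt$cv_pct,
               c(coefficient_of_variation(c(97, 99)),
                 coefficient_of_variation(c(99, 101))))
})

test_that("boxplot summary uses interpolated quartiles and 1.5 IQR fences", {
  b <- boxplot_summary(1:9)
  expect_equal(b$median, 5); expect_equal(b$q1, 3); expect_equal(b$q3, 7)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 9)
  b2 <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(b2$q1, 2); expect_equal(b2$q3, 4)
  expect_equal(b2$outliers, 100)
  expect_equal(b2$whisker_high, 4)
  b3 <- boxplot_summary(rep(3.3, 6))
  expect_length(b3$outliers, 0)
  expect_error(boxplot_summary(1:4), "at least 5")
})

test_that("boxplot outlier partition matches brute-force enumeration", {
  set.seed(31)
  for (i in 1:20) {
    x <- c(rnorm(sample(5:40, 1)), sample(c(-50, 50), sample(0:2, 1),
                                          replace = TRUE))
    b <- boxplot_summary(x)
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    brute_out <- x[x < fence[1] | x > fence[2]]
    expect_equal(sort(b$outliers), sort(brute_out))
    # whisker-bounded points plus outliers partition the data
    inside <- x[x >= b$whisker_low & x <= b$whisker_high]
    expect_equal(sort(c(inside, b$outliers)), sort(x))
  }
})

test_that("normalization divides by initial mass and averages across cells", {
  t <- seq(0, 2, by = 0.25)
  f <- exp(0.3 * t)
  one <- data.frame(trap_id = 1L, time_h = t, mass_pg = 5 * f)
  avg1 <- normalize_and_average(one)
  expect_equal(avg1$mean_normalized_mass, f / f[1])
  expect_equal(avg1$mean_normalized_mass[1], 1)
  # scale invariance: tracks c*f(t) all collapse to f(t)/f(0)
  set.seed(41)
  many <- do.call(rbind, lapply(1:6, function(k)
    data.frame(trap_id = k, time_h = t, mass_pg = runif(1, 1, 100) * f)))
  avg <- normalize_and_average(many)
  expect_equal(avg$mean_normalized_mass, f / f[1], tolerance = 1e-12)
  expect_equal(avg$n_cells[1], 6L)
})

test_that("growth fit is exact on noiseless exponentials", {
  t <- seq(0, 18, by = 5 / 60)  # 5-min sampling over 18 h
  for (rate in c(-0.1, -0.02, 0.021, 0.08)) {
    fit <- fit_growth_rate(t, exp(rate * t))
    expect_equal(fit$rate, rate, tolerance = 1e-9)
  }
  fit <- fit_growth_rate(t, exp(0.021 * t))
  expect_equal(fit$doubling_time, log(2) / 0.021, tolerance = 1e-6)
  # constant mass: zero rate, undefined doubling time
  fit0 <- fit_growth_rate(t, rep(7, length(t)))
  expect_equal(fit0$rate, 0)
  expect_true(is.na(fit0$doubling_time))
  expect_error(fit_growth_rate(t[1:5], exp(t[1:5])), "at least 10")
  expect_error(fit_growth_rate(t, c(-1, exp(t[-1]))), "positive")
})

test_that("growth fit recovers the rate under 1% measurement noise", {
  t <- seq(0, 18, by = 5 / 60)  # 217 points
  rates <- vapply(1:50, function(s) {
    set.seed(s)
    m <- exp(0.021 * t) * exp(rnorm(length(t), 0, 0.01))
    fit_growth_rate(t, m)$rate
  }, numeric(1))
  expect_true(mean(abs(rates - 0.021) <= 0.002) >= 0.95)
})

test_that("mass tracks are extracted for traps occupied in every frame", {
  tab <- rbind(
    data.frame(frame = 1L, trap_id = 1:3,
               optical_volume_um3 = c(83, 120, 130),
               occupied = c(FALSE, TRUE, TRUE),
               cell_optical_volume_um3 = c(NA, 37, 47),
               cell_mass_pg = c(NA, 37, 47) / 0.18),
    data.frame(frame = 2L, trap_id = 1:3,
               optical_volume_um3 = c(83, 121, 83),
               occupied = c(FALSE, TRUE, FALSE),
               cell_optical_volume_um3 = c(NA, 38, NA),
               cell_mass_pg = c(NA, 38, NA) / 0.18))
  tr <- extract_mass_tracks(tab, dt_min = 5)
  expect_equal(unique(tr$trap_id), 2L)  # trap 3 lost its cell
  expect_equal(tr$time_h, c(0, 5 / 60))
  expect_equal(tr$mass_pg, c(37, 38) / 0.18)
})
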