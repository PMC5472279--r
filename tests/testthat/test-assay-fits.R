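test_that("delta-F ratio algebra", {
  expect_equal(delta_f(1.5, 1.5), 0)
  expect_equal(delta_f(3, 1.5), 100)
  expect_error(delta_f(1, 0), "positive")
  # invariant to common rescaling of both fluorescence channels
  a665 <- c(120, 240); a615 <- c(100, 100)
  r <- a665 / a615
  expect_equal(delta_f(r[2], r[1]), delta_f(5 * a665[2] / (5 * a615[2]),
                                            5 * a665[1] / (5 * a615[1])))
  expect_equal(normalize_competition(c(80, 40, 0), 80), c(1, 0.5, 0))
  expect_equal(normalize_competition(2 * c(80, 40), 80),
               2 * normalize_competition(c(80, 40), 80))
  expect_error(normalize_competition(1, 0), "positive")
})

test_that("4PL fitting recovers noise-free generating parameters", {
  gt <- curve_ground_truth("4PL", list(top = 1, bottom = 0,
                                       logIC50 = log10(8.4e-6), hill = 1))
  d <- gen_curve(gt, seq(-8.5, -2.5, length.out = 12))
  f <- fit_4pl(d$x, d$y, seed = 1)
  expect_lt(abs(f$ic50 - 8.4e-6) / 8.4e-6, 1e-3)
  expect_equal(f$hill, 1, tolerance = 1e-4)
  expect_gt(f$r_squared, 0.99)
  expect_true(f$significant)
  # dose-shift equivariance: x + delta shifts logIC50 by delta
  f2 <- fit_4pl(d$x + 1.25, d$y, seed = 1)
  expect_equal(f2$logIC50 - f$logIC50, 1.25, tolerance = 1e-6)
  expect_error(fit_4pl(c(-6, -5, -4, -6), c(1, .5, 0, 1), seed = 1),
               "5 distinct")
})

test_that("flat responses are reported non-significant, not errors", {
  f <- fit_4pl(seq(-8, -3, 1), rep(0.8, 6), seed = 1)
  expect_false(f$significant)
  expect_equal(f$r_squared, 0)
})

test_that("4PL recovery error shrinks with the noise level", {
  x <- seq(-8.5, -2.5, length.out = 12)
  err_at <- function(sd) {
    errs <- vapply(1:12, function(s) {
      gt <- curve_ground_truth("4PL",
                               list(top = 1, bottom = 0,
                                    logIC50 = -5.076, hill = 1),
                               noise_sd = sd, noise_type = "multiplicative",
                               seed = 900 + s)
      d <- gen_curve(gt, x)
      f <- fit_4pl(d$x, d$y, seed = s)
      abs(f$ic50 - 10^-5.076) / 10^-5.076
    }, numeric(1))
    median(errs)
  }
  errs <- vapply(c(0.005, 0.02, 0.10), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[2], 0.15)       # 2% multiplicative noise: median within 15%
})

test_that("Boltzmann melt fitting: exact recovery, shifts, truncation", {
  gt <- curve_ground_truth("boltzmann", list(f_min = 100, f_max = 900,
                                             tm_c = 55, slope_a = 2.2))
  tt <- seq(20, 90, 0.5)
  d <- gen_curve(gt, tt)
  f <- fit_boltzmann(d$x, d$y)
  expect_equal(f$tm_c, 55, tolerance = 1e-6)
  # post-peak dye-dissociation decay must not bias the fit
  decay <- d
  sel <- decay$x > 75
  decay$y[sel] <- decay$y[sel] - seq(0, 400, length.out = sum(sel))
  fd <- fit_boltzmann(decay$x, decay$y)
  expect_equal(fd$tm_c, 55, tolerance = 1e-3)
  # destabilised sample: -3 C shift read out against the control
  gt2 <- curve_ground_truth("boltzmann", list(f_min = 100, f_max = 900,
                                              tm_c = 52, slope_a = 2.2))
  d2 <- gen_curve(gt2, tt)
  f2 <- fit_boltzmann(d2$x, d2$y, reference_tm_c = f$tm_c)
  expect_equal(f2$delta_tm_c, -3, tolerance = 1e-6)
  expect_error(fit_boltzmann(tt, 1000 - 5 * tt), "transition")
})

test_that("noisy Tm extraction stays within 0.3 C in >= 90% of runs", {
  tt <- seq(20, 90, 0.5)
  ok <- vapply(1:50, function(s) {
    gt <- curve_ground_truth("boltzmann",
                             list(f_min = 100, f_max = 900, tm_c = 55,
                                  slope_a = 2.2),
                             noise_sd = 0.01 * 800, seed = 700 + s)
    d <- gen_curve(gt, tt)
    f <- fit_boltzmann(d$x, d$y)
    abs(f$tm_c - 55) <= 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("one-site ITC fitting recovers noise-free isotherms within 1%", {
  truth <- list(n_sites = 1, K_A = 1 / 3.7e-6, delta_H = -40,
                cell_conc = 5e-5)
  gt <- curve_ground_truth("wiseman_one_site", truth)
  xr <- seq(0.08, 2.5, length.out = 17)
  d <- gen_curve(gt, xr)
  f <- fit_itc_one_site(d$x, d$y, cell_conc = 5e-5, seed = 2)
  expect_lt(abs(f$n_sites - 1), 0.01)
  expect_lt(abs(f$K_A - truth$K_A) / truth$K_A, 0.01)
  expect_lt(abs(f$delta_H - (-40)) / 40, 0.01)
  expect_false(f$low_confidence)
  # thermodynamic identity enforced on the returned object
  expect_lt(abs(f$delta_H - f$T_delta_S - f$delta_G), 1e-12)
  expect_equal(f$K_d, 1 / f$K_A)
  expect_error(fit_itc_one_site(xr, rep(0, 17), 5e-5, seed = 1), "zero")
})

test_that("weak-binding fits carry the low-confidence c-value flag", {
  truth <- list(n_sites = 1, K_A = 1e4, delta_H = -30, cell_conc = 5e-5)
  gt <- curve_ground_truth("wiseman_one_site", truth)
  d <- gen_curve(gt, seq(0.08, 4, length.out = 20))
  f <- fit_itc_one_site(d$x, d$y, cell_conc = 5e-5, seed = 3)
  expect_true(f$c_value < 1)
  expect_true(f$low_confidence)
})

test_that("thermodynamic derivations follow the Gibbs relations", {
  expect_equal(derive_thermo(1, -10, 298.15)$delta_G, 0)
  th <- derive_thermo(1 / 4.9e-6, -40, 298.15)
  expect_equal(th$delta_G, -8.314 * 298.15 * log(1 / 4.9e-6) / 1000)
  expect_equal(th$delta_G, -30.3, tolerance = 0.002)   # kJ/mol
  same <- derive_thermo(exp(-(-20 * 1000) / (8.314 * 298.15)), -20, 298.15)
  expect_equal(same$T_delta_S, 0, tolerance = 1e-9)
  expect_error(derive_thermo(-1, 0, 298.15))
})

test_that("assay parameter recovery improves as noise vanishes", {
  # Boltzmann and ITC noisy-vs-clean ordering (4PL covered above)
  tt <- seq(20, 90, 0.5)
  tm_err <- vapply(c(0, 8, 40), function(sd) {
    gt <- curve_ground_truth("boltzmann",
                             list(f_min = 100, f_max = 900, tm_c = 55,
                                  slope_a = 2.2), noise_sd = sd, seed = 55)
    d <- gen_curve(gt, tt)
    abs(fit_boltzmann(d$x, d$y)$tm_c - 55)
  }, numeric(1))
  expect_true(all(diff(tm_err) > 0))
})
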