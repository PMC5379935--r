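test_that("polarization arithmetic and edge cases", {
  expect_equal(polarization(100, 100)$P, 0)
  expect_equal(polarization(100, 0)$mP, 1000)
  p <- polarization(150, 100)
  expect_equal(p$P, 0.2)
  expect_equal(p$mP, 200)
  expect_error(polarization(0, 0), "zero total")
  expect_error(polarization(-1, 2), "non-negative")
})

test_that("the logistic sigmoid has the stated midpoint, plateaus and slope", {
  p <- list(A1 = 40, A2 = 260, x0 = -7.5, dx = 0.3)
  expect_equal(eval_logistic4(p$x0, p), (p$A1 + p$A2) / 2, tolerance = 1e-12)
  expect_lt(abs(eval_logistic4(p$x0 - 10 * p$dx, p) - p$A1),
            1e-3 * abs(p$A2 - p$A1))
  expect_lt(abs(eval_logistic4(p$x0 + 10 * p$dx, p) - p$A2),
            1e-3 * abs(p$A2 - p$A1))
  slope <- function(dx) {
    q <- utils::modifyList(p, list(dx = dx))
    h <- 1e-6
    (eval_logistic4(p$x0 + h, q) - eval_logistic4(p$x0 - h, q)) / (2 * h)
  }
  expect_equal(slope(0.15), 2 * slope(0.3), tolerance = 1e-4)
  expect_error(eval_logistic4(0, list(A1 = 1, A2 = 2, x0 = 0, dx = 0)), "dx")
})

test_that("the depletion isotherm matches its closed form and limits", {
  # Kd = L = T = 1 (arbitrary unit): f = (3 - sqrt(5)) / 2
  p <- list(A1 = 0, A2 = 1, Kd = 1, probe_total = 1)
  expect_equal(eval_depletion(1, p), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # stoichiometric and dilute limits
  tight <- list(A1 = 10, A2 = 200, Kd = 1e-15, probe_total = 5e-9)
  expect_equal(eval_depletion(1e-8, tight), 200, tolerance = 1e-3)
  expect_equal(eval_depletion(0, p), 0, tolerance = 1e-12)
  # monotone in titrant, decreasing in Kd
  grid <- 10^seq(-10, -5, length.out = 40)
  d1 <- eval_depletion(grid, list(A1 = 0, A2 = 1, Kd = 1e-8,
                                  probe_total = 5e-9))
  expect_true(all(diff(d1) > 0))
  d2 <- eval_depletion(grid, list(A1 = 0, A2 = 1, Kd = 3e-8,
                                  probe_total = 5e-9))
  expect_true(all(d2 < d1))
})

test_that("the depletion curve converges to a Hill-1 logistic when probe << Kd", {
  Kd <- 1e-6; L <- 1e-9  # ratio 1e-3
  grid <- 10^seq(log10(Kd) - 3, log10(Kd) + 3, length.out = 61)
  dep <- eval_depletion(grid, list(A1 = 0, A2 = 100, Kd = Kd,
                                   probe_total = L))
  hill1 <- eval_logistic4(log10(grid), list(A1 = 0, A2 = 100,
                                            x0 = log10(Kd), dx = 1 / log(10)))
  expect_lt(max(abs(dep - hill1)), 1)  # < 1% of the 100-unit range
})

test_that("noiseless self-fits recover generating parameters", {
  pl <- list(A1 = 50, A2 = 250, x0 = log10(21.3e-9), dx = 1 / (1.3 * log(10)))
  d <- simulate_fp("logistic4", pl, noise_sd_mP = 0)
  fit <- fit_model(d, "logistic4")
  for (nm in names(pl))
    expect_lt(abs(fit$params[[nm]] - pl[[nm]]) / abs(pl[[nm]]), 1e-6)
  expect_equal(fit$kd, 21.3e-9, tolerance = 1e-6)
  expect_true(fit$converged)

  pd <- list(A1 = 50, A2 = 250, Kd = 10e-9)
  dd <- simulate_fp("depletion", pd, noise_sd_mP = 0, probe_total = 5e-9)
  fd <- fit_model(dd, "depletion")
  expect_lt(abs(fd$kd - 10e-9) / 10e-9, 1e-4)
})

test_that("ignoring depletion inflates the apparent Kd by probe/2", {
  pd <- list(A1 = 50, A2 = 250, Kd = 10e-9)
  dd <- simulate_fp("depletion", pd, noise_sd_mP = 0, probe_total = 5e-9)
  fl <- fit_model(dd, "logistic4")
  offset <- fl$kd - 10e-9
  expect_lt(abs(offset - 2.5e-9) / 2.5e-9, 0.1)
})

test_that("fits flag thin data and unbracketed transitions", {
  few <- data.frame(conc_M = 10^seq(-9, -8, length.out = 4), mP = 1:4)
  expect_error(fit_model(few, "logistic4"), "at least 6")
  d <- simulate_fp("depletion", noise_sd_mP = 0)
  expect_error(fit_model(d, "depletion", probe_total = NULL),
               NA)  # attribute supplies the probe
  d2 <- d; attributes(d2)$probe_total <- NULL
  expect_error(fit_model(as.data.frame(d2)[, c("conc_M", "mP")], "depletion"),
               "probe_total")
})

test_that("replicate-mean fitting matches replicate-level fitting on noiseless data", {
  d <- simulate_fp("logistic4", noise_sd_mP = 0, n_reps = 3)
  f_raw <- fit_model(d, "logistic4")
  f_avg <- fit_model(d, "logistic4", average_replicates = TRUE)
  expect_equal(f_avg$kd, f_raw$kd, tolerance = 1e-8)
  expect_equal(f_avg$n_points, 18)
  expect_equal(f_raw$n_points, 54)
})

test_that("model comparison reports offsets, percent difference and n_H", {
  dd <- simulate_fp("depletion", list(A1 = 50, A2 = 250, Kd = 5e-9),
                    noise_sd_mP = 0, probe_total = 5e-9)
  fl <- fit_model(dd, "logistic4")
  fd <- fit_model(dd, "depletion")
  cmp <- compare_fits(fl, fd)
  expect_gt(cmp$kd_logistic, cmp$kd_depletion)
  expect_equal(cmp$predicted_offset, 2.5e-9)
  expect_equal(cmp$hill_report$n_H, 1 / (fl$params$dx * log(10)),
               tolerance = 1e-12)
  expect_error(compare_fits(fl, fl), "different models|different")
  # argument order does not matter
  cmp2 <- compare_fits(fd, fl)
  expect_equal(cmp2$kd_logistic, cmp$kd_logistic)

  # with probe << Kd the two models agree
  dd2 <- simulate_fp("depletion", list(A1 = 50, A2 = 250, Kd = 1e-6),
                     noise_sd_mP = 0, probe_total = 5e-9)
  cmp3 <- compare_fits(fit_model(dd2, "logistic4"), fit_model(dd2, "depletion"))
  expect_lt(abs(cmp3$percent_difference), 5)
})
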