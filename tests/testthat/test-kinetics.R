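times_default <- seq(5e-4, 0.5, length.out = 120)

make_trace <- function(kobs = 12, noise = 0, seed = 1, times = times_default,
                       mdm2 = 2e-6) {
  generate_kinetic_trace(
    ground_truth("kinetic_trace",
                 list(kobs = kobs, amplitude = -1, offset = 10,
                      mdm2_conc_M = mdm2),
                 noise_sd = noise, seed = seed), times)
}

test_that("trace averaging is a pointwise mean with replicate bookkeeping", {
  tr <- make_trace()
  avg <- average_traces(list(tr, tr, tr, tr))
  expect_equal(avg$signal, tr$signal)
  expect_equal(avg$n_averaged, 4L)
  expect_warning(average_traces(list(tr, tr)), "fewer than 4")

  # antisymmetric noise cancels exactly
  up <- tr; up$signal <- tr$signal + 1e-3
  dn <- tr; dn$signal <- tr$signal - 1e-3
  expect_warning(avg2 <- average_traces(list(up, dn)), "fewer")
  expect_equal(avg2$signal, tr$signal, tolerance = 1e-12)

  other <- make_trace(times = times_default + 1e-3)
  expect_error(average_traces(list(tr, other)), "share")

  # averaging n replicates shrinks residual noise ~ 1/sqrt(n)
  sds <- vapply(c(1, 4, 16), function(n) {
    reps <- lapply(seq_len(n), function(r) make_trace(noise = 0.05,
                                                      seed = 100 + r))
    if (n > 1) {
      avg <- suppressWarnings(average_traces(reps))
    } else {
      avg <- reps[[1]]
    }
    stats::sd(avg$signal - make_trace()$signal)
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.2)
  expect_equal(sds[2] / sds[3], 2, tolerance = 0.2)
})

test_that("single-exponential fits recover rates and reject flat traces", {
  expect_equal(fit_single_exponential(make_trace(kobs = 20))$kobs, 20,
               tolerance = 1e-8)

  # WT-like observed rate at 2 uM MDM2: kon*C + koff = 12.2 /s
  fit <- fit_single_exponential(make_trace(kobs = 12.2, noise = 0.01,
                                           seed = 3))
  expect_lt(abs(fit$kobs - 12.2), 2 * fit$se[["kobs"]])

  flat <- make_trace()
  flat$signal <- rep(10, length(flat$time_s))
  expect_error(fit_single_exponential(flat), "no exponential behaviour")

  noise_only <- make_trace()
  noise_only$signal <- 10 + stats::rnorm(length(noise_only$time_s), 0, 0.05)
  expect_error(fit_single_exponential(noise_only), "no exponential")
})

test_that("pseudo-first-order regression returns slope kon and intercept koff", {
  concs <- seq(1e-6, 3e-6, length.out = 5)
  series <- data.frame(mdm2_conc_M = concs,
                       kobs_s = 1.6e6 * concs + 9.0)
  fit <- suppressWarnings(fit_pseudo_first_order(series))
  expect_equal(fit$kon, 1.6e6, tolerance = 1e-12)
  expect_equal(fit$koff, 9.0, tolerance = 1e-12)
  expect_identical(fit$kd_kinetic_M, fit$koff / fit$kon)

  # two points: exact interpolating line
  two <- data.frame(mdm2_conc_M = c(1e-6, 3e-6), kobs_s = c(10, 14))
  f2 <- suppressWarnings(fit_pseudo_first_order(two))
  expect_equal(f2$kon, 2e6)
  expect_equal(f2$koff, 8)

  neg <- data.frame(mdm2_conc_M = concs, kobs_s = 1e6 * concs - 0.5)
  expect_true(suppressWarnings(fit_pseudo_first_order(neg))$negative_koff)

  # round trip: points generated from a fit's own line refit exactly
  regen <- data.frame(mdm2_conc_M = concs,
                      kobs_s = fit$kon * concs + fit$koff)
  f3 <- suppressWarnings(fit_pseudo_first_order(regen))
  expect_equal(f3$kon, fit$kon, tolerance = 1e-12)
  expect_equal(f3$koff, fit$koff, tolerance = 1e-12)
})

test_that("extrapolating to the y-axis inflates the koff error well beyond the in-range precision", {
  concs <- seq(1e-6, 3e-6, length.out = 5)
  penalty <- vapply(1:100, function(r) {
    kobs <- withr::with_seed(2000 + r,
      1.6e6 * concs + 9.0 + stats::rnorm(5, 0, 0.15))
    f <- fit_pseudo_first_order(data.frame(mdm2_conc_M = concs,
                                           kobs_s = kobs))
    sigma <- sqrt(sum((kobs - (f$kon * concs + f$koff))^2) / 3)
    # SE of the intercept vs SE of the line where the data actually are
    f$koff_se / (sigma / sqrt(5))
  }, numeric(1))
  expect_gt(stats::median(penalty), 2)
})

test_that("kinetic Kd and its propagated error match the published ratios and a Monte-Carlo oracle", {
  expect_equal(kd_from_rates(1.6e6, 9.0)$kd * 1e6, 5.625)  # printed 5.5
  expect_equal(kd_from_rates(9.5e6, 7)$kd * 1e6, 0.7368, tolerance = 1e-3)
  expect_equal(kd_from_rates(1.6e6, 0)$kd, 0)
  expect_error(kd_from_rates(-1, 5), "kon")

  tab <- table_kinetics()
  tab <- tab[!is.na(tab$kon_M_s), ]
  for (i in seq_len(nrow(tab))) {
    quad <- kd_from_rates(tab$kon_M_s[i], tab$koff_s[i],
                          tab$kon_err[i], tab$koff_err[i])
    mc <- withr::with_seed(99, kd_from_rates(
      tab$kon_M_s[i], tab$koff_s[i], tab$kon_err[i], tab$koff_err[i],
      method = "montecarlo", n_draws = 1e5))
    # quadrature is first-order; MC includes the fat ratio tail, so
    # compare on the median-of-magnitude scale: 5% agreement
    skip_large <- tab$kon_err[i] / tab$kon_M_s[i] > 0.3
    if (!skip_large) {
      expect_equal(quad$kd_err, mc$kd_err, tolerance = 0.05,
                   label = tab$peptide[i])
    }
  }
})
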