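wt_two_state <- function(P0 = 0.125e-6, M0 = 2e-6) {
  mechanism_params("two_state", kon = 1.6e6, koff = 9.0,
                   conc0 = c(P = P0, M = M0))
}

test_that("scheme parameter validation rejects foreign and missing rates", {
  expect_error(mechanism_params("two_state", kon = 1e6, koff = 9, kf = 10,
                                conc0 = c(P = 1e-6, M = 1e-6)),
               "not in scheme")
  expect_error(mechanism_params("conformational_selection", kon = 1e6,
                                koff = 9, conc0 = c(Pu = 1e-6, M = 1e-6)),
               "missing rates")
  expect_error(mechanism_params("two_state", kon = 1e6, koff = 9,
                                conc0 = c(Q = 1e-6)), "unknown species")
})

test_that("two-state relaxation under MDM2 excess is single-exponential at kon[M]+koff", {
  traj <- simulate_mechanism(wt_two_state(), t_end = 1.0, n_points = 800)
  ek <- extract_kobs(traj)
  expect_true(ek$single_exponential)
  expect_equal(ek$kobs, 1.6e6 * 2e-6 + 9.0, tolerance = 0.01)  # 12.2 /s

  # all rates zero: nothing moves
  still <- mechanism_params("two_state", kon = 0, koff = 0,
                            conc0 = c(P = 1e-6, M = 2e-6, C = 5e-7))
  ts <- simulate_mechanism(still, t_end = 1)
  expect_equal(apply(ts$conc, 2, stats::sd), c(P = 0, M = 0, C = 0))
})

test_that("rapid pre-equilibrium conformational selection folds kf/(kf+ku) into kon", {
  p <- mechanism_params("conformational_selection", kon = 1.6e6, koff = 9.0,
                        kf = 4e4, ku = 6e4,
                        conc0 = c(Pu = 0.125e-6, M = 2e-6))
  traj <- simulate_mechanism(p, t_end = 1.2, n_points = 1000)
  ek <- extract_kobs(traj)
  pred <- 1.6e6 * 2e-6 * 4e4 / (4e4 + 6e4) + 9.0
  expect_equal(ek$kobs, pred, tolerance = 0.02)
})

test_that("slow folding makes the conformational-selection relaxation biphasic", {
  # peptide pre-equilibrated between coil and helix before mixing
  p <- mechanism_params("conformational_selection", kon = 1.6e6, koff = 9.0,
                        kf = 0.5, ku = 0.5,
                        conc0 = c(Pu = 0.0625e-6, Ph = 0.0625e-6, M = 2e-6))
  traj <- simulate_mechanism(p, t_end = 8, n_points = 1000)
  ek <- extract_kobs(traj)
  expect_false(ek$single_exponential)
  # the linearised rate matrix predicts two well-separated relaxations
  rates <- relaxation_rates(p, 2e-6)
  expect_lt(rates[1] * 10, rates[2])
})

test_that("a silent fast induced-fit step keeps single-exponential kinetics but shifts the equilibrium Kd", {
  p <- mechanism_params("induced_fit", kon = 1.6e6, koff = 9.0,
                        kon_star = 2100, koff_star = 1000,
                        conc0 = c(P = 0.125e-6, M = 2e-6))
  traj <- simulate_mechanism(p, t_end = 1.0, n_points = 800)
  ek <- extract_kobs(traj)
  expect_true(ek$single_exponential)
  kd_app <- apparent_kd_equilibrium(p)
  expect_gt(abs(kd_app - 9.0 / 1.6e6) / (9.0 / 1.6e6), 0.5)
})

test_that("analytic apparent Kd formulas match the printed anchors", {
  expect_equal(apparent_kd_equilibrium(wt_two_state()) * 1e6, 5.625)
  cs <- mechanism_params("conformational_selection", kon = 1.6e6,
                         koff = 9.0, kf = 100, ku = 100,
                         conc0 = c(Pu = 1e-6, M = 1e-6))
  expect_equal(apparent_kd_equilibrium(cs), 2 * 9.0 / 1.6e6)
  # an induced-fit step with K* = 2.1 reconciles the kinetic ratio with ITC
  ifp <- mechanism_params("induced_fit", kon = 1.6e6, koff = 9.0,
                          kon_star = 210, koff_star = 100,
                          conc0 = c(P = 1e-6, M = 1e-6))
  expect_equal(apparent_kd_equilibrium(ifp) * 1e6, 5.625 / 3.1)
  expect_equal(apparent_kd_equilibrium(ifp) * 1e6, 1.8, tolerance = 0.01)
})

test_that("simulated equilibria satisfy the analytic apparent Kd and detailed balance", {
  set.seed(31)
  for (rep in 1:5) {
    kon <- 10^stats::runif(1, 5.5, 7)
    koff <- 10^stats::runif(1, 0.3, 1.5)
    k1 <- 10^stats::runif(1, 2, 3.5)
    k2 <- 10^stats::runif(1, 2, 3.5)
    cases <- list(
      mechanism_params("two_state", kon = kon, koff = koff,
                       conc0 = c(P = 2e-6, M = 3e-6)),
      mechanism_params("conformational_selection", kon = kon, koff = koff,
                       kf = k1, ku = k2, conc0 = c(Pu = 2e-6, M = 3e-6)),
      mechanism_params("induced_fit", kon = kon, koff = koff,
                       kon_star = k1, koff_star = k2,
                       conc0 = c(P = 2e-6, M = 3e-6)))
    for (p in cases) {
      traj <- simulate_mechanism(p, t_end = 60 / koff, n_points = 300)
      eq <- traj$conc[nrow(traj$conc), ]
      free_pep <- sum(eq[intersect(names(eq), c("P", "Pu", "Ph"))])
      complexes <- sum(eq[intersect(names(eq), c("Cstar", "C"))])
      kd_sim <- free_pep * eq[["M"]] / complexes
      expect_equal(kd_sim, apparent_kd_equilibrium(p), tolerance = 1e-3)
      # detailed balance of each elementary step
      if (p$scheme == "conformational_selection") {
        expect_equal(eq[["Ph"]] / eq[["Pu"]], p$kf / p$ku, tolerance = 1e-4)
        expect_equal(eq[["C"]] / (eq[["Ph"]] * eq[["M"]]),
                     p$kon / p$koff, tolerance = 1e-4)
      }
      if (p$scheme == "induced_fit") {
        expect_equal(eq[["C"]] / eq[["Cstar"]], p$kon_star / p$koff_star,
                     tolerance = 1e-4)
        expect_equal(eq[["Cstar"]] / (eq[["P"]] * eq[["M"]]),
                     p$kon / p$koff, tolerance = 1e-4)
      }
    }
  }
})

test_that("both multi-step schemes collapse onto the two-state trajectory in their limits", {
  base <- simulate_mechanism(wt_two_state(), t_end = 0.5, n_points = 300)
  span <- max(base$signal)
  cs <- mechanism_params("conformational_selection", kon = 1.6e6,
                         koff = 9.0, kf = 1e6, ku = 1e-6,
                         conc0 = c(Pu = 0.125e-6, M = 2e-6))
  tr_cs <- simulate_mechanism(cs, t_end = 0.5, n_points = 300)
  expect_lt(max(abs(tr_cs$signal - base$signal)) / span, 0.005)

  ifp <- mechanism_params("induced_fit", kon = 1.6e6, koff = 9.0,
                          kon_star = 0, koff_star = 1,
                          conc0 = c(P = 0.125e-6, M = 2e-6))
  tr_if <- simulate_mechanism(ifp, t_end = 0.5, n_points = 300)
  expect_lt(max(abs(tr_if$signal - base$signal)) / span, 0.005)
})

test_that("kinetics-module refit of simulated rates recovers the simulator's constants", {
  # probe peptide well inside the pseudo-first-order regime (>= 30-fold
  # excess); at the 8-fold minimum the PFO approximation itself biases the
  # intercept by ~2%
  concs <- seq(1e-6, 3e-6, length.out = 5)
  series <- do.call(rbind, lapply(concs, function(M0) {
    traj <- simulate_mechanism(wt_two_state(P0 = 0.03e-6, M0 = M0),
                               t_end = 1.2, n_points = 600)
    data.frame(mdm2_conc_M = M0, kobs_s = extract_kobs(traj)$kobs)
  }))
  fit <- fit_pseudo_first_order(series)
  expect_equal(fit$kon, 1.6e6, tolerance = 0.02)
  expect_equal(fit$koff, 9.0, tolerance = 0.02)
})
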