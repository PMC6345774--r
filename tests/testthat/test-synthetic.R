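test_that("kinetic trace generator reproduces the exponential model exactly at zero noise", {
  times <- seq(0.001, 0.5, length.out = 100)
  tr <- generate_kinetic_trace(
    ground_truth("kinetic_trace",
                 list(kobs = 20, amplitude = -1, offset = 10)), times)
  expect_equal(tr$signal, 10 - exp(-20 * times))

  # rates from the published WT row encode kobs = kon C + koff = 12.2 /s
  kobs <- 1.6e6 * 2e-6 + 9.0
  expect_equal(kobs, 12.2)
  tr2 <- generate_kinetic_trace(
    ground_truth("kinetic_trace",
                 list(kobs = kobs, amplitude = -1, offset = 10)), times)
  expect_equal(fit_single_exponential(tr2)$kobs, 12.2, tolerance = 1e-8)

  expect_error(generate_kinetic_trace(
    ground_truth("kinetic_trace",
                 list(kobs = 20, amplitude = -1, offset = 10)),
    c(0.1, 0.05)), "non-monotone")
})

test_that("generators are bit-identical under a fixed seed", {
  t1 <- ground_truth("kinetic_trace",
                     list(kobs = 12, amplitude = -1, offset = 10),
                     noise_sd = 0.05, seed = 7)
  times <- seq(0.001, 0.5, length.out = 50)
  expect_identical(generate_kinetic_trace(t1, times)$signal,
                   generate_kinetic_trace(t1, times)$signal)

  tf <- ground_truth("fluor_titration",
                     list(Kd = 3e-6, F0 = 100, dFmax = 40,
                          MDM2_total = 4e-6), 0.5, 11)
  pc <- seq(0, 1e-5, length.out = 15)
  expect_identical(generate_fluor_titration(tf, pc)$F,
                   generate_fluor_titration(tf, pc)$F)

  te <- ground_truth("ensemble", list(helix_prob = 0.4), 0, 3)
  e1 <- generate_ensemble(te, 5, 6)
  e2 <- generate_ensemble(te, 5, 6)
  expect_identical(e1$frames, e2$frames)
})

test_that("fluorescence titration generator obeys the quadratic isotherm limits", {
  truth <- ground_truth("fluor_titration",
                        list(Kd = 3e-6, F0 = 100, dFmax = 40,
                             MDM2_total = 4e-6))
  cur <- generate_fluor_titration(truth, c(0, 1e-6, 5e-6))
  expect_equal(cur$F[1], 100)  # zero titrant -> F0

  # weak-binding limit: with dFmax/Kd fixed the initial response follows
  # the linear series F0 + (dFmax/Kd) * P_T
  big <- ground_truth("fluor_titration",
                      list(Kd = 1, F0 = 0, dFmax = 1e6,
                           MDM2_total = 4e-6))
  pc <- seq(0, 1e-6, length.out = 5)
  F <- generate_fluor_titration(big, pc)$F
  expect_equal(F, 1e6 * pc / 1, tolerance = 1e-3)

  expect_error(generate_fluor_titration(truth, c(-1e-6, 0)), "negative")
})

test_that("TFE titration generator places the transition midpoint at dG/m", {
  truth <- ground_truth("tfe_titration",
                        list(dG_water = 910, m_value = 130,
                             theta_coil = -2000, theta_helix = -31500))
  cur <- generate_tfe_titration(truth, c(0, 7, 60))
  expect_equal(cur$mre222[2], (-2000 - 31500) / 2)  # half-helical at 7%

  sym <- ground_truth("tfe_titration",
                      list(dG_water = 0, m_value = 100,
                           theta_coil = -2000, theta_helix = -31500))
  cur2 <- generate_tfe_titration(sym, c(0, 30))
  expect_equal(cur2$mre222[1], (-2000 - 31500) / 2)

  expect_error(ground_truth("tfe_titration",
                            list(dG_water = 910, m_value = -1,
                                 theta_coil = 0, theta_helix = -1)),
               "m_value")
})

test_that("ITC heat generator: zero enthalpy leaves only the dilution heat", {
  truth <- ground_truth("itc_heats",
                        list(KA = 1e5, dH = 0, n = 1, dilution_heat = 0.37))
  ex <- generate_itc_heats(truth, default_itc_schedule())
  expect_equal(ex$heats_ucal, rep(0.37, 20))
  expect_error(itc_experiment(0, 3e-4, 2e-5, rep(2e-6, 5)), "cell volume")
  expect_error(itc_experiment(2e-4, 0, 2e-5, rep(2e-6, 5)), "syringe")
})

test_that("shift-table generator maps helix probability onto conformational shifts", {
  seq13 <- wt_sequence()
  z <- generate_shift_table(
    ground_truth("shift_table", list(helix_prob = 0)), seq13, rc_ha_refs)
  expect_equal(z$delta_obs_ppm - z$delta_rc_ppm, rep(0, 13))

  half <- generate_shift_table(
    ground_truth("shift_table", list(helix_prob = 0.54)), seq13, rc_ha_refs)
  dd <- conformational_shifts(half)
  win <- dd$residue_index %in% 20:25 & dd$atom == "HA"
  expect_equal(mean(dd$delta_ppm[win]), 0.54 * -0.39, tolerance = 1e-12)

  full <- generate_shift_table(
    ground_truth("shift_table", list(helix_prob = 1)), seq13, rc_ha_refs)
  expect_equal(full$delta_obs_ppm - full$delta_rc_ppm, rep(-0.39, 13))

  pseq <- parse_peptide_sequence("Ac-EptFpsDLWKLLPEN-NH2")
  pt <- generate_shift_table(
    ground_truth("shift_table", list(helix_prob = 0.2)), pseq, rc_ha_refs)
  expect_setequal(pt$residue_index[pt$atom == "HN"], c(18, 20))
  expect_true(all(pt$phospho[pt$atom == "HN"]))

  expect_error(generate_shift_table(
    ground_truth("shift_table", list(helix_prob = 0)), seq13,
    rc_ha_refs[setdiff(names(rc_ha_refs), "W")]), "W")
})

test_that("ensemble generator realises the prescribed helix probabilities", {
  all_helix <- generate_ensemble(
    ground_truth("ensemble", list(helix_prob = 1), seed = 5), 20, 10)
  rmsds <- vapply(all_helix$frames, rmsd_to_reference, numeric(1),
                  reference = all_helix$reference)
  expect_lt(max(rmsds), 1e-9)

  en <- generate_ensemble(
    ground_truth("ensemble", list(helix_prob = 0.5), seed = 8), 2000, 5)
  freq <- mean(en$helical[3, ])
  expect_lt(abs(freq - 0.5), 0.03)  # ~2.7 binomial SDs
  # the dihedral-based assignment recovers the generator's own draws
  expect_equal(unname(helix_propensity(en)[3]), freq)

  expect_error(generate_ensemble(
    ground_truth("ensemble", list(helix_prob = 1)), 5, 2), "n_residues")
})

test_that("fitted-parameter errors grow monotonically with generator noise", {
  times <- seq(0.002, 0.5, length.out = 60)
  med_se <- vapply(c(0.005, 0.02, 0.08), function(ns) {
    ses <- vapply(1:50, function(r) {
      tr <- generate_kinetic_trace(
        ground_truth("kinetic_trace",
                     list(kobs = 12, amplitude = -1, offset = 10),
                     noise_sd = ns, seed = 1000 + r), times)
      fit_single_exponential(tr)$se[["kobs"]]
    }, numeric(1))
    stats::median(ses)
  }, numeric(1))
  expect_true(all(diff(med_se) > 0))
})
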