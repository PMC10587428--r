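fs26 <- default_frame_schedule()

test_that("simulated tissue TACs obey the degenerate limits", {
  p <- default_aif()
  tg <- fine_grid(fs26, 0.5)
  # K1 = 0: pure blood signal
  tru <- organ_truth("myocardium", kinetic_params(0, 0.1, Vb = 0.4))
  got <- simulate_tissue_tac(tru, p, fs26)
  blood_avg <- oracle_frame_average(0.4 * eval_input_function(p, tg), tg,
                                    fs26)
  expect_equal(got$value, blood_avg, tolerance = 1e-10)
  # Vb = 0, k2 = 0: frame-averaged cumulative integral K1 * int Cp
  tru2 <- organ_truth("myocardium", kinetic_params(0.5, 0, Vb = 0))
  got2 <- simulate_tissue_tac(tru2, p, fs26)
  cp <- eval_input_function(p, tg)
  h <- tg[2] - tg[1]
  cum <- 0.5 * c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2 * h))
  expect_equal(got2$value, oracle_frame_average(cum, tg, fs26),
               tolerance = 1e-10)
  expect_error(simulate_tissue_tac(tru, p, fs26, blood_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("simulated myocardial TAC matches the ODE oracle within 0.1%", {
  skip_if_not_installed("deSolve")
  p <- default_aif()
  tru <- organ_truth("myocardium", kinetic_params(0.61, 0.063, Vb = 0))
  got <- simulate_tissue_tac(tru, p, fs26)
  tg <- fine_grid(fs26, 0.5)
  ref <- ode_tissue_oracle(0.61, 0.063, 0, tg, eval_input_function(p, tg))
  expect_lt(max_rel_err(got$value, oracle_frame_average(ref, tg, fs26)),
            1e-3)
})

test_that("noiseless TACs are non-negative and linear in K1 when Vb = 0", {
  p <- default_aif()
  set.seed(11)
  for (i in 1:20) {
    kp <- kinetic_params(runif(1, 0, 2), runif(1, 0, 1), runif(1, 0, 0.1),
                         Vb = 0)
    base <- simulate_tissue_tac(organ_truth("myocardium", kp), p, fs26)
    expect_true(all(base$value >= -1e-12))
    kp2 <- kinetic_params(2 * kp$K1, kp$k2, kp$k3, Vb = 0)
    dbl <- simulate_tissue_tac(organ_truth("myocardium", kp2), p, fs26)
    expect_equal(dbl$value, 2 * base$value, tolerance = 1e-12)
  }
})

test_that("pelvis simulation produces one or two peaks as configured", {
  p <- default_aif()
  # second component off: single early vascular peak
  tru1 <- organ_truth("renal_pelvis", kinetic_params(0, 0),
                      vascular_fraction = 0.25)
  tac1 <- simulate_pelvis_tac(tru1, p, fs26)
  expect_equal(nrow(detect_peaks(tac1)), 1L)
  # both components off: all-zero curve
  tru0 <- organ_truth("renal_pelvis", kinetic_params(0, 0),
                      vascular_fraction = 0)
  expect_equal(simulate_pelvis_tac(tru0, p, fs26)$value, rep(0, 26))
  # delayed 7-min excretion component: second peak near the dense-grid
  # argmax of the generating gamma-variate (its mode, 7 min)
  sp <- list(amplitude = 170, mode_min = 7, onset_min = 1.75, shape = 3)
  tru2 <- organ_truth("renal_pelvis", kinetic_params(0, 0),
                      second_peak = sp, vascular_fraction = 0.25)
  tac2 <- simulate_pelvis_tac(tru2, p, fs26)
  pks <- detect_peaks(tac2)
  expect_equal(nrow(pks), 2L)
  expect_lt(abs(pks$T_max[2] - 7), 2.5)  # within one late frame
  expect_gt(pks$SUV_max[2], pks$SUV_max[1])
  expect_error(organ_truth("renal_pelvis", kinetic_params(0, 0),
                           second_peak = list(amplitude = 1, mode_min = -1,
                                              onset_min = 0, shape = 3)),
               "mode_min")
})

test_that("noise model: scale 0, determinism, and Monte-Carlo SD", {
  p <- default_aif()
  tru <- organ_truth("myocardium", kinetic_params(0.6, 0.08, Vb = 0.4))
  x <- simulate_tissue_tac(tru, p, fs26)
  expect_identical(add_noise(x, noise_spec(0)), x)
  n1 <- add_noise(x, noise_spec(0.05, seed = 99))
  n2 <- add_noise(x, noise_spec(0.05, seed = 99))
  expect_identical(n1$value, n2$value)
  expect_error(noise_spec(-0.1), ">= 0")
  # empirical SD of fixed frames over 1000 replicates vs the closed form
  set.seed(314)
  reps <- replicate(1000, add_noise(x, noise_spec(0.05))$value)
  sd_emp <- apply(reps, 1, sd)
  sd_th <- noise_sd(x, noise_spec(0.05))
  for (fr in c(5, 15, 22, 26))
    expect_lt(abs(sd_emp[fr] - sd_th[fr]) / sd_th[fr], 0.05)
})

test_that("cohort generation: determinism, degenerate cases, truth means", {
  expect_error(generate_cohort(0), ">= 1")
  # zero-variance distributions reproduce the configured means exactly
  td <- default_kinetic_truth()
  td[grep("_sd$", names(td))] <- 0
  co1 <- generate_cohort(1, truth_distributions = td, seed = 5,
                         noise = noise_spec(0))
  tr1 <- cohort_truth_table(co1)
  myo <- tr1[tr1$region == "myocardium" & tr1$tracer == "acac", ]
  expect_equal(myo$K1, 0.61)
  expect_equal(myo$k2, 0.063)
  # fixed seed => bit-identical output
  ca <- generate_cohort(3, seed = 7)
  cb <- generate_cohort(3, seed = 7)
  expect_identical(cohort_tac_table(ca), cohort_tac_table(cb))
  # default truth distributions: ketone myocardial K1 mean within 2 SE
  co <- generate_cohort(10, seed = 42)
  tr <- cohort_truth_table(co)
  k1 <- tr$K1[tr$region == "myocardium" & tr$tracer == "acac"]
  expect_lt(abs(mean(k1) - 0.61), 2 * 0.07 / sqrt(10))
})
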