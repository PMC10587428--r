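grid_15min <- seq(0, 15, by = 1 / 120)

test_that("one-tissue model matches the closed form for a step input", {
  # constant plasma concentration c: C_t(t) = (K1 c / k2) (1 - e^{-k2 t})
  cval <- 7.5
  step_if <- structure(list(type = "interp",
                            table = data.frame(t = c(0, 60),
                                               v = c(cval, cval)),
                            parent_model = NULL),
                       class = c("input_function"))
  pars <- kinetic_params(K1 = 0.8, k2 = 0.25, Vb = 0)
  got <- model_1tc(pars, step_if, step_if, grid_15min)
  want <- 0.8 * cval / 0.25 * (1 - exp(-0.25 * grid_15min))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("K1 = 0 gives pure blood signal; Vb mixing is linear", {
  p <- default_aif()
  cb <- eval_input_function(p, grid_15min)
  got <- model_1tc(kinetic_params(0, 0.1, Vb = 0.35), p, p, grid_15min)
  expect_equal(got, 0.35 * cb, tolerance = 1e-12)
  expect_error(model_1tc(kinetic_params(0.5, 0.1, k3 = 0.01), p, p,
                         grid_15min), "k3")
})

test_that("1TC forward model matches the stiff ODE oracle on random draws", {
  skip_if_not_installed("deSolve")
  p <- default_aif()
  cp <- eval_input_function(p, grid_15min)
  set.seed(42)
  for (i in 1:50) {
    K1 <- runif(1, 0.1, 2); k2 <- runif(1, 0.02, 1)
    got <- model_1tc(kinetic_params(K1, k2), p, p, grid_15min)
    ref <- ode_tissue_oracle(K1, k2, 0, grid_15min, cp)
    expect_lt(max_rel_err(got, ref), 1e-3)
  }
})

test_that("irreversible 2TC model: nesting, trapping limit, ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- default_aif()
  cp <- eval_input_function(p, grid_15min)
  # k3 = 0 reduces exactly to the 1TC model (same convolution path)
  pars0 <- kinetic_params(0.9, 0.3, 0, Vb = 0.2)
  expect_identical(model_2tc_irr(pars0, p, p, grid_15min),
                   model_1tc(pars0, p, p, grid_15min))
  # k2 = 0: everything taken up is trapped, C_t = K1 * int Cp
  got <- model_2tc_irr(kinetic_params(0.7, 0, 0.05), p, p, grid_15min)
  h <- 1 / 120
  cum <- c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2 * h))
  expect_equal(got, 0.7 * cum, tolerance = 1e-10)
  # renal-cortex-like parameters against the ODE oracle
  got <- model_2tc_irr(kinetic_params(0.87, 0.37, 0.021), p, p, grid_15min)
  ref <- ode_tissue_oracle(0.87, 0.37, 0.021, grid_15min, cp)
  expect_lt(max_rel_err(got, ref), 1e-3)
})

test_that("forward models are linear in K1 and in the input", {
  p <- default_aif()
  base <- model_2tc_irr(kinetic_params(0.5, 0.2, 0.03), p, p, grid_15min)
  dbl <- model_2tc_irr(kinetic_params(1.0, 0.2, 0.03), p, p, grid_15min)
  expect_equal(dbl, 2 * base, tolerance = 1e-12)
  p2 <- feng_params(A1 = 2 * 2000, A2 = 2 * 4, A3 = 2 * 12)
  scaled <- model_2tc_irr(kinetic_params(0.5, 0.2, 0.03), p2, p2,
                          grid_15min)
  expect_equal(scaled, 2 * base, tolerance = 1e-12)
})

test_that("tissue value beyond the input peak decreases as k2 increases", {
  p <- default_aif()
  t_late <- which.min(abs(grid_15min - 10))
  vals <- vapply(seq(0.05, 1, length.out = 10), function(k2)
    model_1tc(kinetic_params(0.6, k2), p, p, grid_15min)[t_late],
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("decay correction round-trips and scales by the half-life", {
  fs <- frame_schedule(c(0, 1200), c(1200, 1243.68))
  # second frame mid-time = 20.364 min (one half-life); first = 10 min
  x <- tac(fs, c(1, 1), decay_corrected = FALSE)
  xc <- decay_correct(x, decay_spec(halflife = 20.364), "apply")
  expect_equal(xc$value[2], 2, tolerance = 1e-6)
  expect_equal(xc$value[1], 2^(10 / 20.364), tolerance = 1e-6)
  back <- decay_correct(xc, decay_spec(halflife = 20.364), "remove")
  expect_equal(back$value, x$value, tolerance = 1e-12)
  expect_false(back$decay_corrected)
  expect_error(decay_correct(xc, direction = "apply"), "already")
  expect_error(decay_correct(x, direction = "remove"), "not decay-corrected")
})

test_that("linear CO2 metabolite model gives the expected parent fraction", {
  m <- metabolite_model("linear_co2", slope = 1.323)
  expect_equal(parent_fraction(m, 0), 1)
  expect_equal(parent_fraction(m, 10), 1 - 0.1323, tolerance = 1e-12)
  # clamp: fraction never negative even when metabolites reach 100%
  m2 <- metabolite_model("linear_co2", slope = 20)
  expect_equal(parent_fraction(m2, 10), 0)
  expect_true(all(diff(parent_fraction(m, seq(0, 30, 0.5))) <= 0))
  expect_error(metabolite_model("linear_co2", slope = -1), ">= 0")
})

test_that("metabolite correction rescales the plasma curve, clamped at 0", {
  p <- default_aif()
  cp <- metabolite_correct(p, metabolite_model("linear_co2", slope = 1.323))
  tt <- c(0.5, 5, 10, 20)
  expect_equal(eval_input_function(cp, tt),
               eval_input_function(p, tt) * (1 - 1.323 * tt / 100),
               tolerance = 1e-12)
  expect_equal(eval_input_function(cp, 0), 0)
  m <- metabolite_model("table_interpolated",
                        table = default_acetate_parent_table())
  cpa <- metabolite_correct(p, m)
  expect_true(all(eval_input_function(cpa, tt) <=
                    eval_input_function(p, tt)))
  expect_error(metabolite_model("table_interpolated",
                                table = data.frame(time_min = c(0, 5),
                                                   parent_fraction =
                                                     c(0.5, 0.4))),
               "must be 1 at t = 0")
})
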