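# single-substrate chain with yield Y gDW per mmol: mu = Y * v
dfba_toy <- function(Y = 0.05) toy_chain_model(yield = Y)

test_that("trajectories match the closed-form batch solution within 1%", {
  Y <- 0.05; v <- 5; X0 <- 0.01; S0 <- 20
  mu <- Y * v
  m <- dfba_toy(Y)
  tr <- dfba_simulate(m, list(biomass = X0, substrates = c(EX_glc = S0)),
                      kinetics = c(EX_glc = v), dt = 0.01, t_end = 10)
  tt <- tr$time
  X_closed <- X0 * exp(mu * tt)
  S_closed <- S0 - (v * X0 / mu) * (exp(mu * tt) - 1)
  expect_lt(max(abs(tr$biomass - X_closed) / X_closed), 0.01)
  expect_lt(max(abs(tr$EX_glc - S_closed) / S0), 0.01)
  expect_true(all(tr$EX_glc >= 0))
})

test_that("no substrate and a closed medium give a flat trajectory", {
  m <- dfba_toy()
  tr <- dfba_simulate(m, list(biomass = 0.5,
                              substrates = c(EX_glc = 0)),
                      kinetics = c(EX_glc = 5), dt = 0.1, t_end = 2)
  expect_true(all(tr$biomass == 0.5))
  expect_true(all(tr$mu == 0))
})

test_that("growth switches to CO2 fixation after organic depletion", {
  # organic route (yield 0.05/mmol) plus a carbon-fixation route
  # (yield 0.01/mmol) fed by a CO2 exchange held open in the medium
  m <- metabolic_model(
    "mixotroph", c(c = "cytoplasm", e = "extracellular"),
    metabolites = list(
      metabolite("org_e", compartment = "e"),
      metabolite("org_c", compartment = "c"),
      metabolite("co2_e", compartment = "e"),
      metabolite("co2_c", compartment = "c"),
      metabolite("bm_c", compartment = "c")),
    reactions = list(
      reaction("EX_org", c(org_e = -1), kind = "exchange"),
      reaction("EX_co2", c(co2_e = -1), kind = "exchange"),
      reaction("T_org", c(org_e = -1, org_c = 1)),
      reaction("T_co2", c(co2_e = -1, co2_c = 1)),
      reaction("R_org", c(org_c = -1, bm_c = 0.05)),
      reaction("R_fix", c(co2_c = -1, bm_c = 0.01)),
      reaction("BIOMASS", c(bm_c = -1), kind = "biomass")),
    objective = "BIOMASS")
  tr <- dfba_simulate(
    m, list(biomass = 0.05, substrates = c(EX_org = 5)),
    kinetics = c(EX_org = 4), dt = 0.05, t_end = 40,
    medium = c(EX_co2 = 2))
  # regime 1: mu = 0.05*4 + CO2 contribution 0.01*2 = 0.22
  expect_equal(tr$mu[1], 0.22, tolerance = 1e-6)
  # after depletion: autotrophic FBA value of the second regime
  expect_equal(tr$EX_org[nrow(tr)], 0)
  expect_equal(tr$mu[nrow(tr)], 0.02, tolerance = 1e-6)
  # biomass keeps growing on CO2 alone
  n <- nrow(tr)
  expect_gt(tr$biomass[n], tr$biomass[n - 10])
})

test_that("halving dt moves the endpoint by less than 0.5%", {
  m <- dfba_toy()
  init <- list(biomass = 0.01, substrates = c(EX_glc = 20))
  end <- vapply(c(0.1, 0.05), function(dt) {
    tr <- dfba_simulate(m, init, c(EX_glc = 5), dt = dt, t_end = 12)
    tr$biomass[nrow(tr)]
  }, numeric(1))
  expect_lt(abs(end[2] - end[1]) / end[1], 0.005)
})

test_that("carbon is conserved across the trajectory on a closed toy", {
  # 1 substrate carbon unit -> yield bm units; track substrate + biomass
  Y <- 0.05; v <- 5; X0 <- 0.01; S0 <- 20
  m <- dfba_toy(Y)
  tr <- dfba_simulate(m, list(biomass = X0, substrates = c(EX_glc = S0)),
                      kinetics = c(EX_glc = v), dt = 0.01, t_end = 15)
  # substrate consumed (mmol/L) vs biomass formed (gDW/L) / yield
  consumed <- S0 - tr$EX_glc
  formed <- (tr$biomass - X0) / Y
  keep <- consumed > 0.01 * S0
  expect_lt(max(abs(formed[keep] - consumed[keep]) / consumed[keep]),
            0.005)
})

test_that("calibration recovers the generating uptake rate", {
  Y <- 0.05; v_true <- 5
  m <- dfba_toy(Y)
  ser <- gen_kinetic_series(1, v = v_true, Y = Y, X0 = 0.01, S0 = 20,
                            sigma = 0)
  obs <- data.frame(time = ser$data$time, biomass = ser$data$biomass,
                    EX_glc = ser$data$substrate)
  init <- list(biomass = 0.01, substrates = c(EX_glc = 20))
  kin <- calibrate(m, init, obs, dt = 0.05)
  expect_lt(abs(kin[["EX_glc"]] - v_true) / v_true, 0.02)

  # data generated by the simulator itself: self-consistent r2 = 1
  tr <- dfba_simulate(m, init, kin, dt = 0.1, t_end = max(obs$time))
  self_obs <- data.frame(time = tr$time, biomass = tr$biomass)
  kin2 <- calibrate(m, init, self_obs, dt = 0.1)
  tr2 <- dfba_simulate(m, init, kin2, dt = 0.1, t_end = max(tr$time))
  fs <- fit_statistics(tr2, self_obs)
  expect_gt(fs$r_squared, 0.999999)

  # a non-bracketing search range is diagnosed
  expect_error(calibrate(m, init, obs, dt = 0.1,
                         vmax_range = c(50, 100)),
               "bracket")
})

test_that("co-substrate rates are apportioned by depletion slope", {
  # two parallel substrates with equal yields; planted vmax ratio 2:1
  m <- metabolic_model(
    "twosub", c(c = "cytoplasm", e = "extracellular"),
    metabolites = list(
      metabolite("a_e", compartment = "e"),
      metabolite("b_e", compartment = "e"),
      metabolite("a_c", compartment = "c"),
      metabolite("b_c", compartment = "c"),
      metabolite("bm_c", compartment = "c")),
    reactions = list(
      reaction("EX_a", c(a_e = -1), kind = "exchange"),
      reaction("EX_b", c(b_e = -1), kind = "exchange"),
      reaction("T_a", c(a_e = -1, a_c = 1)),
      reaction("T_b", c(b_e = -1, b_c = 1)),
      reaction("R_a", c(a_c = -1, bm_c = 0.05)),
      reaction("R_b", c(b_c = -1, bm_c = 0.05)),
      reaction("BIOMASS", c(bm_c = -1), kind = "biomass")),
    objective = "BIOMASS")
  init <- list(biomass = 0.01, substrates = c(EX_a = 20, EX_b = 20))
  truth <- c(EX_a = 4, EX_b = 2)
  tr <- dfba_simulate(m, init, truth, dt = 0.05, t_end = 5)
  obs <- data.frame(time = tr$time, biomass = tr$biomass,
                    EX_a = tr$EX_a, EX_b = tr$EX_b)
  obs <- obs[seq(1, nrow(obs), by = 10), ]
  kin <- calibrate(m, init, obs, dt = 0.1)
  expect_lt(abs(kin[["EX_a"]] / kin[["EX_b"]] - 2) / 2, 0.05)
  expect_lt(abs(kin[["EX_a"]] - 4) / 4, 0.05)
})

test_that("fit statistics agree with a hand-computed Pearson r", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  fs <- fit_statistics(x, y)
  expect_equal(fs$r_squared, r_hand^2, tolerance = 1e-9)
  expect_equal(fit_statistics(x, x)$r_squared, 1)
  # r-squared is sign-blind
  expect_equal(fit_statistics(x, -y)$r_squared, fs$r_squared)
  expect_error(fit_statistics(x, rep(1, 4)), "zero-variance")
  expect_error(fit_statistics(x[1:2], y[1:2]), ">= 3")
})
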