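test_that("hazard ratio per IQR converts to a log-linear slope", {
  # HR 1.33 per 6.53 ug/m^3 is about a 4.4% risk increase per ug/m^3
  expect_equal(100 * slope_from_hazard_ratio(1.33, 6.53), 4.4, tolerance = 0.01)
  expect_equal(slope_from_hazard_ratio(1.0, 6.53), 0)
  expect_equal(slope_from_hazard_ratio(exp(1), 1.0), 1.0)
  expect_error(slope_from_hazard_ratio(-1, 1), "positive")
  expect_error(slope_from_hazard_ratio(1.2, 0), "positive")
  asth <- default_asthma_crf()
  expect_equal(asth$beta, log(1.33) / 6.53)
  expect_equal(asth$threshold, 0)
})

test_that("at-risk children exclude those currently with asthma", {
  tab <- toy_health_table(population = 1000)
  tab$asthma_prevalence <- 0.08
  expect_equal(at_risk_population(tab)$at_risk, 920)
  tab$asthma_prevalence <- 0
  expect_equal(at_risk_population(tab)$at_risk, 1000)
  tab$asthma_prevalence <- 1
  expect_equal(at_risk_population(tab)$at_risk, 0)
})

test_that("attributable cases follow the attributable-fraction formula", {
  crf <- concentration_response("asthma_onset", beta = 0.0437)
  tab <- toy_health_table(population = 10000, rate = 0.0125)
  dc <- data.frame(cell_id = 1L, pollutant = "PM25_primary", delta_c = 0.01)
  got <- attributable_cases(dc, crf, tab)
  expect_equal(sum(got$cases), 0.0125 * 10000 * (1 - exp(-0.0437 * 0.01)),
               tolerance = 1e-12)
  # zero concentration change, zero cases
  dc0 <- dc; dc0$delta_c <- 0
  expect_equal(sum(attributable_cases(dc0, crf, tab)$cases), 0)
  # negative concentrations are rejected
  dcn <- dc; dcn$delta_c <- -0.1
  expect_error(attributable_cases(dcn, crf, tab), ">= 0")
})

test_that("small exposures agree with the linearized burden within 0.5%", {
  crf <- concentration_response("mortality", beta = 0.008)
  tab <- toy_health_table(population = 50000, rate = 0.012, outcome = "mortality")
  for (dcval in c(1e-4, 0.01, 0.5, 1.25)) {   # beta * dC <= 0.01
    dc <- data.frame(cell_id = 1L, pollutant = "NOx", delta_c = dcval)
    lin <- 0.008 * dcval * 0.012 * 50000
    expect_equal(sum(attributable_cases(dc, crf, tab)$cases), lin,
                 tolerance = 0.005)
  }
})

test_that("channel-wise pollutant attribution sums to the joint burden in the linear regime", {
  crf <- concentration_response("mortality", beta = 0.008)
  tab <- toy_health_table(population = 50000, rate = 0.012, outcome = "mortality")
  dc <- data.frame(cell_id = 1L, pollutant = c("PM25_primary", "NOx", "SO2"),
                   delta_c = c(0.4, 0.7, 0.1))   # beta * sum(dC) < 0.01
  chan <- attributable_cases(dc, crf, tab, attribution = "channel")
  prop <- attributable_cases(dc, crf, tab, attribution = "proportional")
  joint <- 0.012 * 50000 * (1 - exp(-0.008 * sum(dc$delta_c)))
  expect_equal(sum(prop$cases), joint, tolerance = 1e-12)
  expect_equal(sum(chan$cases), joint, tolerance = 0.01)
  # proportional split follows concentration shares exactly
  expect_equal(prop$cases / sum(prop$cases), dc$delta_c / sum(dc$delta_c),
               tolerance = 1e-12)
})

test_that("attributable fraction is bounded by min(1, beta * dC)", {
  set.seed(31)
  for (i in 1:20) {
    b <- runif(1, 0, 0.5); dc <- runif(1, 0, 50)
    af <- 1 - exp(-b * dc)
    expect_gte(af, 0)
    expect_lte(af, min(1, b * dc))
  }
})

test_that("burden is monotone in slope, population and baseline rate", {
  dc <- data.frame(cell_id = 1L, pollutant = "NOx", delta_c = 0.3)
  burden <- function(beta, pop, rate) {
    sum(attributable_cases(dc, concentration_response("mortality", beta = beta),
                           toy_health_table(population = pop, rate = rate,
                                            outcome = "mortality"))$cases)
  }
  b0 <- burden(0.008, 50000, 0.012)
  expect_gt(burden(0.010, 50000, 0.012), b0)
  expect_gt(burden(0.008, 60000, 0.012), b0)
  expect_gt(burden(0.008, 50000, 0.015), b0)
})

test_that("marginal damage per ton matches closed form and self-consistency", {
  # single cell, entry k: closed form rate*pop*(1 - exp(-beta*k))
  k <- 2.5e-3
  srm1 <- make_toy_srm(stats::setNames(lapply(POLLUTANTS, function(p) matrix(k)),
                                       POLLUTANTS))
  crf <- concentration_response("mortality", beta = 0.008)
  tab <- toy_health_table(population = 40000, rate = 0.013, outcome = "mortality")
  expect_equal(marginal_damage_per_ton(1L, "PM25_primary", crf, tab, srm1),
               0.013 * 40000 * (1 - exp(-0.008 * k)), tolerance = 1e-12)
  # zero-entry row gives zero
  z <- matrix(0); srm0 <- make_toy_srm(stats::setNames(
    lapply(POLLUTANTS, function(p) z), POLLUTANTS))
  expect_equal(marginal_damage_per_ton(1L, "NOx", crf, tab, srm0), 0)
  # 10-cell domain: equals attributable_cases run on a unit field
  tab10 <- do.call(rbind, lapply(1:10, function(i)
    toy_health_table(cell_id = i, population = 1000 * i, rate = 0.01,
                     outcome = "mortality")))
  set.seed(8)
  mats <- stats::setNames(lapply(POLLUTANTS, function(p) matrix(runif(100, 0, 1e-3), 10)),
                          POLLUTANTS)
  srm10 <- make_toy_srm(mats)
  unit <- data.frame(cell_id = 4L, pollutant = "NOx", tons_per_year = 1)
  dc <- apply_srm(unit, srm10)
  expect_equal(marginal_damage_per_ton(4L, "NOx", crf, tab10, srm10),
               sum(attributable_cases(dc[dc$pollutant == "NOx", ], crf, tab10)$cases),
               tolerance = 1e-12)
  # small-exposure limit: beta x iF x pop-weighted rate x population within 1%
  dom10 <- make_toy_domain(1000 * (1:10))
  iF <- pseudo_intake_fraction(srm10, dom10, 4, "NOx")
  approxval <- 0.008 * iF * 0.01 * sum(1000 * (1:10))
  expect_equal(marginal_damage_per_ton(4L, "NOx", crf, tab10, srm10),
               approxval, tolerance = 0.01)
})

test_that("toxicity multiplier scales only the primary-PM2.5 channel", {
  bd <- data.frame(outcome = "mortality",
                   pollutant = c("PM25_primary", "NOx"),
                   cell_id = 1L, county_id = 1L, cases = c(1, 1))
  class(bd) <- c("impact_breakdown", "data.frame")
  expect_equal(sum(apply_toxicity_multiplier(bd, 1)$cases), 2)
  # 50% primary share, m = 5: total x3
  expect_equal(sum(apply_toxicity_multiplier(bd, 5)$cases), 6)
  pure <- bd[bd$pollutant == "PM25_primary", ]
  expect_equal(sum(apply_toxicity_multiplier(pure, 5)$cases), 5)
  expect_equal(attr(apply_toxicity_multiplier(bd, 5), "toxicity_multiplier"), 5)
  expect_error(apply_toxicity_multiplier(bd, -2), ">= 0")
})

test_that("grid electricity impacts convert units and scale linearly", {
  # zero losses, unit scaler, 2.2 deaths/TWh, 1 kWh/mile -> 2.2e-9 deaths/mile
  gi <- electric_grid_impacts(kwh_per_mile = 1, grid_loss = 0, charging_loss = 0,
                              deaths_per_twh_base = 2.2,
                              projection_scalers = c("2023" = 1))
  expect_equal(gi$deaths_per_mile, 2.2e-9, tolerance = 1e-15)
  expect_equal(electric_grid_impacts(deaths_per_twh_base = 0)$deaths_per_mile, 0)
  g1 <- electric_grid_impacts()
  g2 <- electric_grid_impacts(projection_scalers = default_grid_scalers() / 2)
  expect_equal(g2$deaths_per_mile, g1$deaths_per_mile / 2)
  expect_equal(g1$generation_kwh_per_mile, 1.54 / (0.9 * 0.952), tolerance = 1e-12)
  expect_error(electric_grid_impacts(grid_loss = 1), "losses")
  expect_error(electric_grid_impacts(projection_scalers = c(0.5, -1)), "> 0")
  # asthma transfer ratio
  g3 <- electric_grid_impacts(asthma_ratio = 1.7)
  expect_equal(g3$asthma_per_mile, 1.7 * g3$deaths_per_mile)
})

test_that("pooled-cohort slope matches a finite-difference derivative", {
  loghr <- function(c, th, al, mu, nu, cf = 2.4) {
    z <- max(c - cf, 0)
    th * log(1 + z / al) / (1 + exp(-(z - mu) / nu))
  }
  th <- 0.14; al <- 1.6; mu <- 15.5; nu <- 36.8
  for (amb in c(5, 8, 12, 20)) {
    h <- 1e-6
    fd <- (loghr(amb + h, th, al, mu, nu) - loghr(amb - h, th, al, mu, nu)) / (2 * h)
    expect_equal(gemm_slope(amb, th, al, mu, nu), fd, tolerance = 1e-6)
  }
})
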