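test_that("replacing a bus with an identical bus yields exactly zero", {
  sc <- replacement_scenario("MY2010", "MY2010", "large_central_metro")
  res <- per_mile_benefit(sc, fix_domain, fix_srm, fix_efs)
  expect_identical(res$benefit_per_mile_usd, 0)
})

test_that("with zero grid damages the benefit equals the diesel bus's own impact", {
  sc <- replacement_scenario("MY2005", "electric", "large_central_metro")
  res <- per_mile_benefit(sc, fix_domain, fix_srm, fix_efs,
                          grid = list(deaths_per_twh_base = 0))
  expect_equal(res$benefit_per_mile_usd, res$replaced$usd_per_mile[["total"]],
               tolerance = 1e-12)
})

test_that("dense-population regions derive larger benefits than sparse ones", {
  mk <- function(region) per_mile_benefit(
    replacement_scenario("MY2005", "electric", region),
    fix_domain, fix_srm, fix_efs)$benefit_per_mile_usd
  expect_gt(mk("large_central_metro"), mk("noncore"))
})

test_that("per-bus fields apply lifetime mileage and discounting", {
  sc <- replacement_scenario("MY2005", "electric", "large_central_metro")
  res <- evaluate_scenario(sc, fix_domain, fix_srm, fix_efs)
  mult <- lifetime_discount_multiplier(13.5, 0.03, "mid-year")
  expect_equal(res$per_bus$health_usd,
               res$benefit_per_mile_usd * 190134 * mult, tolerance = 1e-12)
  expect_equal(res$per_bus$lifetime_multiplier, mult)
  # rate 0: per bus = per mile x lifetime miles exactly
  v0 <- valuation_params(discount_rate = 0)
  res0 <- evaluate_scenario(sc, fix_domain, fix_srm, fix_efs, valuation = v0)
  expect_equal(res0$per_bus$health_usd, res0$benefit_per_mile_usd * 190134,
               tolerance = 1e-9)
  # climate side comes from the valued flow series
  expect_equal(res$per_bus$climate_usd, climate_benefit_per_bus(), tolerance = 1e-9)
  expect_equal(res$per_bus$net_benefit_usd,
               res$per_bus$total_usd - 156000, tolerance = 1e-9)
})

test_that("scenario benefits are additive along a replacement chain", {
  reg <- "large_central_metro"
  b <- function(a, z) per_mile_benefit(replacement_scenario(a, z, reg),
                                       fix_domain, fix_srm, fix_efs)$benefit_per_mile_usd
  expect_equal(b("MY2005", "MY2020"),
               b("MY2005", "MY2010") + b("MY2010", "MY2020"), tolerance = 1e-9)
})

test_that("replacing old diesel with new diesel recovers most of the electric benefit", {
  reg <- "large_central_metro"
  b_elec <- per_mile_benefit(replacement_scenario("MY2005", "electric", reg),
                             fix_domain, fix_srm, fix_efs)$benefit_per_mile_usd
  b_new <- per_mile_benefit(replacement_scenario("MY2005", "MY2020", reg),
                            fix_domain, fix_srm, fix_efs)$benefit_per_mile_usd
  expect_gte(b_elec, b_new)
  expect_gte(b_new, 0)
  expect_gt(b_new / b_elec, 0.6)
})

test_that("higher primary-PM toxicity raises urban-old benefits fastest", {
  ratio <- function(repl, region) {
    b1 <- per_mile_benefit(replacement_scenario(repl, "electric", region),
                           fix_domain, fix_srm, fix_efs)$benefit_per_mile_usd
    b5 <- per_mile_benefit(replacement_scenario(repl, "electric", region,
                                                toxicity_multiplier = 5),
                           fix_domain, fix_srm, fix_efs)$benefit_per_mile_usd
    b5 / b1
  }
  r_urban_old <- ratio("MY2005", "large_central_metro")
  r_rural_new <- ratio("MY2010", "noncore")
  expect_gt(r_urban_old, 1)
  expect_gt(r_rural_new, 1)
  expect_gt(r_urban_old, r_rural_new)
})

test_that("fleet burden is linear in VMT with invariant per-mile rates", {
  vmt <- data.frame(county_id = fix_domain$counties$county_id,
                    vmt = c(4e6, 2e6, 3e6, 5e6, 1e6, 2e6))
  ef <- ef_vector(fix_efs, "fleet-average-2017")
  fb <- fleet_burden(vmt, ef, fix_domain, fix_srm)
  expect_gt(fb$deaths_per_year, 0)
  vmt2 <- transform(vmt, vmt = 2 * vmt)
  fb2 <- fleet_burden(vmt2, ef, fix_domain, fix_srm)
  expect_equal(fb2$deaths_per_year, 2 * fb$deaths_per_year, tolerance = 1e-4)
  expect_equal(fb2$deaths_per_100M_miles, fb$deaths_per_100M_miles,
               tolerance = 1e-4)
  # zero VMT, zero burden
  fb0 <- fleet_burden(transform(vmt, vmt = 0), ef, fix_domain, fix_srm)
  expect_equal(fb0$deaths_per_year, 0)
  # weighted-mean oracle: fleet rate equals the VMT-weighted county rates
  tab <- population_health_table(fix_domain)
  rates <- vapply(seq_len(nrow(vmt)), function(i) {
    one <- fleet_burden(vmt[i, ], ef, fix_domain, fix_srm, table = tab)
    one$deaths_per_year / vmt$vmt[i]
  }, numeric(1))
  expect_equal(fb$deaths_per_year / sum(vmt$vmt),
               sum(rates * vmt$vmt) / sum(vmt$vmt), tolerance = 1e-3)
})

test_that("class aggregation is a weighted mean whose totals sum to the fleet", {
  cv <- data.frame(county_id = fix_domain$counties$county_id,
                   value = c(10, 20, 30, 40, 50, 60))
  # equal weights: arithmetic mean per class (one county per class here)
  eq <- aggregate_by_class(cv, fix_domain)
  expect_equal(sort(eq$value), sort(cv$value))
  # random weights: matches direct weighted computation and conserves totals
  set.seed(77)
  w <- data.frame(county_id = cv$county_id, weight = runif(6, 1, 10))
  ag <- aggregate_by_class(cv, fix_domain, w)
  expect_equal(sum(ag$total), sum(cv$value * w$weight), tolerance = 1e-9)
  cls <- fix_domain$counties$urban_class[match(cv$county_id,
                                               fix_domain$counties$county_id)]
  for (k in seq_len(nrow(ag))) {
    idx <- cls == ag$urban_class[k]
    expect_equal(ag$value[k],
                 sum(cv$value[idx] * w$weight[idx]) / sum(w$weight[idx]),
                 tolerance = 1e-9)
  }
  expect_error(aggregate_by_class(data.frame(county_id = 999, value = 1),
                                  fix_domain), "unclassified")
})

test_that("district mapping conserves totals through the crosswalk", {
  cv <- data.frame(county_id = 1:3, value = c(100, 200, 300))
  # identity crosswalk: unchanged
  ident <- data.frame(county_id = 1:3, district_id = 11:13, weight = 1)
  expect_equal(map_to_districts(cv, ident)$value, cv$value)
  # 50/50 split of one county
  half <- data.frame(county_id = 1, district_id = c(1, 2), weight = 0.5)
  expect_equal(map_to_districts(cv[1, ], half)$value, c(50, 50))
  # random 10x7 crosswalk conserves totals to 1e-9 relative
  set.seed(12)
  cv10 <- data.frame(county_id = 1:10, value = runif(10, -50, 500))
  xw <- do.call(rbind, lapply(1:10, function(cid) {
    w <- runif(7); w <- w / sum(w)
    data.frame(county_id = cid, district_id = 1:7, weight = w)
  }))
  got <- map_to_districts(cv10, xw)
  expect_equal(sum(got$value), sum(cv10$value), tolerance = 1e-9)
  bad <- transform(xw, weight = weight * 1.01)
  expect_error(map_to_districts(cv10, bad), "sum to 1")
})

test_that("local share is a proper fraction and orders by decay length", {
  # diagonal source-receptor structure: all impacts stay in the source county
  sc <- replacement_scenario("MY2005", "electric", region = 4)
  res <- per_mile_benefit(sc, fix_domain, fix_srm, fix_efs)
  bd <- res$replaced$breakdown
  shares <- vapply(fix_domain$counties$county_id,
                   function(cid) local_share(bd, cid), numeric(1))
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  expect_true(all(shares >= 0 & shares <= 1))
  # primary PM2.5 stays more local than NOx (shorter decay length)
  pm <- local_share(bd[bd$pollutant == "PM25_primary", ], 4)
  nox <- local_share(bd[bd$pollutant == "NOx", ], 4)
  expect_gt(pm, nox)
  # all-self-cell matrix: share exactly 1
  n <- 3
  eye <- stats::setNames(lapply(POLLUTANTS, function(p) diag(n)), POLLUTANTS)
  srm1 <- make_toy_srm(eye)
  dom1 <- make_toy_domain(c(1000, 2000, 3000), county_id = c(1, 1, 2))
  tab1 <- population_health_table(dom1)
  md <- attributable_cases(
    apply_srm(data.frame(cell_id = 1, pollutant = "NOx", tons_per_year = 1), srm1),
    default_mortality_crf(), tab1)
  expect_equal(local_share(md, 1), 1.0)
})

test_that("net benefit subtracts the cost differential", {
  expect_equal(net_benefit(207200 + 40400, 156000), 91600)
  expect_equal(net_benefit(0, 156000), -156000)
  expect_equal(net_benefit(123, 0), 123)
  sc <- replacement_scenario("MY2005", "electric", "large_central_metro")
  res <- evaluate_scenario(sc, fix_domain, fix_srm, fix_efs)
  expect_equal(net_benefit(res), res$per_bus$total_usd - 156000)
  expect_error(net_benefit(per_mile_benefit(sc, fix_domain, fix_srm, fix_efs)),
               "per-bus")
})

test_that("evaluation is deterministic for a fixed fixture", {
  sc <- replacement_scenario("fleet-average-2017", "electric", "all")
  r1 <- evaluate_scenario(sc, fix_domain, fix_srm, fix_efs)
  r2 <- evaluate_scenario(sc, fix_domain, fix_srm, fix_efs)
  expect_identical(r1$benefit_per_mile_usd, r2$benefit_per_mile_usd)
  expect_identical(r1$per_bus, r2$per_bus)
})

test_that("unknown regions are rejected", {
  sc <- replacement_scenario("MY2005", "electric", region = 99)
  expect_error(per_mile_benefit(sc, fix_domain, fix_srm, fix_efs),
               "not in domain")
})
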