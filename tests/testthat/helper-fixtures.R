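# Shared fixture: a 100-cell, 6-county synthetic domain (one county per
# urban-rural class), its kernel source-receptor matrix and emission factors.
# Built once per test run; everything is deterministic under the fixed seed.
fix_spec <- domain_spec(n_cells = 100, n_counties = 6, seed = 42)
fix_domain <- generate_domain(fix_spec)
fix_srm <- generate_srm(fix_domain)
fix_efs <- generate_emission_factors()
fix_table <- population_health_table(fix_domain)

# Hand-built miniature domain for exact-arithmetic tests. All population in
# a single age bin ("45-49" unless given) so exposure math is transparent.
make_toy_domain <- function(pops, county_id = rep(1L, length(pops)),
                            x = seq_along(pops) * 10, y = rep(0, length(pops)),
                            area = rep(100, length(pops)), bin = "45-49") {
  n <- length(pops)
  rates <- default_rates()
  pop_age <- matrix(0L, n, nrow(rates), dimnames = list(NULL, rates$age_bin))
  pop_age[, bin] <- as.integer(pops)
  cells <- data.frame(cell_id = seq_len(n), county_id = as.integer(county_id),
                      x_km = x, y_km = y, area_km2 = area,
                      population = as.integer(pops),
                      density = pops / area,
                      urban_class = "medium_metro", stringsAsFactors = FALSE)
  cpop <- tapply(cells$population, cells$county_id, sum)
  counties <- data.frame(county_id = as.integer(names(cpop)),
                         population = as.integer(cpop),
                         area_km2 = as.numeric(tapply(cells$area_km2, cells$county_id, sum)),
                         density = NA_real_, urban_class = "medium_metro",
                         stringsAsFactors = FALSE)
  structure(list(cells = cells, counties = counties, pop_age = pop_age,
                 rates = rates, spec = NULL), class = "bus_domain")
}

# Wrap a list of (dense or sparse) per-pollutant matrices as a bus_srm
make_toy_srm <- function(mats, cell_id = seq_len(nrow(mats[[1]]))) {
  mats <- lapply(mats, function(m) methods::as(Matrix::Matrix(m, sparse = TRUE),
                                              "CsparseMatrix"))
  structure(list(matrices = mats, cell_id = cell_id,
                 units = "ug_m3_per_t_yr"), class = "bus_srm")
}

# One-row population-health table for closed-form burden checks
toy_health_table <- function(cell_id = 1L, population = 10000,
                             rate = 0.0125, outcome = "asthma") {
  if (outcome == "asthma") {
    data.frame(cell_id = cell_id, county_id = 1L, age_bin = "0-4",
               population = population, mortality_rate = 0,
               asthma_incidence = rate, asthma_prevalence = 0,
               is_child = TRUE, is_adult = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = cell_id, county_id = 1L, age_bin = "45-49",
               population = population, mortality_rate = rate,
               asthma_incidence = 0, asthma_prevalence = 0,
               is_child = FALSE, is_adult = TRUE, stringsAsFactors = FALSE)
  }
}
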