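#' Pollutant species tracked by the pipeline
#'
#' Primary PM2.5 plus the four precursor gases whose atmospheric reaction
#' products contribute secondary PM2.5.
#'
#' @export
POLLUTANTS <- c("PM25_primary", "NOx", "SO2", "NH3", "VOC")

#' Six-level urban-rural county classification, most to least urban
#' @export
URBAN_CLASSES <- c("large_central_metro", "large_fringe_metro", "medium_metro",
                   "small_metro", "micropolitan", "noncore")

# Age bins: children 0-17 (asthma onset), 18-24 carried for bookkeeping only,
# adults 25+ in 5-year steps (mortality).
CHILD_BINS <- c("0-4", "5-9", "10-14", "15-17")
ADULT_BINS <- c("25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
                "55-59", "60-64", "65-69", "70-74", "75-79", "80+")
AGE_BINS <- c(CHILD_BINS, "18-24", ADULT_BINS)

# National-style age composition (fractions of total population, normalized
# at use). Children ~22%, adults 25+ ~64%.
AGE_FRACTIONS <- c(
  "0-4" = 0.060, "5-9" = 0.061, "10-14" = 0.064, "15-17" = 0.038,
  "18-24" = 0.092,
  "25-29" = 0.069, "30-34" = 0.068, "35-39" = 0.066, "40-44" = 0.062,
  "45-49" = 0.061, "50-54" = 0.063, "55-59" = 0.065, "60-64" = 0.062,
  "65-69" = 0.053, "70-74" = 0.044, "75-79" = 0.030, "80+" = 0.039
)

#' Default age-specific baseline rates
#'
#' Baseline all-cause mortality (deaths/person/yr, adults 25+), childhood
#' asthma incidence among at-risk children (new cases/child/yr, averaging
#' about 12.5 per 1,000 across child ages) and current-asthma prevalence
#' (fraction). National-scale magnitudes; every value is editable through
#' [domain_spec()].
#'
#' @return A data.frame with one row per age bin: `age_bin`, `is_child`,
#'   `is_adult`, `mortality_rate`, `asthma_incidence`, `asthma_prevalence`.
#' @export
default_rates <- function() {
  mort <- c("25-29" = 0.0018, "30-34" = 0.0022, "35-39" = 0.0027,
            "40-44" = 0.0033, "45-49" = 0.0045, "50-54" = 0.0065,
            "55-59" = 0.0095, "60-64" = 0.0130, "65-69" = 0.0180,
            "70-74" = 0.0270, "75-79" = 0.0430, "80+" = 0.1100)
  inc <- c("0-4" = 0.022, "5-9" = 0.011, "10-14" = 0.0085, "15-17" = 0.007)
  prev <- c("0-4" = 0.040, "5-9" = 0.080, "10-14" = 0.100, "15-17" = 0.110)
  data.frame(
    age_bin = AGE_BINS,
    is_child = AGE_BINS %in% CHILD_BINS,
    is_adult = AGE_BINS %in% ADULT_BINS,
    mortality_rate = unname(ifelse(AGE_BINS %in% names(mort), mort[AGE_BINS], 0)),
    asthma_incidence = unname(ifelse(AGE_BINS %in% names(inc), inc[AGE_BINS], 0)),
    asthma_prevalence = unname(ifelse(AGE_BINS %in% names(prev), prev[AGE_BINS], 0)),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic assessment domain
#'
#' Collects everything that determines a synthetic domain: grid size, county
#' count, the log-normal population-density model, the dispersion-kernel
#' scales per pollutant, and baseline health rates. The seed fully determines
#' the generated domain: identical specs give bit-identical output.
#'
#' Primary PM2.5 disperses over a much shorter range than the secondary
#' species formed from precursor gases, so its decay length must be strictly
#' smaller than every other pollutant's.
#'
#' @param n_cells Number of grid cells (>= `n_counties`).
#' @param n_counties Number of counties (>= 1); contiguous groups of cells.
#' @param seed Integer seed determining all random draws.
#' @param density_meanlog,density_sdlog Log-normal parameters of population
#'   density (people/km^2).
#' @param spacing_km Lattice spacing between cell centroids (km).
#' @param decay_lengths_km Named per-pollutant Gaussian kernel scale (km).
#' @param kernel_amplitudes Named per-pollutant self-cell kernel amplitude,
#'   in (ug/m^3) per (t/yr) emitted.
#' @param truncation_rel Entries below this fraction of the self-cell value
#'   are dropped from the sparse matrix.
#' @param rates Age-specific baseline rates table, see [default_rates()].
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(n_cells = 400L, n_counties = 12L, seed = 1L,
                        density_meanlog = log(100), density_sdlog = 1.2,
                        spacing_km = 10,
                        decay_lengths_km = c(PM25_primary = 5, NOx = 50,
                                             SO2 = 50, NH3 = 50, VOC = 50),
                        kernel_amplitudes = c(PM25_primary = 6e-3, NOx = 1e-5,
                                              SO2 = 1e-5, NH3 = 2e-5, VOC = 5e-6),
                        truncation_rel = 1e-12,
                        rates = default_rates()) {
  n_cells <- as.integer(n_cells); n_counties <- as.integer(n_counties)
  if (is.na(n_cells) || is.na(n_counties) || n_cells < n_counties || n_counties < 1L)
    stop("need n_cells >= n_counties >= 1")
  if (!is.finite(density_meanlog) || !is.finite(density_sdlog) || density_sdlog < 0)
    stop("malformed density parameters")
  stopifnot(all(POLLUTANTS %in% names(decay_lengths_km)),
            all(POLLUTANTS %in% names(kernel_amplitudes)))
  if (any(decay_lengths_km <= 0)) stop("decay lengths must be positive")
  if (any(decay_lengths_km["PM25_primary"] >= decay_lengths_km[setdiff(POLLUTANTS, "PM25_primary")]))
    stop("primary PM2.5 decay length must be strictly smaller than the secondary species'")
  if (any(kernel_amplitudes < 0)) stop("kernel amplitudes must be non-negative")
  structure(list(
    n_cells = n_cells, n_counties = n_counties, seed = as.integer(seed),
    density_meanlog = density_meanlog, density_sdlog = density_sdlog,
    spacing_km = spacing_km,
    decay_lengths_km = decay_lengths_km[POLLUTANTS],
    kernel_amplitudes = kernel_amplitudes[POLLUTANTS],
    truncation_rel = truncation_rel, rates = rates
  ), class = "domain_spec")
}

# Largest-remainder rounding: integer vector summing to `total`.
round_largest_remainder <- function(x, total = round(sum(x))) {
  if (length(x) == 0L) return(integer(0))
  fl <- floor(x)
  rem <- as.integer(total - sum(fl))
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  } else if (rem < 0) {
    idx <- order(x - fl)[seq_len(-rem)]
    fl[idx] <- fl[idx] - 1
  }
  as.integer(fl)
}

#' Generate a synthetic assessment domain
#'
#' Lays `n_cells` cell centroids on a serpentine square lattice, draws
#' log-normal population densities with a single dense "metro core" bump,
#' assigns contiguous counties along the lattice path, classifies counties
#' into density sextiles (six urban-rural classes), and rounds populations to
#' integers with the largest-remainder method so county totals are exact.
#'
#' @param spec A [domain_spec()].
#' @return An object of class `bus_domain`: list with `cells` (data.frame),
#'   `counties` (data.frame), `pop_age` (cells x age-bins integer matrix),
#'   `rates`, and `spec`.
#' @export
generate_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  n <- spec$n_cells
  nx <- ceiling(sqrt(n))
  ix <- (seq_len(n) - 1L) %% nx          # column within row
  iy <- (seq_len(n) - 1L) %/% nx         # row
  ix <- ifelse(iy %% 2L == 0L, ix, nx - 1L - ix)  # serpentine path
  x <- (ix + 0.5) * spec$spacing_km
  y <- (iy + 0.5) * spec$spacing_km

  set.seed(spec$seed)
  z <- stats::rnorm(n)
  # metro core centered on the lattice: raises density smoothly
  cx <- nx * spec$spacing_km / 2
  cy <- (max(iy) + 1) * spec$spacing_km / 2
  core <- 3 * exp(-((x - cx)^2 + (y - cy)^2) / (2 * (3 * spec$spacing_km)^2))
  density <- exp(spec$density_meanlog + spec$density_sdlog * z + core)

  # variable resolution: dense cells are smaller
  area <- spec$spacing_km^2 / (1 + density / exp(spec$density_meanlog + 1))
  pop_real <- density * area

  # contiguous counties: near-equal-length runs along the serpentine path
  sizes <- diff(round(seq(0, n, length.out = spec$n_counties + 1)))
  county_id <- rep(seq_len(spec$n_counties), times = sizes)

  # integer populations, county totals exact
  pop <- integer(n)
  for (co in unique(county_id)) {
    sel <- county_id == co
    pop[sel] <- round_largest_remainder(pop_real[sel])
  }

  # county density sextiles -> ordered classes (densest first)
  cnty_pop <- tapply(pop, county_id, sum)
  cnty_area <- tapply(area, county_id, sum)
  cnty_dens <- cnty_pop / cnty_area
  qs <- rank(-cnty_dens, ties.method = "first") / length(cnty_dens)
  cls_idx <- pmin(ceiling(qs * 6), 6L)
  cnty_class <- URBAN_CLASSES[cls_idx]
  names(cnty_class) <- names(cnty_dens)

  # split each cell's population into age bins, rows sum exactly to cell totals
  frac <- AGE_FRACTIONS[AGE_BINS] / sum(AGE_FRACTIONS)
  pop_age <- t(vapply(pop, function(p) round_largest_remainder(p * frac, p),
                      integer(length(AGE_BINS))))
  colnames(pop_age) <- AGE_BINS

  cells <- data.frame(
    cell_id = seq_len(n), county_id = county_id,
    x_km = x, y_km = y, area_km2 = area,
    population = pop,
    density = pop / area,
    urban_class = unname(cnty_class[as.character(county_id)]),
    stringsAsFactors = FALSE
  )
  counties <- data.frame(
    county_id = as.integer(names(cnty_pop)),
    population = as.integer(cnty_pop),
    area_km2 = as.numeric(cnty_area),
    density = as.numeric(cnty_dens),
    urban_class = unname(cnty_class),
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, counties = counties, pop_age = pop_age,
                 rates = spec$rates, spec = spec),
            class = "bus_domain")
}

#' @export
print.bus_domain <- function(x, ...) {
  cat("Synthetic assessment domain:", nrow(x$cells), "cells,",
      nrow(x$counties), "counties,",
      format(sum(x$cells$population), big.mark = ","), "people\n")
  cat("Urban classes:",
      paste(names(table(x$counties$urban_class)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a pseudo source-receptor matrix
#'
#' For each pollutant, the marginal concentration at receptor r from one
#' t/yr emitted in source cell s is a Gaussian kernel of the centroid
#' distance, `k_p * exp(-d^2 / (2 L_p^2))`, truncated below
#' `truncation_rel` of the self-cell value and stored sparsely. The self-cell
#' entry (d = 0) is the row maximum by construction. Units:
#' (ug/m^3) per (t/yr).
#'
#' @param domain A `bus_domain`.
#' @param spec Defaults to the domain's own spec.
#' @return Object of class `bus_srm`: named list of sparse matrices (one per
#'   pollutant, sources in rows, receptors in columns) plus metadata.
#' @export
generate_srm <- function(domain, spec = domain$spec) {
  stopifnot(inherits(domain, "bus_domain"))
  cells <- domain$cells
  if (nrow(cells) == 0L) stop("empty cell list")
  d2 <- outer(cells$x_km, cells$x_km, "-")^2 + outer(cells$y_km, cells$y_km, "-")^2
  mats <- lapply(POLLUTANTS, function(p) {
    L <- spec$decay_lengths_km[[p]]
    k <- spec$kernel_amplitudes[[p]]
    m <- k * exp(-d2 / (2 * L^2))
    m[m < spec$truncation_rel * k] <- 0
    # general (not symmetric-packed) storage so coordinate export sees all entries
    methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                "CsparseMatrix")
  })
  names(mats) <- POLLUTANTS
  structure(list(matrices = mats, cell_id = cells$cell_id,
                 units = "ug_m3_per_t_yr",
                 decay_lengths_km = spec$decay_lengths_km,
                 kernel_amplitudes = spec$kernel_amplitudes),
            class = "bus_srm")
}

#' @export
print.bus_srm <- function(x, ...) {
  nnz <- vapply(x$matrices, function(m) length(m@x), numeric(1))
  cat("Source-receptor matrix:", length(x$cell_id), "cells x",
      length(x$matrices), "pollutants;",
      format(sum(nnz), big.mark = ","), "nonzero entries\n")
  cat("Units: (ug/m^3) per (t/yr)\n")
  invisible(x)
}

#' Synthetic per-mile emission factor sets
#'
#' Tailpipe emission factors (g/mile, tire and brake wear already excluded)
#' for the 2017 fleet average, selected diesel model years, and an all-zero
#' electric set. Emission controls phased in from model year 2007 cut rates
#' steeply: the default fixture pins the MY2005:MY2010 ratios at exactly 12
#' (primary PM2.5), 4 (NOx) and 5 (VOC).
#'
#' @param model_years Diesel model years to include (subset of 2005, 2010,
#'   2020).
#' @param include_fleet_avg Include the 2017 fleet-average set.
#' @param include_electric Include the all-zero electric tailpipe set.
#' @return A data.frame of class `ef_table` with columns `source_label`,
#'   `pollutant`, `ef_g_per_mile`.
#' @export
generate_emission_factors <- function(model_years = c(2005, 2010, 2020),
                                      include_fleet_avg = TRUE,
                                      include_electric = TRUE) {
  if (!all(model_years %in% c(2005, 2010, 2020)))
    stop("model years available: 2005, 2010, 2020")
  base <- list(
    # MY2010 anchors the post-2007-regulation level; MY2005 = 12x PM, 4x NOx, 5x VOC
    "MY2010" = c(PM25_primary = 0.10, NOx = 5.0, SO2 = 0.010, NH3 = 0.025, VOC = 0.40),
    "MY2005" = c(PM25_primary = 1.20, NOx = 20.0, SO2 = 0.012, NH3 = 0.025, VOC = 2.00),
    "MY2020" = c(PM25_primary = 0.02, NOx = 1.0, SO2 = 0.008, NH3 = 0.025, VOC = 0.10),
    "fleet-average-2017" = c(PM25_primary = 0.35, NOx = 9.0, SO2 = 0.010,
                             NH3 = 0.025, VOC = 0.80),
    "electric" = c(PM25_primary = 0, NOx = 0, SO2 = 0, NH3 = 0, VOC = 0)
  )
  keep <- paste0("MY", model_years)
  if (include_fleet_avg) keep <- c("fleet-average-2017", keep)
  if (include_electric) keep <- c(keep, "electric")
  rows <- do.call(rbind, lapply(keep, function(lbl) {
    data.frame(source_label = lbl, pollutant = POLLUTANTS,
               ef_g_per_mile = unname(base[[lbl]][POLLUTANTS]),
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("ef_table", "data.frame")
  rows
}

#' Extract one emission-factor set as a named vector
#'
#' @param efs An `ef_table`.
#' @param label A `source_label` present in the table.
#' @return Named numeric vector over the pollutant set (g/mile).
#' @export
ef_vector <- function(efs, label) {
  sel <- efs[efs$source_label == label, ]
  if (nrow(sel) == 0L) stop("unknown emission-factor set: ", label)
  stats::setNames(sel$ef_g_per_mile, sel$pollutant)[POLLUTANTS]
}

#' Write a fixture bundle to disk
#'
#' Cells and counties as tab-separated tables, the source-receptor matrix in
#' coordinate format (source_id, receptor_id, pollutant, value), emission
#' factors as TSV, and a JSON manifest recording the generating spec and seed.
#'
#' @param domain A `bus_domain`.
#' @param srm A `bus_srm`.
#' @param efs An `ef_table`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(domain, srm, efs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- cbind(domain$cells, as.data.frame(domain$pop_age, check.names = FALSE))
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(domain$counties, file.path(dir, "counties.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(domain$rates, file.path(dir, "rates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  coo <- do.call(rbind, lapply(POLLUTANTS, function(p) {
    m <- methods::as(srm$matrices[[p]], "generalMatrix")
    tr <- Matrix::mat2triplet(m)
    if (length(tr$x) == 0L) return(NULL)
    data.frame(source_id = srm$cell_id[tr$i], receptor_id = srm$cell_id[tr$j],
               pollutant = p, value = tr$x, stringsAsFactors = FALSE)
  }))
  utils::write.table(coo, file.path(dir, "srm.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(efs), file.path(dir, "emission_factors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  spec <- domain$spec
  manifest <- list(
    n_cells = spec$n_cells, n_counties = spec$n_counties, seed = spec$seed,
    density_meanlog = spec$density_meanlog, density_sdlog = spec$density_sdlog,
    spacing_km = spec$spacing_km,
    decay_lengths_km = as.list(spec$decay_lengths_km),
    kernel_amplitudes = as.list(spec$kernel_amplitudes),
    truncation_rel = spec$truncation_rel,
    srm_units = srm$units
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param dir Directory containing the bundle.
#' @return List with `domain`, `srm`, `efs`.
#' @export
read_fixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  rates <- utils::read.delim(file.path(dir, "rates.tsv"), check.names = FALSE)
  spec <- domain_spec(
    n_cells = man$n_cells, n_counties = man$n_counties, seed = man$seed,
    density_meanlog = man$density_meanlog, density_sdlog = man$density_sdlog,
    spacing_km = man$spacing_km,
    decay_lengths_km = unlist(man$decay_lengths_km),
    kernel_amplitudes = unlist(man$kernel_amplitudes),
    truncation_rel = man$truncation_rel, rates = rates
  )
  cells_full <- utils::read.delim(file.path(dir, "cells.tsv"), check.names = FALSE)
  counties <- utils::read.delim(file.path(dir, "counties.tsv"), check.names = FALSE)
  pop_age <- as.matrix(cells_full[, AGE_BINS, drop = FALSE])
  cells <- cells_full[, setdiff(names(cells_full), AGE_BINS)]
  domain <- structure(list(cells = cells, counties = counties,
                           pop_age = pop_age, rates = rates, spec = spec),
                      class = "bus_domain")
  coo <- utils::read.delim(file.path(dir, "srm.tsv"), check.names = FALSE)
  n <- nrow(cells)
  idx <- match(coo$source_id, cells$cell_id)
  jdx <- match(coo$receptor_id, cells$cell_id)
  mats <- lapply(POLLUTANTS, function(p) {
    sel <- coo$pollutant == p
    Matrix::sparseMatrix(i = idx[sel], j = jdx[sel], x = coo$value[sel],
                         dims = c(n, n))
  })
  names(mats) <- POLLUTANTS
  srm <- structure(list(matrices = mats, cell_id = cells$cell_id,
                        units = man$srm_units,
                        decay_lengths_km = spec$decay_lengths_km,
                        kernel_amplitudes = spec$kernel_amplitudes),
                   class = "bus_srm")
  efs <- utils::read.delim(file.path(dir, "emission_factors.tsv"), check.names = FALSE)
  class(efs) <- c("ef_table", "data.frame")
  list(domain = domain, srm = srm, efs = efs)
}
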