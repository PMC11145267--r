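#' Allocate county emissions to grid cells by population
#'
#' The within-county spatial distribution of school-bus emissions is assumed
#' to follow that of population: each cell receives its county's emissions in
#' proportion to its share of county population. Per-county totals are
#' conserved exactly.
#'
#' @param county_emissions data.frame with columns `county_id`, `pollutant`,
#'   `tons_per_year`.
#' @param domain A `bus_domain`.
#' @param fallback What to do for a county with zero total population:
#'   `"error"` (default) or `"uniform_area"` (spread in proportion to area).
#' @return data.frame of class `emission_field`: `cell_id`, `pollutant`,
#'   `tons_per_year` (zero rows dropped).
#' @export
allocate_county_emissions <- function(county_emissions, domain,
                                      fallback = c("error", "uniform_area")) {
  fallback <- match.arg(fallback)
  stopifnot(all(c("county_id", "pollutant", "tons_per_year") %in%
                  names(county_emissions)))
  if (any(county_emissions$tons_per_year < 0)) stop("emission rates must be >= 0")
  if (!all(county_emissions$pollutant %in% POLLUTANTS))
    stop("unknown pollutant in county emissions")
  cells <- domain$cells
  out <- lapply(seq_len(nrow(county_emissions)), function(i) {
    row <- county_emissions[i, ]
    sel <- cells$county_id == row$county_id
    if (!any(sel)) stop("county not in domain: ", row$county_id)
    pop <- cells$population[sel]
    if (sum(pop) > 0) {
      share <- pop / sum(pop)
    } else if (fallback == "uniform_area") {
      share <- cells$area_km2[sel] / sum(cells$area_km2[sel])
    } else {
      stop("county ", row$county_id, " has zero population; ",
           "enable the uniform-area fallback to allocate by area")
    }
    data.frame(cell_id = cells$cell_id[sel], pollutant = row$pollutant,
               tons_per_year = row$tons_per_year * share,
               stringsAsFactors = FALSE)
  })
  field <- do.call(rbind, out)
  field <- field[field$tons_per_year > 0, , drop = FALSE]
  # collapse duplicates (same cell+pollutant from several input rows)
  field <- stats::aggregate(tons_per_year ~ cell_id + pollutant, field, sum)
  class(field) <- c("emission_field", "data.frame")
  field
}

#' Propagate an emission field through the source-receptor matrix
#'
#' Computes the marginal ambient PM2.5 change at every receptor,
#' `delta_c(r, p) = sum_s srm(s, r, p) * E(s, p)`, keeping the per-pollutant
#' decomposition. Missing sparse entries contribute exactly zero. Linear in
#' the emission field.
#'
#' @param field An `emission_field` (cell_id, pollutant, tons_per_year).
#' @param srm A `bus_srm`.
#' @return data.frame: `cell_id` (receptor), `pollutant`, `delta_c` (ug/m^3),
#'   including zero receptors.
#' @export
apply_srm <- function(field, srm) {
  stopifnot(inherits(srm, "bus_srm"))
  if (!is.null(attr(field, "units_mismatch")) && isTRUE(attr(field, "units_mismatch")))
    stop("emission field units do not match the source-receptor matrix")
  if (!all(field$pollutant %in% names(srm$matrices)))
    stop("field contains pollutants absent from the source-receptor matrix")
  if (any(field$tons_per_year < 0)) stop("emission rates must be >= 0")
  n <- length(srm$cell_id)
  out <- lapply(names(srm$matrices), function(p) {
    e <- numeric(n)
    sel <- field$pollutant == p
    if (any(sel)) {
      idx <- match(field$cell_id[sel], srm$cell_id)
      if (anyNA(idx)) stop("field cell not present in the source-receptor matrix")
      e[idx] <- e[idx] + field$tons_per_year[sel]
    }
    dc <- as.numeric(Matrix::crossprod(srm$matrices[[p]], e))
    data.frame(cell_id = srm$cell_id, pollutant = p, delta_c = dc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Population-weighted marginal concentration per unit emission
#'
#' The pseudo intake fraction for a source cell and pollutant: the
#' population-weighted mean marginal concentration change per one t/yr
#' emitted, `sum_r pop_r srm(s,r,p) / sum_r pop_r`. Invariant to uniform
#' rescaling of all populations, and non-decreasing in every matrix entry.
#'
#' @param srm A `bus_srm`.
#' @param domain A `bus_domain` supplying receptor populations.
#' @param source_cell Cell id of the emitting cell.
#' @param pollutant One of [POLLUTANTS].
#' @return Scalar, (ug/m^3) per (t/yr), population-weighted.
#' @export
pseudo_intake_fraction <- function(srm, domain, source_cell, pollutant) {
  stopifnot(pollutant %in% names(srm$matrices))
  i <- match(source_cell, srm$cell_id)
  if (is.na(i)) stop("source cell not in domain: ", source_cell)
  pop <- domain$cells$population[match(srm$cell_id, domain$cells$cell_id)]
  if (sum(pop) <= 0) stop("zero total population")
  row <- as.numeric(srm$matrices[[pollutant]][i, ])
  sum(row * pop) / sum(pop)
}
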