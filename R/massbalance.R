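#' Per-cell geosmin yield from a culture experiment
#'
#' Splits measured geosmin into extracellular (free, supernatant) and
#' cell-bound (pellet) per-cell yields.
#'
#' @param supernatant_geosmin,pellet_geosmin total geosmin masses in g.
#' @param cell_count number of cells in the culture, > 0.
#' @param culture_volume_L optional, carried as provenance only.
#' @return object of class `cell_yield`: `free_g_per_cell`,
#'   `bound_g_per_cell`, `total_g_per_cell`.
#' @examples
#' per_cell_yield(73e-9, 67e-9, 1e9)  # 73e-18 free, 67e-18 bound
#' @export
per_cell_yield <- function(supernatant_geosmin, pellet_geosmin, cell_count,
                           culture_volume_L = NA_real_) {
  assert_nonneg(supernatant_geosmin, "supernatant geosmin")
  assert_nonneg(pellet_geosmin, "pellet geosmin")
  if (!is.finite(cell_count) || cell_count <= 0)
    stop("cell_count must be positive")
  free <- supernatant_geosmin / cell_count
  bound <- pellet_geosmin / cell_count
  structure(list(free_g_per_cell = free, bound_g_per_cell = bound,
                 total_g_per_cell = free + bound,
                 culture_volume_L = culture_volume_L),
            class = "cell_yield")
}

#' @export
print.cell_yield <- function(x, ...) {
  cat(sprintf("Per-cell geosmin yield: free %.3g, bound %.3g, total %.3g g/cell\n",
              x$free_g_per_cell, x$bound_g_per_cell, x$total_g_per_cell))
  invisible(x)
}

#' Potential geosmin production of a compartment's producer population
#'
#' Producer cells = density x size / copies_per_cell; production = cells x
#' total per-cell yield, reported in the compartment-native unit:
#' ng/L for water (per-mL density x 1000), ng/intestine for mucous
#' (density x mucous area in cm2), pg/g for digesta, ng/cm2 for fins.
#'
#' @param cell_density copies per mL (water), per cm2 (mucous/fin) or per g
#'   (digesta).
#' @param yield a `cell_yield`.
#' @param compartment one of "water", "mucous", "digesta", "fin".
#' @param size mucous area in cm2 (required for mucous; ignored elsewhere).
#' @param copies_per_cell geoA copies per producer cell (default 1).
#' @return production (scalar/vector) with attribute `unit`.
#' @export
compartment_production <- function(cell_density, yield,
                                   compartment = c("water", "mucous", "digesta", "fin"),
                                   size = 1, copies_per_cell = 1) {
  compartment <- match.arg(compartment)
  assert_nonneg(cell_density, "cell density")
  if (any(size < 0)) stop("size must be non-negative")
  if (!inherits(yield, "cell_yield")) stop("yield must be a cell_yield")
  if (copies_per_cell <= 0) stop("copies_per_cell must be positive")
  cells <- cell_density / copies_per_cell
  g <- yield$total_g_per_cell
  out <- switch(compartment,
    water = cells * 1000 * g * 1e9,        # ng per L
    mucous = cells * size * g * 1e9,       # ng per intestine
    digesta = cells * g * 1e12,            # pg per g
    fin = cells * g * 1e9)                 # ng per cm2
  attr(out, "unit") <- switch(compartment, water = "ng/L",
                              mucous = "ng/intestine",
                              digesta = "pg/g", fin = "ng/cm2")
  out
}

#' Potential contribution of intestinal-mucous production to flesh geosmin
#'
#' `100 * production / (flesh_concentration * fish_mass)`; the percent column
#' of the contribution table equals production over flesh concentration under
#' a 1 kg flesh-mass equivalence, which is the default.
#'
#' @param mucous_production ng per intestine.
#' @param flesh_conc measured flesh geosmin, ng per kg; must be > 0.
#' @param fish_mass_kg flesh mass equivalent (default 1).
#' @return percent; `NA` with a warning when `flesh_conc <= 0`.
#' @export
contribution_to_flesh <- function(mucous_production, flesh_conc, fish_mass_kg = 1) {
  assert_nonneg(mucous_production, "mucous production")
  if (fish_mass_kg <= 0) stop("fish_mass_kg must be positive")
  out <- 100 * mucous_production / (flesh_conc * fish_mass_kg)
  bad <- !is.finite(flesh_conc) | flesh_conc <= 0
  if (any(bad)) {
    warning("contribution undefined: non-positive flesh concentration")
    out[bad] <- NA_real_
  }
  out
}

#' Potential contribution of water-borne producers to water geosmin
#'
#' @param calc calculated production, ng per L.
#' @param measured measured water geosmin, ng per L.
#' @return percent; 0 when both are 0; `NA` with a warning when measured is 0
#'   but calc > 0 (undefined ratio).
#' @export
contribution_to_water <- function(calc, measured) {
  assert_nonneg(calc, "calculated production")
  assert_nonneg(measured, "measured geosmin")
  out <- 100 * calc / measured
  out[measured == 0 & calc == 0] <- 0
  undef <- measured == 0 & calc > 0
  if (any(undef)) {
    warning("contribution undefined: measured water geosmin is zero")
    out[undef] <- NA_real_
  }
  out
}

#' First-order (delta-method) propagation of standard errors
#'
#' Propagates independent input SEs through an arbitrary smooth arithmetic
#' expression via a numerically evaluated gradient:
#' `SE(y)^2 = sum_i (df/dx_i * SE_i)^2`. For a product of two terms with
#' relative SEs r_a and r_b this reduces to the familiar
#' `sqrt(r_a^2 + r_b^2)` relative SE; for sums, variances add.
#'
#' @param f function taking the named inputs as arguments (or a single named
#'   list) and returning a scalar.
#' @param values named numeric vector of input values.
#' @param ses named numeric vector of standard errors (same names).
#' @return list `value`, `se`, `flags` (notes zero-valued inputs carrying SE,
#'   for which relative-error reasoning breaks down).
#' @export
propagate_se <- function(f, values, ses) {
  if (is.null(names(values)) || !setequal(names(values), names(ses)))
    stop("values and ses must share the same names")
  ses <- ses[names(values)]
  assert_nonneg(ses, "standard errors")
  call_f <- function(v) do.call(f, as.list(v))
  y <- call_f(values)
  grad <- numeric(length(values))
  for (i in seq_along(values)) {
    h <- 1e-6 * max(abs(values[i]), 1)
    up <- values; up[i] <- up[i] + h
    dn <- values; dn[i] <- dn[i] - h
    grad[i] <- (call_f(up) - call_f(dn)) / (2 * h)
  }
  flags <- character(0)
  if (any(values == 0 & ses > 0))
    flags <- c(flags, "zero_value_with_nonzero_se")
  list(value = y, se = sqrt(sum((grad * ses)^2)), flags = flags)
}

#' Assemble the per-farm contribution table
#'
#' One row per farm: calculated production (with SE, by linear scaling of the
#' density SE) for mucous, digesta, fin and water, the measured flesh and
#' water geosmin, and the contribution percentages. Missing compartments
#' yield `NA` cells and an entry in the `flags` column. Percentages are
#' rounded only at serialization (see [write_contribution_table()]).
#'
#' @param densities data.frame: `farm`, `compartment`, `density`, `se`
#'   (per-farm mean producer density in compartment units and its SE).
#' @param measurements data.frame: `farm`, `compartment` ("flesh"/"water"),
#'   `value`, `se`, `unit`.
#' @param yield a `cell_yield`.
#' @param mucous_area_cm2 effective intestinal mucous area converting
#'   copies/cm2 to per-intestine totals (no literature default; must be set
#'   deliberately).
#' @param fish_mass_kg flesh-mass equivalence for the percent column.
#' @param copies_per_cell geoA copies per producer cell.
#' @return data.frame of class `contribution_table`, one row per farm.
#' @export
build_contribution_table <- function(densities, measurements, yield,
                                     mucous_area_cm2, fish_mass_kg = 1,
                                     copies_per_cell = 1) {
  farms <- sort(unique(c(densities$farm, measurements$farm)))
  get_dens <- function(f, comp) {
    r <- densities[densities$farm == f & densities$compartment == comp, , drop = FALSE]
    if (nrow(r) == 0) c(NA_real_, NA_real_) else c(r$density[1], r$se[1])
  }
  get_meas <- function(f, comp) {
    r <- measurements[measurements$farm == f & measurements$compartment == comp, , drop = FALSE]
    if (nrow(r) == 0) c(NA_real_, NA_real_) else c(r$value[1], r$se[1])
  }
  rows <- lapply(farms, function(f) {
    flags <- character(0)
    prod1 <- function(comp, size = 1) {
      d <- get_dens(f, comp)
      if (is.na(d[1])) {
        flags <<- c(flags, paste0("missing_", comp))
        return(c(NA_real_, NA_real_))
      }
      p <- as.numeric(compartment_production(d[1], yield, comp, size = size,
                                             copies_per_cell = copies_per_cell))
      ## production is linear in density, so the SE scales identically
      pse <- if (is.na(d[2])) NA_real_ else
        as.numeric(compartment_production(d[2], yield, comp, size = size,
                                          copies_per_cell = copies_per_cell))
      c(p, pse)
    }
    muc <- prod1("mucous", size = mucous_area_cm2)
    dig <- prod1("digesta")
    fin <- prod1("fin")
    wat <- prod1("water")
    flesh <- get_meas(f, "flesh")
    water_m <- get_meas(f, "water")
    if (is.na(flesh[1])) flags <- c(flags, "missing_flesh_measurement")
    if (is.na(water_m[1])) flags <- c(flags, "missing_water_measurement")
    cf <- if (is.na(muc[1]) || is.na(flesh[1]) || flesh[1] <= 0) NA_real_ else
      contribution_to_flesh(muc[1], flesh[1], fish_mass_kg)
    cw <- if (is.na(wat[1]) || is.na(water_m[1]) || water_m[1] <= 0) NA_real_ else
      contribution_to_water(wat[1], water_m[1])
    data.frame(farm = f,
               mucous_production_ng = muc[1], mucous_production_se = muc[2],
               flesh_ng_per_kg = flesh[1], flesh_se = flesh[2],
               contribution_flesh_pct = cf,
               digesta_pg_per_g = dig[1], digesta_se = dig[2],
               fin_ng_per_cm2 = fin[1], fin_se = fin[2],
               water_calc_ng_per_L = wat[1], water_calc_sd = wat[2],
               water_measured_ng_per_L = water_m[1], water_measured_sd = water_m[2],
               contribution_water_pct = cw,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contribution_table", class(out))
  out
}
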