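#' Configure the food-nitrogen flow model
#'
#' Parameters of the substance-flow accounting of human food N. The
#' per-capita food demand (286.1 kg person^-1 y^-1) and the compost
#' share of the municipal solid-waste stream (5.96%) are back-derived
#' from the published watershed totals; the N content of food (2.45%)
#' and the waste-stream split (38% municipal solid waste, 44% wastewater
#' exported to the ocean after primary treatment, 18% backyard septic)
#' are literature values.
#'
#' @param per_capita_food_kg Food demand, kg person^-1 y^-1.
#' @param food_n_content N mass fraction of food (default 0.0245).
#' @param frac_msw,frac_ocean,frac_septic Waste-stream partition; must
#'   sum to 1.
#' @param compost_frac_of_msw Fraction of the MSW stream recycled as
#'   compost (remainder is landfilled).
#' @return Object of class `flow_config`.
#' @export
flow_config <- function(per_capita_food_kg = 286.1,
                        food_n_content = 0.0245,
                        frac_msw = 0.38, frac_ocean = 0.44,
                        frac_septic = 0.18,
                        compost_frac_of_msw = 0.0596) {
  fr <- c(frac_msw, frac_ocean, frac_septic, compost_frac_of_msw,
          food_n_content)
  if (any(fr < 0 | fr > 1))
    stop("flow_config: fractions must lie in [0, 1]")
  if (abs(frac_msw + frac_ocean + frac_septic - 1) > 1e-9)
    stop("flow_config: waste-stream fractions must sum to 1")
  structure(list(per_capita_food_kg = per_capita_food_kg,
                 food_n_content = food_n_content,
                 frac_msw = frac_msw, frac_ocean = frac_ocean,
                 frac_septic = frac_septic,
                 compost_frac_of_msw = compost_frac_of_msw),
            class = "flow_config")
}

#' Annual nitrogen input in food
#'
#' `population * per_capita_food_kg * food_n_content / 1000` (kg -> Mg).
#'
#' @param population Persons (>= 0).
#' @param config A [flow_config()].
#' @return Mg N y^-1.
#' @export
food_n_input <- function(population, config = flow_config()) {
  if (any(population < 0)) stop("food_n_input: population must be >= 0")
  population * config$per_capita_food_kg * config$food_n_content / 1000
}

#' Partition food nitrogen into waste streams
#'
#' Splits an annual food-N input into ocean-bound wastewater (44%),
#' septic leachate to groundwater (18%) and municipal solid waste (38%),
#' the last divided between compost and landfill. The human N stock
#' change is assumed zero, so the four flows sum exactly to the input.
#'
#' @param food_n Mg N y^-1.
#' @param config A [flow_config()].
#' @return Named list `ocean`, `septic`, `landfill`, `compost` (Mg y^-1).
#' @export
partition_flows <- function(food_n, config = flow_config()) {
  if (food_n < 0) stop("partition_flows: food_n must be >= 0")
  msw <- config$frac_msw * food_n
  list(ocean = config$frac_ocean * food_n,
       septic = config$frac_septic * food_n,
       compost = config$compost_frac_of_msw * msw,
       landfill = (1 - config$compost_frac_of_msw) * msw)
}

#' Areal rate of a flow
#'
#' @param flow Mg y^-1.
#' @param area_ha Hectares (> 0).
#' @return Mg ha^-1 y^-1.
#' @export
areal_rate <- function(flow, area_ha) {
  if (any(area_ha <= 0)) stop("areal_rate: area must be > 0")
  flow / area_ha
}

#' Area of a circular buffer
#'
#' @param radius_m Buffer radius, metres.
#' @return Hectares (`pi r^2 / 1e4`).
#' @export
buffer_area <- function(radius_m) {
  if (any(radius_m < 0)) stop("buffer_area: radius must be >= 0")
  if (any(radius_m == 0)) warning("buffer_area: zero radius gives zero area")
  pi * radius_m^2 / 1e4
}

#' Full food-nitrogen budget for a population unit
#'
#' Combines [food_n_input()], [partition_flows()] and [areal_rate()]
#' into one mass-balanced budget for a watershed or a site buffer.
#'
#' @param population Persons.
#' @param area_ha Reference area for areal rates (watershed area, or the
#'   500 m buffer area for a site).
#' @param config A [flow_config()].
#' @param unit Label for the population unit.
#' @return Object of class `flow_budget` with the flows (Mg y^-1), the
#'   areal food rate and the wastewater (ocean + septic) export rate
#'   (Mg ha^-1 y^-1).
#' @export
flow_budget <- function(population, area_ha, config = flow_config(),
                        unit = "unit") {
  food_n <- food_n_input(population, config)
  fl <- partition_flows(food_n, config)
  structure(c(list(unit = unit, population = population, food_n = food_n),
              fl,
              list(area_ha = area_ha,
                   areal_food_rate = areal_rate(food_n, area_ha),
                   wastewater_export_rate =
                     areal_rate(fl$ocean + fl$septic, area_ha))),
            class = "flow_budget")
}

#' @export
print.flow_budget <- function(x, ...) {
  cat(sprintf(
    paste0("<flow_budget> %s: %s persons -> %.1f Mg N/y\n",
           "  ocean %.1f, septic %.1f, landfill %.1f, compost %.1f Mg/y\n",
           "  areal food %.3f, wastewater export %.3f Mg/ha/y (%.1f ha)\n"),
    x$unit, format(x$population, big.mark = ","), x$food_n,
    x$ocean, x$septic, x$landfill, x$compost,
    x$areal_food_rate, x$wastewater_export_rate, x$area_ha))
  invisible(x)
}

#' Flow-budget table for several population units
#'
#' @param populations Data frame `unit,population,area_ha` (e.g. the
#'   watershed plus the site buffers).
#' @param config A [flow_config()].
#' @return Data frame, one row per unit, with all flows and areal rates.
#' @export
flow_budget_table <- function(populations, config = flow_config()) {
  do.call(rbind, lapply(seq_len(nrow(populations)), function(i) {
    b <- flow_budget(populations$population[i], populations$area_ha[i],
                     config, unit = populations$unit[i])
    data.frame(unit = b$unit, population = b$population,
               area_ha = b$area_ha, food_n_mg = b$food_n,
               landfill_mg = b$landfill, compost_mg = b$compost,
               ocean_mg = b$ocean, septic_mg = b$septic,
               areal_food_rate = b$areal_food_rate,
               wastewater_export_rate = b$wastewater_export_rate,
               stringsAsFactors = FALSE)
  }))
}

#' Check that the human N stock change is negligible
#'
#' Growing children retain some N, which the flow model neglects. This
#' check quantifies that retention -- children (a fraction of the
#' population) gaining `mass_gain_kg` per year of which `n_frac_of_gain`
#' is N -- and compares it with the annual wastewater (ocean + septic)
#' flows.
#'
#' @param population Persons.
#' @param child_frac Fraction of the population that are children
#'   (default 0.2).
#' @param mass_gain_kg Annual body-mass gain per child, kg (default 2.5).
#' @param n_frac_of_gain N fraction of the gained mass (default 0.02).
#' @param config A [flow_config()] for the wastewater comparison.
#' @return List `stock_gain_kg` (kg N y^-1) and
#'   `fraction_of_wastewater` (dimensionless).
#' @export
child_stock_check <- function(population, child_frac = 0.2,
                              mass_gain_kg = 2.5, n_frac_of_gain = 0.02,
                              config = flow_config()) {
  if (population < 0) stop("child_stock_check: population must be >= 0")
  gain_kg <- population * child_frac * mass_gain_kg * n_frac_of_gain
  fl <- partition_flows(food_n_input(population, config), config)
  ww_kg <- (fl$ocean + fl$septic) * 1000
  list(stock_gain_kg = gain_kg,
       fraction_of_wastewater = if (ww_kg > 0) gain_kg / ww_kg else NA_real_)
}
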