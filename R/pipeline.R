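#' Areal summary of estuary-wide N pools
#'
#' Converts estuary-wide pool totals (Mg) and accumulation totals
#' (Mg y^-1) into areal values over the mangrove area and reports the
#' soil share of total ecosystem N -- the standard summary of how much
#' of the mangrove N pool sits belowground.
#'
#' @param ag_stock_mg Aboveground N stock total, Mg.
#' @param soil_recent_mg,soil_historic_mg Soil N stock totals per
#'   deposition period, Mg.
#' @param area_ha Mangrove area, ha.
#' @param ag_accum_mg_y,soil_recent_accum_mg_y,soil_historic_accum_mg_y
#'   Optional accumulation totals, Mg y^-1.
#' @return List of areal values (Mg ha^-1 and Mg ha^-1 y^-1), the total
#'   areal stock, and `soil_share_pct` (percent of total N in soils).
#' @export
estuary_pool_summary <- function(ag_stock_mg, soil_recent_mg,
                                 soil_historic_mg, area_ha,
                                 ag_accum_mg_y = NA_real_,
                                 soil_recent_accum_mg_y = NA_real_,
                                 soil_historic_accum_mg_y = NA_real_) {
  if (area_ha <= 0) stop("estuary_pool_summary: area must be > 0")
  soil <- soil_recent_mg + soil_historic_mg
  total <- soil + ag_stock_mg
  list(ag_areal = ag_stock_mg / area_ha,
       soil_recent_areal = soil_recent_mg / area_ha,
       soil_historic_areal = soil_historic_mg / area_ha,
       soil_areal = soil / area_ha,
       total_areal = total / area_ha,
       soil_share_pct = 100 * soil / total,
       ag_accum_areal = ag_accum_mg_y / area_ha,
       soil_recent_accum_areal = soil_recent_accum_mg_y / area_ha,
       soil_historic_accum_areal = soil_historic_accum_mg_y / area_ha)
}

.read_mask <- function(path, cell_size) {
  m <- utils::read.csv(path)
  if (!all(c("x_m", "y_m") %in% names(m)))
    stop("mask: needs columns x_m,y_m")
  grid_spec(data.frame(x = m$x_m, y = m$y_m), cell_size)
}

#' Run the full nitrogen-budget pipeline
#'
#' Orchestrates all stages over a bundle of input tables: core loading
#' and validation, per-core period budgets, bootstrap estimates with
#' site pooling and overlap comparisons, stochastic estuary-wide
#' upscaling of stocks and accumulation, the food-N flow model,
#' porewater summaries, and isotope profile fits. One summary table per
#' stage is written to the output directory together with a run manifest
#' (config echo, seed, package version); identical config and seed give
#' an identical bundle.
#'
#' @param config Either a YAML file path or a list with entries:
#'   `input` (paths `cores`, `sar`, `sites`, `porewater`, `populations`,
#'   `mask`), `cell_size`, `bootstrap` (`n_boot`, `seed`), `upscaling`
#'   (`n_iterations`, `power`, `skew`), `flow` (passed to
#'   [flow_config()]), `output_dir`.
#' @return Invisible list of per-stage results (`budget`, `bootstrap`,
#'   `comparisons`, `upscaling`, `flows`, `porewater`, `isotopes`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inp <- config$input
  for (f in c("cores", "sar", "sites", "populations", "mask")) {
    if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
      stop("run_pipeline: missing input file '", f, "'")
  }
  out_dir <- config$output_dir %||% stop("run_pipeline: output_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$bootstrap$seed %||% 1L
  n_boot <- config$bootstrap$n_boot %||% 1000L
  n_iter <- config$upscaling$n_iterations %||% 100L
  power <- config$upscaling$power %||% 2
  skew <- config$upscaling$skew %||% 1.5
  periods <- default_periods()

  # -- load ----------------------------------------------------------
  sar <- read_sar_table(inp$sar)
  cores <- read_core_table(inp$cores, sar = sar)
  sites <- read_site_table(inp$sites)
  missing_site <- setdiff(vapply(cores, `[[`, "", "site_id"), names(sites))
  if (length(missing_site))
    stop("run_pipeline: cores reference site(s) without a location: ",
         paste(unique(missing_site), collapse = ", "))
  grid <- .read_mask(inp$mask, config$cell_size %||% 20)
  pops <- utils::read.csv(inp$populations, stringsAsFactors = FALSE)

  # -- deterministic budgets ----------------------------------------
  budget <- budget_report(cores, periods)
  utils::write.csv(budget, file.path(out_dir, "budget.csv"),
                   row.names = FALSE)

  # -- bootstrap + comparisons --------------------------------------
  boot <- bootstrap_cores(cores, periods, n_boot = n_boot, seed = seed)
  utils::write.csv(boot$table, file.path(out_dir, "bootstrap.csv"),
                   row.names = FALSE)
  comparisons <- .temporal_comparisons(boot, cores, periods)
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)

  # -- estuary upscaling --------------------------------------------
  site_ids <- names(sites)
  locs <- data.frame(site_id = site_ids,
                     x = vapply(sites, `[[`, 0, "x"),
                     y = vapply(sites, `[[`, 0, "y"))
  upsc <- list()
  for (pd in periods) {
    for (q in c("stock", "accumulation")) {
      dd <- .site_distributions(boot, cores, pd$name, q, skew)
      if (is.null(dd) || nrow(dd) < length(site_ids)) next
      if (q == "accumulation") dd$mean <- dd$mean / 100  # g m-2 y-1 -> Mg/ha/y
      if (q == "accumulation") dd$sd <- dd$sd / 100
      est <- estuary_estimate(dd, locs, grid, n_iterations = n_iter,
                              power = power,
                              seed = substream_seed(seed,
                                                    paste(pd$name, q)))
      upsc[[paste(pd$name, q, sep = "_")]] <- est
    }
  }
  upsc_tab <- do.call(rbind, lapply(names(upsc), function(k) {
    e <- upsc[[k]]
    data.frame(quantity = k, total_mean = e$total_mean,
               total_se = e$total_se, areal_mean = e$areal_mean,
               n_iterations = e$n_iterations, area_ha = e$area_ha)
  }))
  utils::write.csv(upsc_tab, file.path(out_dir, "upscaling.csv"),
                   row.names = FALSE)

  # -- flow model ----------------------------------------------------
  fc <- do.call(flow_config, config$flow %||% list())
  flows <- flow_budget_table(pops, fc)
  utils::write.csv(flows, file.path(out_dir, "flows.csv"),
                   row.names = FALSE)

  # -- porewater -----------------------------------------------------
  pw_summary <- NULL
  if (!is.null(inp$porewater) && file.exists(inp$porewater)) {
    pw <- read_porewater_table(inp$porewater)
    pw_summary <- porewater_summary(pw)
    utils::write.csv(pw_summary, file.path(out_dir, "porewater.csv"),
                     row.names = FALSE)
  }

  # -- isotope profiles ---------------------------------------------
  iso_tab <- NULL
  by_site <- split(cores, vapply(cores, `[[`, "", "site_id"))
  fits <- list()
  for (sid in names(by_site)) {
    s <- do.call(rbind, lapply(by_site[[sid]], `[[`, "slices"))
    if (sum(!is.na(s$d34s)) >= 4L) {
      fits[[sid]] <- fit_profile((s$depth_top + s$depth_bottom) / 2,
                                 s$d34s, site_id = sid)
    }
  }
  if (length(fits) >= 1L) {
    fits <- simultaneous_bounds(fits)
    iso_tab <- profile_fit_table(fits)
    utils::write.csv(iso_tab, file.path(out_dir, "isotopes.csv"),
                     row.names = FALSE)
  }

  manifest <- list(seed = seed, n_boot = n_boot, n_iterations = n_iter,
                   power = power, skew = skew,
                   cell_size = grid$cell_size, area_ha = grid$total_area_ha,
                   config = config,
                   package_version = as.character(
                     utils::packageVersion("mangroveN")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(budget = budget, bootstrap = boot,
                 comparisons = comparisons, upscaling = upsc,
                 flows = flows, porewater = pw_summary, isotopes = iso_tab,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recent-vs-historic overlap calls per core and quantity (stocks
# normalized by period length before comparison)
.temporal_comparisons <- function(boot, cores, periods) {
  rows <- list()
  for (cid in names(boot$estimates)) {
    per <- boot$estimates[[cid]]
    if (!all(c("recent", "historic") %in% names(per))) next
    for (qn in intersect(names(per$recent), names(per$historic))) {
      a <- per$recent[[qn]]; b <- per$historic[[qn]]
      if (qn == "stock") {
        a <- new_boot_estimate(a$replicate_values /
                                 periods$recent$duration_y)
        b <- new_boot_estimate(b$replicate_values /
                                 periods$historic$duration_y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        core_id = cid, quantity = qn,
        recent_mean = a$mean, historic_mean = b$mean,
        call = compare_estimates(a, b), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# site-level value distributions for upscaling: pooled bootstrap
# replicates of the per-core derived quantity give the site mean and sd
.site_distributions <- function(boot, cores, period_name, quantity, skew) {
  site_of <- vapply(cores, `[[`, "", "site_id")
  rows <- list()
  for (sid in unique(site_of)) {
    cids <- names(cores)[site_of == sid]
    ests <- list()
    for (cid in cids) {
      e <- boot$estimates[[cid]][[period_name]][[quantity]]
      if (!is.null(e)) ests[[length(ests) + 1L]] <- e
    }
    if (!length(ests)) next
    pooled <- pool_site(ests)
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sid, mean = pooled$mean,
      sd = stats::sd(pooled$replicate_values), skew = skew,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
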