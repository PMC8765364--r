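#' Describe a synthetic mangrove site
#'
#' Holds everything needed to simulate cores, porewater and population
#' for one site: period-specific true moments of N fraction and bulk
#' density, period SARs, isotope structure, skewness of within-site
#' value distributions, stand composition and buffer population. The
#' envelopes enforced here (bulk density means in (0.1, 1.1) g cm^-3,
#' SARs in (1, 7) mm y^-1, N-fraction means in (0.003, 0.02)) are the
#' observed ranges of peri-urban mangrove cores that the generator
#' emulates.
#'
#' @param site_id,urban_index,x,y As in [site_record()].
#' @param recent,historic Lists `n_mean,n_sd,bd_mean,bd_sd,sar` for each
#'   period (fractions, g cm^-3, mm y^-1).
#' @param d15n Named numeric `c(recent=, historic=)`, per mil.
#' @param d34s Numeric `c(intercept, slope, quad, noise_sd)` of the
#'   depth profile (per mil, per mil cm^-1, per mil cm^-2, per mil).
#' @param skew Right-skew shape of value draws (default 1.5).
#' @param cn_molar Molar C:N used to derive carbon fractions.
#' @param species_composition Named biomass proportions (sum 1).
#' @param population Persons in the 500 m buffer.
#' @param porewater List `wet`/`dry`, each `c(nh4=, nox=, po4=)` in uM.
#' @param d15n_sd Slice-level d15N noise sd, per mil (default 0.3).
#' @return Object of class `site_template`.
#' @export
site_template <- function(site_id, urban_index, x, y, recent, historic,
                          d15n, d34s, skew = 1.5, cn_molar = 20,
                          species_composition = c(A_germinans = 1),
                          population = 0, porewater = NULL,
                          d15n_sd = 0.3) {
  for (p in list(recent, historic)) {
    stopifnot(all(c("n_mean", "n_sd", "bd_mean", "bd_sd", "sar") %in%
                    names(p)))
    if (!(p$bd_mean > 0.1 && p$bd_mean < 1.1))
      stop("site ", site_id, ": bulk density mean outside (0.1, 1.1)")
    if (!(p$sar > 1 && p$sar < 7))
      stop("site ", site_id, ": SAR outside (1, 7) mm y-1")
    if (!(p$n_mean > 0.003 && p$n_mean < 0.02))
      stop("site ", site_id, ": n_fraction mean outside (0.003, 0.02)")
  }
  structure(list(site_id = as.character(site_id),
                 urban_index = urban_index, x = x, y = y,
                 recent = recent, historic = historic,
                 d15n = d15n, d15n_sd = d15n_sd, d34s = d34s,
                 skew = skew, cn_molar = cn_molar,
                 species_composition = species_composition,
                 population = population, porewater = porewater),
            class = "site_template")
}

#' Default synthetic site templates
#'
#' Five sites patterned on the study design the package targets: a
#' dredged, well flushed high-urban site (dense mineral soil, low %N,
#' surface-depleted d34S), a clogged sewage-influenced site (fast
#' accretion, surface-enriched d34S, P-rich porewater), a settling-basin
#' lagoon (very low bulk density, the highest %N), a dredged-inlet
#' lagoon with high within-site variability, and a hypersaline isolated
#' forest (low C:N, very high porewater ammonium). Porewater means
#' follow the published site-by-season concentration table.
#'
#' @return Named list of five `site_template`s.
#' @export
default_site_templates <- function() {
  t <- list(
    site_template("MPW", 100, x = 200, y = 800,
      recent = list(n_mean = 0.0049, n_sd = 0.0010, bd_mean = 0.80,
                    bd_sd = 0.10, sar = 2.0),
      historic = list(n_mean = 0.0045, n_sd = 0.0010, bd_mean = 0.85,
                      bd_sd = 0.10, sar = 1.6),
      d15n = c(recent = 2.8, historic = 3.9),
      d34s = c(intercept = -2, slope = 0.45, quad = -0.006, noise_sd = 0.8),
      cn_molar = 24,
      species_composition = c(L_racemosa = 0.6, A_germinans = 0.4),
      population = 3953,
      porewater = list(wet = c(nh4 = 24.5, nox = 0.3, po4 = 1.7),
                       dry = c(nh4 = 36.2, nox = 5.8, po4 = 3.8))),
    site_template("MPE", 90, x = 1500, y = 700,
      recent = list(n_mean = 0.0074, n_sd = 0.0015, bd_mean = 0.60,
                    bd_sd = 0.08, sar = 6.2),
      historic = list(n_mean = 0.0060, n_sd = 0.0012, bd_mean = 0.62,
                      bd_sd = 0.08, sar = 3.0),
      d15n = c(recent = 3.9, historic = 3.9),
      d34s = c(intercept = 10, slope = -0.5, quad = 0.008, noise_sd = 0.8),
      cn_molar = 20,
      species_composition = c(L_racemosa = 0.5, A_germinans = 0.3,
                              R_mangle = 0.2),
      population = 4303,
      porewater = list(wet = c(nh4 = 20.8, nox = 2.3, po4 = 49.8),
                       dry = c(nh4 = 125.8, nox = 1.0, po4 = 93.4))),
    site_template("SJ", 55, x = 2800, y = 900,
      recent = list(n_mean = 0.0124, n_sd = 0.0020, bd_mean = 0.18,
                    bd_sd = 0.03, sar = 1.6),
      historic = list(n_mean = 0.0097, n_sd = 0.0015, bd_mean = 0.20,
                      bd_sd = 0.03, sar = 1.3),
      d15n = c(recent = 5.1, historic = 7.2),
      d34s = c(intercept = 4, slope = -0.12, quad = 0, noise_sd = 0.6),
      cn_molar = 27,
      species_composition = c(A_germinans = 0.5, L_racemosa = 0.5),
      population = 1729,
      porewater = list(wet = c(nh4 = 34.6, nox = 0.4, po4 = 4.2),
                       dry = c(nh4 = 27.8, nox = 1.4, po4 = 4.7))),
    site_template("Torr", 30, x = 4300, y = 600,
      recent = list(n_mean = 0.0076, n_sd = 0.0015, bd_mean = 0.55,
                    bd_sd = 0.15, sar = 2.9),
      historic = list(n_mean = 0.0060, n_sd = 0.0012, bd_mean = 0.60,
                      bd_sd = 0.15, sar = 1.8),
      d15n = c(recent = 5.6, historic = 5.6),
      d34s = c(intercept = 7, slope = -0.35, quad = 0.005, noise_sd = 0.8),
      cn_molar = 25,
      species_composition = c(R_mangle = 0.6, L_racemosa = 0.4),
      population = 517,
      porewater = list(wet = c(nh4 = 24.9, nox = 1.2, po4 = 8.3),
                       dry = c(nh4 = 22.5, nox = 0.6, po4 = 9.1))),
    site_template("Pin", 1, x = 5600, y = 900,
      recent = list(n_mean = 0.0086, n_sd = 0.0015, bd_mean = 0.45,
                    bd_sd = 0.06, sar = 5.5),
      historic = list(n_mean = 0.0075, n_sd = 0.0012, bd_mean = 0.48,
                      bd_sd = 0.06, sar = 3.8),
      d15n = c(recent = 3.7, historic = 3.8),
      d34s = c(intercept = 12, slope = -0.45, quad = 0.007, noise_sd = 0.8),
      cn_molar = 12,
      species_composition = c(R_mangle = 0.5, A_germinans = 0.3,
                              L_racemosa = 0.2),
      population = 36,
      porewater = list(wet = c(nh4 = 1057.3, nox = 0.0, po4 = 3.9),
                       dry = c(nh4 = 451.0, nox = 0.3, po4 = 31.6)))
  )
  stats::setNames(t, vapply(t, `[[`, "", "site_id"))
}

#' Default synthetic estuary mask
#'
#' An elliptical mangrove mask of roughly 6 km by 1.6 km at 20 m cells
#' (~19,000 cells, ~750 ha): a desk-scale stand-in for a full-resolution
#' coastal land-cover mask; resolution is a config choice.
#'
#' @param cell_size Cell edge, metres (default 20).
#' @return A `grid_spec`.
#' @export
default_estuary_grid <- function(cell_size = 20) {
  make_mask(nx = round(6000 / cell_size), ny = round(1600 / cell_size),
            cell_size = cell_size, shape = "ellipse")
}

# Linear age-depth relation: within each period the template SAR holds,
# anchored at the collection year at the surface.
.depth_to_date <- function(depth_cm, template, periods) {
  sr <- template$recent$sar / 10   # cm per year
  sh <- template$historic$sar / 10
  rt <- sr * periods$recent$duration_y   # cm of recent deposit
  ifelse(depth_cm <= rt,
         periods$recent$end_year - depth_cm / sr,
         periods$recent$start_year - (depth_cm - rt) / sh)
}

#' Generate a synthetic sediment core
#'
#' Builds the standard slicing scheme (1-cm slices over 0--3 cm, then
#' 2-cm slices to `max_depth`), dates each slice midpoint with a linear
#' age-depth relation per period using the template SARs, draws bulk
#' density and N fraction from right-skewed distributions with the
#' template period moments (truncated to physical ranges), derives the
#' carbon fraction from the template molar C:N, and writes d15N (period
#' mean + noise) and d34S (quadratic depth profile + noise).
#'
#' With `noise = 0` every drawn value equals its template mean, so the
#' computed budgets reproduce the ground truth exactly.
#'
#' @param template A `site_template`.
#' @param core_id Label.
#' @param seed Integer seed (cores get deterministic substreams from it).
#' @param periods Period definitions (default [default_periods()]).
#' @param max_depth Core depth, cm (default 37, within the 37--50 cm
#'   range of real cores).
#' @param noise Multiplier on all template sds (0 = deterministic).
#' @return A `sediment_core` with `sar_by_period` attached.
#' @export
generate_core <- function(template, core_id, seed = 1,
                          periods = default_periods(), max_depth = 37,
                          noise = 1) {
  set.seed(substream_seed(seed, core_id))
  top <- c(0, 1, 2, seq(3, max_depth - 2, by = 2))
  bottom <- c(1, 2, 3, seq(5, max_depth, by = 2))
  mid <- (top + bottom) / 2
  dates <- .depth_to_date(mid, template, periods)
  recent <- dates >= periods$recent$start_year
  par_of <- function(field) {
    ifelse(recent, template$recent[[field]], template$historic[[field]])
  }
  n <- length(mid)
  zf <- draw_skew_normal(n, 0, 1, skew = template$skew, truncate = FALSE)
  fn <- par_of("n_mean") + par_of("n_sd") * noise * zf
  zb <- draw_skew_normal(n, 0, 1, skew = template$skew, truncate = FALSE)
  bd <- par_of("bd_mean") + par_of("bd_sd") * noise * zb
  fn <- pmin(pmax(fn, 1e-5), 0.0999)
  bd <- pmin(pmax(bd, 0.05), 2.5)
  cfrac <- pmin(fn * template$cn_molar * 12.011 / 14.007, 0.599)
  d15 <- ifelse(recent, template$d15n[["recent"]],
                template$d15n[["historic"]]) +
    stats::rnorm(n, 0, template$d15n_sd * noise)
  pr <- template$d34s
  d34 <- pr[["intercept"]] + pr[["slope"]] * mid + pr[["quad"]] * mid^2 +
    stats::rnorm(n, 0, pr[["noise_sd"]] * noise)
  slices <- data.frame(depth_top = top, depth_bottom = bottom,
                       mid_date = dates, bulk_density = bd,
                       n_fraction = fn, c_fraction = cfrac,
                       d15n = d15, d34s = d34)
  sediment_core(core_id, template$site_id, slices,
                sar_by_period = c(recent = template$recent$sar,
                                  historic = template$historic$sar))
}

#' Generate synthetic porewater samples for a site
#'
#' Draws `n` replicate samples per season from right-skewed
#' distributions around the template's seasonal means (cv 0.3 scaled by
#' `noise`). Nitrate+nitrite draws that fall below the detection limit
#' are flagged as non-detects, exercising the non-detect policy
#' downstream.
#'
#' @param template A `site_template` with a `porewater` entry.
#' @param n Replicates per season (default 5).
#' @param seed Seed.
#' @param noise Noise multiplier.
#' @param dl Detection limit for nitrate+nitrite, uM.
#' @return Porewater sample data frame (see [read_porewater_table()]).
#' @export
generate_porewater <- function(template, n = 5, seed = 1, noise = 1,
                               dl = 0.05) {
  if (is.null(template$porewater)) return(NULL)
  set.seed(substream_seed(seed, paste0("pw-", template$site_id)))
  rows <- list()
  for (season in c("wet", "dry")) {
    m <- template$porewater[[season]]
    nh4 <- draw_skew_normal(n, m[["nh4"]], 0.3 * m[["nh4"]] * noise,
                            skew = template$skew)
    nox <- draw_skew_normal(n, m[["nox"]], 0.5 * max(m[["nox"]], 0.1) * noise,
                            skew = template$skew)
    po4 <- draw_skew_normal(n, m[["po4"]], 0.3 * m[["po4"]] * noise,
                            skew = template$skew)
    det <- nox >= dl
    rows[[season]] <- data.frame(
      site_id = template$site_id, season = season,
      nh4_um = nh4, nox_um = ifelse(det, nox, NA_real_),
      nox_detected = det, po4_um = po4,
      salinity_psu = NA_real_, ph = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Ground truth implied by site templates
#'
#' Deterministic reference values computed from the template means: the
#' per-site, per-period N stock (from a zero-noise core, so the depth
#' discretization matches the generator exactly) and accumulation rate,
#' and -- when a grid is supplied -- deterministic estuary-wide totals
#' obtained by interpolating the site true values over the mask.
#'
#' @param templates List of `site_template`s.
#' @param grid Optional `grid_spec` for estuary totals.
#' @param periods Period definitions.
#' @param max_depth Core depth used for the reference cores.
#' @param power IDW exponent.
#' @return List with `sites` (data frame of per-site truths) and,
#'   given a grid, `estuary` (named totals in Mg and Mg y^-1).
#' @export
ground_truth <- function(templates, grid = NULL,
                         periods = default_periods(), max_depth = 37,
                         power = 2) {
  sites <- do.call(rbind, lapply(templates, function(tpl) {
    core0 <- generate_core(tpl, "truth", seed = 0, periods = periods,
                           max_depth = max_depth, noise = 0)
    data.frame(
      site_id = tpl$site_id,
      stock_recent = core_period_stock(core0, periods$recent)$value,
      stock_historic = core_period_stock(core0, periods$historic)$value,
      accum_recent = n_accumulation_rate(tpl$recent$sar, tpl$recent$bd_mean,
                                         tpl$recent$n_mean),
      accum_historic = n_accumulation_rate(tpl$historic$sar,
                                           tpl$historic$bd_mean,
                                           tpl$historic$n_mean),
      stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  out <- list(sites = sites)
  if (!is.null(grid)) {
    locs <- data.frame(site_id = sites$site_id,
                       x = vapply(templates, `[[`, 0, "x"),
                       y = vapply(templates, `[[`, 0, "y"))
    det_total <- function(values) {
      dd <- data.frame(site_id = sites$site_id, mean = values, sd = 0,
                       skew = 1.5)
      estuary_iteration(dd, locs, grid, power = power, seed = 0)
    }
    out$estuary <- c(
      stock_recent_mg = det_total(sites$stock_recent),
      stock_historic_mg = det_total(sites$stock_historic),
      # accumulation in g m-2 y-1 -> Mg ha-1 y-1 for areal upscaling
      accum_recent_mg_y = det_total(sites$accum_recent / 100),
      accum_historic_mg_y = det_total(sites$accum_historic / 100),
      area_ha = grid$total_area_ha)
  }
  out
}

#' Generate a full synthetic estuary bundle
#'
#' Emits everything the analysis pipeline consumes -- cores with SARs,
#' site records, porewater samples, buffer populations, a mangrove mask
#' -- together with the deterministic ground truth for recovery tests.
#'
#' @param templates Site templates (default [default_site_templates()]).
#' @param grid Mangrove mask (default [default_estuary_grid()]).
#' @param cores_per_site Replicate cores per site (default 2).
#' @param seed Run seed.
#' @param noise Noise multiplier (0 = deterministic).
#' @param porewater_n Porewater replicates per site and season.
#' @param periods,max_depth Passed to [generate_core()].
#' @return Object of class `estuary_bundle`: `cores`, `sites`,
#'   `porewater`, `populations`, `grid`, `truth`, `seed`.
#' @export
generate_estuary <- function(templates = default_site_templates(),
                             grid = default_estuary_grid(),
                             cores_per_site = 2, seed = 1, noise = 1,
                             porewater_n = 5,
                             periods = default_periods(), max_depth = 37) {
  if (length(templates) < 2L) stop("generate_estuary: need >= 2 templates")
  cores <- list()
  for (tpl in templates) {
    for (k in seq_len(cores_per_site)) {
      cid <- sprintf("%s-%d", tpl$site_id, k)
      cores[[cid]] <- generate_core(tpl, cid, seed = seed,
                                    periods = periods,
                                    max_depth = max_depth, noise = noise)
    }
  }
  sites <- lapply(templates, function(tpl) {
    site_record(tpl$site_id, tpl$urban_index, tpl$x, tpl$y,
                tpl$species_composition, population = tpl$population)
  })
  names(sites) <- vapply(sites, `[[`, "", "site_id")
  pw <- do.call(rbind, lapply(templates, generate_porewater,
                              n = porewater_n, seed = seed, noise = noise))
  pops <- data.frame(
    unit = vapply(templates, `[[`, "", "site_id"),
    population = vapply(templates, `[[`, 0, "population"),
    area_ha = buffer_area(500), stringsAsFactors = FALSE)
  structure(list(cores = cores, sites = sites, porewater = pw,
                 populations = pops, grid = grid,
                 truth = ground_truth(templates, grid, periods, max_depth),
                 templates = templates, periods = periods, seed = seed),
            class = "estuary_bundle")
}

#' Write an estuary bundle to disk
#'
#' Writes the bundle through the package's tabular writers: core, SAR,
#' site, porewater and population CSVs, the mask cell centres, and the
#' ground truth as JSON.
#'
#' @param bundle An `estuary_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "estuary_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cores = file.path(dir, "cores.csv"),
    sar = file.path(dir, "sar.csv"),
    sites = file.path(dir, "sites.csv"),
    porewater = file.path(dir, "porewater.csv"),
    populations = file.path(dir, "populations.csv"),
    mask = file.path(dir, "mask.csv"),
    truth = file.path(dir, "ground_truth.json"))
  write_core_table(bundle$cores, paths[["cores"]])
  write_sar_table(bundle$cores, paths[["sar"]])
  write_site_table(bundle$sites, paths[["sites"]])
  write_porewater_table(bundle$porewater, paths[["porewater"]])
  utils::write.csv(bundle$populations, paths[["populations"]],
                   row.names = FALSE, quote = FALSE)
  mask <- bundle$grid$mask
  names(mask) <- c("x_m", "y_m")
  utils::write.csv(mask, paths[["mask"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sites = bundle$truth$sites,
         estuary = as.list(bundle$truth$estuary),
         cell_size = bundle$grid$cell_size, seed = bundle$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
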