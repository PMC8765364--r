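#' Nitrogen stock of core slices
#'
#' Stock per slice is the product of dry bulk density, slice thickness
#' and nitrogen mass fraction. With bulk density in g cm^-3, thickness in
#' cm and N as a fraction, the product is g N cm^-2, which converts to
#' Mg ha^-1 with a factor of 100 (10^8 cm^2 ha^-1 / 10^6 g Mg^-1).
#'
#' @param slices Slice table (rows of a `sediment_core$slices`), or a
#'   single-row data frame.
#' @return Numeric vector, Mg N ha^-1 per slice.
#' @export
slice_n_stock <- function(slices) {
  stopifnot(is.data.frame(slices))
  with(slices, bulk_density * (depth_bottom - depth_top) * n_fraction * 100)
}

#' Nitrogen stock of a core within a period
#'
#' Sums [slice_n_stock()] over the slices deposited in the period. The
#' stock of any partition of a core's slices adds up to the core's
#' stock, so the per-period stocks over the standard recent + historic
#' periods never double count.
#'
#' @param core A `sediment_core`.
#' @param period A `period_definition`.
#' @return Object of class `stock_result` with fields `value` (Mg ha^-1),
#'   `period`, `depth_range` (cm, `c(NA, NA)` when no slice qualifies)
#'   and `n_slices`.
#' @export
core_period_stock <- function(core, period) {
  s <- assign_period(core, period)
  structure(list(
    value = if (nrow(s)) sum(slice_n_stock(s)) else 0,
    period = period,
    depth_range = if (nrow(s)) c(min(s$depth_top), max(s$depth_bottom))
                  else c(NA_real_, NA_real_),
    n_slices = nrow(s)
  ), class = "stock_result")
}

#' @export
print.stock_result <- function(x, ...) {
  cat(sprintf("<stock> %.3f Mg ha-1 (%s, %s cm, %d slices)\n",
              x$value, x$period$name,
              if (is.na(x$depth_range[1L])) "-" else
                paste(x$depth_range, collapse = "-"),
              x$n_slices))
  invisible(x)
}

#' Nitrogen accumulation rate
#'
#' Accumulation = sediment accretion rate x dry bulk density x nitrogen
#' fraction. With SAR in mm y^-1 (0.1 cm y^-1) and bulk density in
#' g cm^-3 the product is g N cm^-2 y^-1 x 0.1, i.e. x 1000 in
#' g N m^-2 y^-1 (10^4 cm^2 m^-2). 100 g m^-2 y^-1 = 1 Mg ha^-1 y^-1.
#'
#' @param sar Sediment accretion rate, mm y^-1.
#' @param bulk_density Dry bulk density, g cm^-3.
#' @param n_fraction Nitrogen mass fraction (0--1).
#' @return g N m^-2 y^-1 (vectorized).
#' @examples
#' n_accumulation_rate(5.5, 0.35, 0.012)  # 23.1
#' @export
n_accumulation_rate <- function(sar, bulk_density, n_fraction) {
  if (any(sar < 0) || any(bulk_density < 0) || any(n_fraction < 0))
    stop("n_accumulation_rate: inputs must be non-negative")
  sar * bulk_density * n_fraction * 1000
}

#' Molar C:N ratio
#'
#' @param c_fraction Carbon mass fraction.
#' @param n_fraction Nitrogen mass fraction; must be > 0.
#' @return Dimensionless molar ratio, using atomic weights 12.011 (C)
#'   and 14.007 (N). Vectorized.
#' @export
molar_cn <- function(c_fraction, n_fraction) {
  if (any(n_fraction <= 0)) stop("molar_cn: n_fraction must be > 0")
  (c_fraction / 12.011) / (n_fraction / 14.007)
}

#' Normalize a period stock to an annual rate
#'
#' Divides a per-period stock by the period duration so that periods of
#' unequal length (46 vs 40 y for the standard recent/historic windows)
#' compare on a common Mg ha^-1 y^-1 scale.
#'
#' @param stock A `stock_result` (or a numeric value with `period`).
#' @param period Required when `stock` is plain numeric.
#' @return Mg ha^-1 y^-1.
#' @export
normalize_stock_rate <- function(stock, period = NULL) {
  if (inherits(stock, "stock_result")) {
    period <- stock$period
    stock <- stock$value
  }
  if (is.null(period)) stop("normalize_stock_rate: period required")
  if (period$duration_y <= 0) stop("normalize_stock_rate: zero-length period")
  stock / period$duration_y
}

#' Extrapolate a nitrogen depth profile to a target depth
#'
#' Observed N density (Mg ha^-1 per cm of depth) decays roughly
#' exponentially below the biologically active surface layers. The
#' profile is modelled as `ln(density) = a + b * depth` by least squares
#' on the observed points, and the cumulative stock at `target_depth` is
#' the observed stock down to the deepest point plus the analytic
#' integral of `exp(a + b z)` from there to the target.
#'
#' When `observed_stock` is not supplied it is approximated from the
#' profile itself: trapezoidal integration between the observed midpoints
#' plus a constant-density extension from the shallowest midpoint to the
#' surface.
#'
#' @param depth Depth midpoints, cm (>= 3 points).
#' @param density N density at each midpoint, Mg ha^-1 cm^-1; all > 0.
#' @param target_depth Target depth, cm; must be >= the deepest point.
#' @param observed_stock Optional cumulative stock (Mg ha^-1) down to the
#'   deepest observed point.
#' @return List with `cumulative` (Mg ha^-1 at target), `observed_stock`,
#'   `tail` (extrapolated addition), `coef` (a, b) and `decaying`
#'   (FALSE triggers a non-decaying-extrapolation warning).
#' @export
extrapolate_depth_profile <- function(depth, density, target_depth,
                                      observed_stock = NULL) {
  stopifnot(length(depth) == length(density))
  if (length(depth) < 3L) stop("extrapolate_depth_profile: need >= 3 points")
  if (any(density <= 0))
    stop("extrapolate_depth_profile: densities must be positive (log model)")
  o <- order(depth)
  depth <- depth[o]; density <- density[o]
  d_max <- depth[length(depth)]
  if (target_depth < d_max - 1e-9)
    stop("extrapolate_depth_profile: target_depth above deepest observation")
  fit <- stats::lm(log(density) ~ depth)
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  decaying <- b < 0
  if (!decaying)
    warning("extrapolate_depth_profile: non-decaying profile (b >= 0); ",
            "extrapolation grows with depth")
  if (is.null(observed_stock)) {
    trap <- sum(diff(depth) * (utils::head(density, -1L) +
                                 utils::tail(density, -1L)) / 2)
    observed_stock <- trap + density[1L] * depth[1L]
  }
  tail_int <- if (abs(b) < 1e-12) {
    exp(a) * (target_depth - d_max)
  } else {
    (exp(a) / b) * (exp(b * target_depth) - exp(b * d_max))
  }
  list(cumulative = observed_stock + tail_int,
       observed_stock = observed_stock,
       tail = tail_int, coef = c(a = a, b = b), decaying = decaying)
}

#' Per-core, per-period budget report
#'
#' Convenience table over a collection of cores: stock, normalized stock
#' rate, accumulation rate (from the core's period SAR and the period
#' mean bulk density and N fraction) and mean molar C:N per period.
#'
#' @param cores List of `sediment_core` objects.
#' @param periods Named list of `period_definition`s
#'   (default [default_periods()]).
#' @return Data frame `site_id,core_id,period,n_slices,stock_mg_ha,`
#'   `stock_rate_mg_ha_y,accum_g_m2_y,cn_molar_mean`.
#' @export
budget_report <- function(cores, periods = default_periods()) {
  rows <- list()
  for (co in cores) {
    for (pd in periods) {
      st <- core_period_stock(co, pd)
      s <- assign_period(co, pd)
      sar <- if (!is.null(co$sar_by_period) &&
                 pd$name %in% names(co$sar_by_period))
        unname(co$sar_by_period[[pd$name]]) else NA_real_
      accum <- if (nrow(s) && !is.na(sar))
        n_accumulation_rate(sar, mean(s$bulk_density), mean(s$n_fraction))
      else NA_real_
      cn <- if (nrow(s) && all(s$n_fraction > 0))
        mean(molar_cn(s$c_fraction, s$n_fraction)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = co$site_id, core_id = co$core_id, period = pd$name,
        n_slices = st$n_slices, stock_mg_ha = st$value,
        stock_rate_mg_ha_y = normalize_stock_rate(st),
        accum_g_m2_y = accum, cn_molar_mean = cn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
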