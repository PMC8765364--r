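#' Define an interpolation grid over a mangrove mask
#'
#' @param mask Data frame of mangrove cell centres with columns `x`, `y`
#'   in metres.
#' @param cell_size Cell edge length in metres (default 2, the native
#'   resolution of the coastal land-cover mask; coarser cells are a
#'   config choice for desk-scale runs).
#' @return Object of class `grid_spec` with `total_area_ha` implied by
#'   the mask (`n_cells * cell_size^2 / 1e4`).
#' @export
grid_spec <- function(mask, cell_size = 2) {
  stopifnot(is.data.frame(mask), all(c("x", "y") %in% names(mask)),
            cell_size > 0)
  structure(list(mask = mask[, c("x", "y")], cell_size = cell_size,
                 total_area_ha = nrow(mask) * cell_size^2 / 1e4),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid> %d cells of %g m (%.1f ha)\n",
              nrow(x$mask), x$cell_size, x$total_area_ha))
  invisible(x)
}

#' Rectangular and elliptical synthetic masks
#'
#' Helpers that build simple mangrove masks for simulation: a rectangle
#' of `nx` by `ny` cells, or an ellipse inscribed in that rectangle
#' (cells whose centres fall inside the ellipse).
#'
#' @param nx,ny Cells per side.
#' @param cell_size Cell edge, metres.
#' @param shape `"rectangle"` or `"ellipse"`.
#' @return A `grid_spec`.
#' @export
make_mask <- function(nx, ny, cell_size = 20,
                      shape = c("rectangle", "ellipse")) {
  shape <- match.arg(shape)
  cx <- (seq_len(nx) - 0.5) * cell_size
  cy <- (seq_len(ny) - 0.5) * cell_size
  g <- expand.grid(x = cx, y = cy)
  if (shape == "ellipse") {
    a <- nx * cell_size / 2; b <- ny * cell_size / 2
    keep <- ((g$x - a) / a)^2 + ((g$y - b) / b)^2 <= 1
    g <- g[keep, , drop = FALSE]
  }
  grid_spec(g, cell_size)
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates site values to query points as a weighted mean with
#' weights `d^-power`: every known value contributes, but geographically
#' close values dominate. A query within 1e-9 m of a known point returns
#' that point's value exactly, and every interpolated value lies within
#' the range of the known values (convex combination).
#'
#' @param known Data frame with columns `x`, `y`, `value`.
#' @param query Data frame with columns `x`, `y` (any number of rows).
#' @param power Distance-decay exponent (default 2).
#' @return Numeric vector of interpolated values, one per query row.
#' @export
idw_interpolate <- function(known, query, power = 2) {
  stopifnot(is.data.frame(known), all(c("x", "y", "value") %in% names(known)))
  if (!nrow(known)) stop("idw_interpolate: no known points")
  dx <- outer(query$x, known$x, "-")
  dy <- outer(query$y, known$y, "-")
  d <- sqrt(dx * dx + dy * dy)
  hit <- d < 1e-9
  w <- d^(-power)
  w[hit] <- Inf
  out <- numeric(nrow(query))
  exact <- rowSums(hit) > 0
  if (any(exact)) {
    out[exact] <- known$value[apply(hit[exact, , drop = FALSE], 1L,
                                    which.max)]
  }
  if (any(!exact)) {
    wn <- w[!exact, , drop = FALSE]
    out[!exact] <- as.vector(wn %*% known$value) / rowSums(wn)
  }
  out
}

#' Describe a site's value distribution for stochastic upscaling
#'
#' @param site_id Label.
#' @param mean,sd Target moments (same units as the upscaled quantity,
#'   e.g. Mg ha^-1); `sd >= 0`.
#' @param skew Right-skew shape parameter (>1 right-skewed, 1 = normal).
#' @return Object of class `site_value_distribution`.
#' @export
site_value_distribution <- function(site_id, mean, sd, skew = 1.5) {
  if (sd < 0) stop("site_value_distribution: sd must be >= 0")
  if (skew <= 0) stop("site_value_distribution: skew must be > 0")
  structure(list(site_id = as.character(site_id), mean = mean, sd = sd,
                 skew = skew),
            class = "site_value_distribution")
}

# Moments of the unit two-piece (Fernandez-Steel) skew normal with
# shape xi: mean m1 and sd s1 of the un-standardized variate.
.twopiece_moments <- function(xi) {
  m1 <- sqrt(2 / pi) * (xi - 1 / xi)
  m2 <- xi^2 - 1 + 1 / xi^2
  c(m1 = m1, s1 = sqrt(m2 - m1^2))
}

#' Draw from a right-skewed normal distribution
#'
#' Two-piece (Fernandez-Steel) skew normal with shape `skew`,
#' re-centred and rescaled so the population mean and sd equal the
#' requested moments; `skew = 1` reduces exactly to the normal
#' distribution. Used to mimic the right-skewed within-site value
#' distributions of core measurements.
#'
#' Negative draws are unphysical for stocks and rates, so by default
#' draws are truncated at zero by resampling. When truncation moves the
#' population mean by more than 1% of the target the draws are re-centred
#' by the bias (and a message reports it); smaller biases are left alone.
#'
#' @param n Number of draws.
#' @param mean,sd Target moments of the untruncated distribution.
#' @param skew Shape (> 0), default 1.5.
#' @param truncate Truncate at zero (default TRUE).
#' @param seed Optional seed.
#' @return Numeric vector of length `n`.
#' @export
draw_skew_normal <- function(n, mean, sd, skew = 1.5, truncate = TRUE,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  if (skew <= 0) stop("draw_skew_normal: skew must be > 0")
  mom <- .twopiece_moments(skew)
  draw_raw <- function(k) {
    pos <- stats::runif(k) < skew^2 / (1 + skew^2)
    z <- abs(stats::rnorm(k))
    x <- ifelse(pos, z * skew, -z / skew)
    mean + sd * (x - mom["m1"]) / mom["s1"]
  }
  out <- draw_raw(n)
  if (truncate && any(out < 0)) {
    # resample the negative tail (truncation at 0)
    for (i in 1:100) {
      neg <- out < 0
      if (!any(neg)) break
      out[neg] <- draw_raw(sum(neg))
    }
    out[out < 0] <- 0
    bias <- .truncation_bias(mean, sd, skew)
    if (is.finite(bias) && abs(bias) > 0.01 * abs(mean)) {
      message(sprintf(
        "draw_skew_normal: truncation bias %.3g corrected (mean %.3g)",
        bias, mean))
      out <- pmax(out - bias, 0)
    }
  }
  out
}

# Mean shift caused by truncating the re-moment-matched two-piece skew
# normal at zero: E[X | X > 0] - mean, by numeric integration.
.truncation_bias <- function(mean, sd, skew) {
  mom <- .twopiece_moments(skew)
  # density of the standardized-then-scaled variate
  dens <- function(v) {
    x <- (v - mean) / sd * mom["s1"] + mom["m1"]
    core <- ifelse(x >= 0, stats::dnorm(x / skew), stats::dnorm(x * skew))
    (2 / (skew + 1 / skew)) * core * mom["s1"] / sd
  }
  p0 <- tryCatch(stats::integrate(dens, 0, Inf)$value, error = function(e) NA)
  if (!is.finite(p0) || p0 <= 0) return(0)
  if (p0 > 1 - 1e-9) return(0)
  ex <- stats::integrate(function(v) v * dens(v), 0, Inf)$value
  ex / p0 - mean
}

#' One stochastic estuary-wide total
#'
#' Draws a single value per site from its skew-normal distribution,
#' interpolates the drawn values to every mangrove mask cell by IDW,
#' converts the per-area values (Mg ha^-1) to per-cell mass via the cell
#' area, and sums over the mask.
#'
#' @param dists List of `site_value_distribution`s (or a data frame with
#'   `site_id, mean, sd, skew`).
#' @param sites Data frame `site_id, x, y` of site locations (or a list
#'   of `site_record`s).
#' @param grid A `grid_spec`.
#' @param power IDW exponent (default 2).
#' @param seed Optional seed.
#' @return Estuary-wide total (Mg, or Mg y^-1 for rates).
#' @export
estuary_iteration <- function(dists, sites, grid, power = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dd <- .dist_frame(dists)
  ss <- .site_frame(sites)
  missing_loc <- setdiff(dd$site_id, ss$site_id)
  if (length(missing_loc))
    stop("estuary_iteration: no location for site(s): ",
         paste(missing_loc, collapse = ", "))
  ss <- ss[match(dd$site_id, ss$site_id), , drop = FALSE]
  vals <- mapply(function(m, s, k) draw_skew_normal(1L, m, s, k),
                 dd$mean, dd$sd, dd$skew)
  known <- data.frame(x = ss$x, y = ss$y, value = vals)
  cell_vals <- idw_interpolate(known, grid$mask, power = power)
  sum(cell_vals) * grid$cell_size^2 / 1e4
}

.dist_frame <- function(dists) {
  if (is.data.frame(dists)) {
    if (is.null(dists$skew)) dists$skew <- 1.5
    return(dists[, c("site_id", "mean", "sd", "skew")])
  }
  do.call(rbind, lapply(dists, function(d) {
    data.frame(site_id = d$site_id, mean = d$mean, sd = d$sd, skew = d$skew,
               stringsAsFactors = FALSE)
  }))
}

.site_frame <- function(sites) {
  if (is.data.frame(sites)) return(sites)
  do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, x = s$x, y = s$y,
               stringsAsFactors = FALSE)
  }))
}

#' Monte-Carlo estuary-wide estimate
#'
#' Repeats [estuary_iteration()] `n_iterations` times (default 100) and
#' reports the mean and standard error of the iteration totals, plus the
#' areal mean (total over mask area).
#'
#' @inheritParams estuary_iteration
#' @param n_iterations Number of iterations (>= 2; SE undefined below).
#' @param seed Run seed (each iteration uses a derived substream).
#' @return Object of class `estuary_estimate`: `total_mean`, `total_se`,
#'   `areal_mean`, `n_iterations`, `area_ha`, `totals`.
#' @export
estuary_estimate <- function(dists, sites, grid, n_iterations = 100,
                             power = 2, seed = 1) {
  if (n_iterations < 2) stop("estuary_estimate: n_iterations must be >= 2")
  totals <- vapply(seq_len(n_iterations), function(i) {
    estuary_iteration(dists, sites, grid, power = power,
                      seed = substream_seed(seed, paste0("iter", i)))
  }, numeric(1L))
  structure(list(total_mean = mean(totals),
                 total_se = stats::sd(totals) / sqrt(n_iterations),
                 areal_mean = mean(totals) / grid$total_area_ha,
                 n_iterations = n_iterations,
                 area_ha = grid$total_area_ha,
                 totals = totals),
            class = "estuary_estimate")
}

#' @export
print.estuary_estimate <- function(x, ...) {
  cat(sprintf(
    "<estuary> total %.1f +/- %.2f Mg (%.3f Mg ha-1 over %.0f ha, %d iter)\n",
    x$total_mean, x$total_se, x$areal_mean, x$area_ha, x$n_iterations))
  invisible(x)
}

#' Default aboveground N content per species
#'
#' Mass fractions of N in aboveground biomass: *Avicennia germinans*
#' 0.26%, *Laguncularia racemosa* 0.157%, *Rhizophora mangle* 0.205%,
#' and 0.31% for non-mangrove species.
#'
#' @return Named numeric vector of mass fractions.
#' @export
default_species_n <- function() {
  c(A_germinans = 0.0026, L_racemosa = 0.00157, R_mangle = 0.00205,
    other = 0.0031)
}

#' Aboveground nitrogen stock of a mangrove stand
#'
#' Weighted mean of species N content by biomass proportion, times the
#' stand biomass: `biomass * sum(proportion * n_fraction)`. Species
#' missing from `species_n` fall back to the `"other"` (non-mangrove)
#' content.
#'
#' @param composition Named biomass proportions (must sum to 1 +/- 1e-6).
#' @param biomass Stand aboveground biomass, Mg ha^-1.
#' @param species_n Named N mass fractions (default
#'   [default_species_n()]).
#' @return Aboveground N stock, Mg ha^-1.
#' @export
aboveground_n_stock <- function(composition, biomass,
                                species_n = default_species_n()) {
  if (is.null(names(composition)) || abs(sum(composition) - 1) > 1e-6)
    stop("aboveground_n_stock: composition must be named and sum to 1")
  nf <- species_n[names(composition)]
  nf[is.na(nf)] <- species_n[["other"]]
  biomass * sum(composition * nf)
}
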