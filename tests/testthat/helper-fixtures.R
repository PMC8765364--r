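# Shared fixtures built in code.

# A two-slice core with round numbers, handy for stock arithmetic.
tiny_core <- function(sar = c(recent = 2, historic = 1.5)) {
  sediment_core("c1", "s1", data.frame(
    depth_top = c(0, 1), depth_bottom = c(1, 3),
    mid_date = c(2010, 1990),
    bulk_density = c(0.5, 0.5),
    n_fraction = c(0.01, 0.01),
    c_fraction = c(0.2, 0.2),
    d15n = c(4, 4), d34s = c(NA, NA)
  ), sar_by_period = sar)
}

# A core whose slices span both standard periods with known per-slice
# values, for column-sum oracles.
dated_core <- function() {
  sediment_core("c2", "s1", data.frame(
    depth_top = c(0, 2, 4, 6, 8),
    depth_bottom = c(2, 4, 6, 8, 10),
    mid_date = c(2005, 1985, 1970, 1955, 1935),
    bulk_density = c(0.3, 0.4, 0.5, 0.6, 0.7),
    n_fraction = c(0.012, 0.010, 0.008, 0.006, 0.004),
    c_fraction = c(0.24, 0.20, 0.16, 0.12, 0.08),
    d15n = c(5, 5, 4, 4, 4), d34s = NA_real_
  ), sar_by_period = c(recent = 3, historic = 2.5))
}

# Small estuary setup for fast pipeline tests: three contrasting sites
# on a coarse rectangular mask.
small_templates <- function() default_site_templates()[c("MPW", "MPE", "SJ")]

small_grid <- function() make_mask(30, 10, cell_size = 40,
                                   shape = "rectangle")

# Balanced synthetic porewater fixture: n per cell, lognormal noise, one
# site optionally shifted on the ln scale.
porewater_fixture <- function(n = 10, shift_site = NULL, shift = 0,
                              seed = 42, season_effect = 0) {
  set.seed(seed)
  sites <- c("A", "B", "C")
  base <- c(A = log(20), B = log(20), C = log(20))
  rows <- list()
  for (s in sites) {
    for (season in c("wet", "dry")) {
      mu <- base[[s]] + if (identical(s, shift_site)) shift else 0
      mu <- mu + if (season == "dry") season_effect else 0
      val <- exp(stats::rnorm(n, mu, 0.3))
      rows[[paste(s, season)]] <- data.frame(
        site_id = s, season = season,
        nh4_um = val, nox_um = 0.3, nox_detected = TRUE,
        po4_um = exp(stats::rnorm(n, log(5), 0.3)),
        salinity_psu = NA_real_, ph = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
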