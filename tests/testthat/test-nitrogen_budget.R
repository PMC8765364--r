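test_that("slice stock arithmetic follows bulk density x thickness x fraction", {
  s <- data.frame(depth_top = 0, depth_bottom = 28, mid_date = 2000,
                  bulk_density = 0.5, n_fraction = 0.005, c_fraction = 0.1,
                  d15n = NA_real_, d34s = NA_real_)
  expect_equal(slice_n_stock(s), 7.0)
  s$n_fraction <- 0
  expect_equal(slice_n_stock(s), 0)
  s2 <- data.frame(depth_top = 0, depth_bottom = 18, mid_date = 2000,
                   bulk_density = 0.2, n_fraction = 0.0124,
                   c_fraction = 0.1, d15n = NA, d34s = NA)
  expect_equal(slice_n_stock(s2), 4.464)
})

test_that("core period stock sums member slices and reports depth range", {
  pds <- default_periods()
  st <- core_period_stock(tiny_core(), pds$recent)
  expect_equal(st$value, 0.5 * 1 * 0.01 * 100 + 0.5 * 2 * 0.01 * 100)
  expect_equal(st$depth_range, c(0, 3))

  empty <- core_period_stock(tiny_core(), pds$historic)
  expect_equal(empty$value, 0)
  expect_true(all(is.na(empty$depth_range)))

  # column-sum oracle on a core with known per-slice values
  co <- dated_core()
  r <- assign_period(co, pds$recent)
  oracle <- sum(r$bulk_density * (r$depth_bottom - r$depth_top) *
                  r$n_fraction * 100)
  expect_equal(core_period_stock(co, pds$recent)$value, oracle)
})

test_that("stock is additive over any partition of a core's slices", {
  co <- generate_core(default_site_templates()$MPE, "add", seed = 11)
  per_slice <- slice_n_stock(co$slices)
  pds <- default_periods()
  total_by_period <- core_period_stock(co, pds$recent)$value +
    core_period_stock(co, pds$historic)$value
  in_periods <- co$slices$mid_date >= 1930 & co$slices$mid_date < 2016
  expect_equal(total_by_period, sum(per_slice[in_periods]))
  expect_equal(sum(per_slice), sum(per_slice[1:7]) + sum(per_slice[-(1:7)]))
})

test_that("accumulation rate formula and units are coherent with stocks", {
  expect_equal(n_accumulation_rate(5.5, 0.35, 0.012), 23.1)
  expect_equal(n_accumulation_rate(0, 0.5, 0.01), 0)
  expect_equal(n_accumulation_rate(2.0, 0.5, 0.01), 10.0)
  expect_error(n_accumulation_rate(-1, 0.5, 0.01), "non-negative")

  # one year of deposition at the SAR makes a sar/10-cm slice whose
  # stock (Mg/ha) equals the accumulation rate in Mg/ha/y
  sar <- 3.7; bd <- 0.44; fn <- 0.0081
  slice <- data.frame(depth_top = 0, depth_bottom = sar / 10,
                      mid_date = 2015, bulk_density = bd, n_fraction = fn,
                      c_fraction = 0.1, d15n = NA, d34s = NA)
  expect_equal(n_accumulation_rate(sar, bd, fn) / 100,
               slice_n_stock(slice), tolerance = 1e-9)
})

test_that("molar C:N uses atomic weights 12.011 and 14.007", {
  expect_equal(molar_cn(0.312, 0.0097), 37.6, tolerance = 0.15)
  expect_equal(molar_cn(0.12011, 0.14007), 1.0)
  expect_equal(molar_cn(0.10, 0.01), 11.66, tolerance = 0.01)
  expect_error(molar_cn(0.1, 0), "n_fraction")
})

test_that("stock normalization divides by period duration", {
  pds <- default_periods()
  expect_equal(normalize_stock_rate(7.1, pds$recent), 7.1 / 46,
               tolerance = 1e-12)
  expect_equal(normalize_stock_rate(2.3, pds$historic), 0.0575)
  st <- core_period_stock(tiny_core(), pds$historic)
  expect_equal(normalize_stock_rate(st), 0)
  expect_error(normalize_stock_rate(1), "period")
})

test_that("depth extrapolation integrates the fitted exponential decay", {
  # exact samples of exp(1 - 0.02 d): tail integral matches closed form
  d <- seq(1, 37, by = 2)
  dens <- exp(1 - 0.02 * d)
  res <- extrapolate_depth_profile(d, dens, 100)
  expect_equal(unname(res$coef["a"]), 1, tolerance = 1e-9)
  expect_equal(unname(res$coef["b"]), -0.02, tolerance = 1e-9)
  analytic <- (exp(1) / 0.02) * (exp(-0.02 * 37) - exp(-0.02 * 100))
  expect_equal(res$tail, analytic, tolerance = 1e-6)

  # constant density: cumulative stock doubles from 50 to 100 cm
  dc <- c(5, 15, 25)
  suppressWarnings({
    s50 <- extrapolate_depth_profile(dc, rep(0.1, 3), 50)$cumulative
    s100 <- extrapolate_depth_profile(dc, rep(0.1, 3), 100)$cumulative
  })
  expect_equal(s100, 2 * s50, tolerance = 1e-9)

  # identity at the deepest observation
  res0 <- extrapolate_depth_profile(d, dens, 37)
  expect_equal(res0$cumulative, res0$observed_stock, tolerance = 1e-9)
})

test_that("extrapolation guards its domain and is monotone in depth", {
  d <- seq(1, 21, by = 2)
  dens <- exp(0.5 - 0.05 * d)
  expect_error(extrapolate_depth_profile(d, c(dens[-1], -1), 50), "positive")
  expect_error(extrapolate_depth_profile(d[1:2], dens[1:2], 50), ">= 3")
  expect_error(extrapolate_depth_profile(d, dens, 10), "target_depth")
  expect_warning(extrapolate_depth_profile(d, exp(0.1 + 0.02 * d), 50),
                 "non-decaying")
  targets <- seq(21, 120, by = 10)
  cums <- vapply(targets, function(t)
    extrapolate_depth_profile(d, dens, t)$cumulative, numeric(1L))
  expect_true(all(diff(cums) >= 0))
})

test_that("budget report combines stocks, rates and C:N per core-period", {
  rep <- budget_report(list(dated_core()))
  expect_equal(nrow(rep), 2L)
  r <- rep[rep$period == "recent", ]
  expect_equal(r$stock_mg_ha,
               core_period_stock(dated_core(), default_periods()$recent)$value)
  # slices dated 2005, 1985 and 1970 fall in the recent window
  expect_equal(r$accum_g_m2_y,
               n_accumulation_rate(3, mean(c(0.3, 0.4, 0.5)),
                                   mean(c(0.012, 0.010, 0.008))))
  expect_equal(r$stock_rate_mg_ha_y, r$stock_mg_ha / 46)
})
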