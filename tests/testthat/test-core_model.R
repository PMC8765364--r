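test_that("core tables read with percent-to-fraction conversion and grouping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "core_id,site_id,depth_top_cm,depth_bottom_cm,mid_date,bulk_density_gcm3,percent_n,percent_c,d15n_permil,d34s_permil",
    "c1,s1,0,1,2010,0.5,1.24,20,4.5,",
    "c1,s1,1,3,1995,0.6,0.8,15,4.0,"
  ), path)
  cores <- read_core_table(path)
  expect_length(cores, 1L)
  co <- cores[["c1"]]
  expect_s3_class(co, "sediment_core")
  expect_equal(nrow(co$slices), 2L)
  expect_equal(co$slices$depth_top, c(0, 1))          # depth-ordered
  expect_equal(co$slices$n_fraction[1L], 0.0124)      # 1.24 %N
  expect_equal(co$slices$c_fraction[2L], 0.15)
})

test_that("schema and validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("core_id,site_id,depth_top_cm", "c1,s1,0"), path)
  expect_error(read_core_table(path), "missing column")

  overlapping <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "core_id,site_id,depth_top_cm,depth_bottom_cm,mid_date,bulk_density_gcm3,percent_n,percent_c",
    "cX,s1,0,1,2010,0.5,1.0,10",
    "cX,s1,0.5,2,2000,0.5,1.0,10"
  ), overlapping)
  expect_error(read_core_table(overlapping), "cX.*overlapping")
})

test_that("unparseable rows are dropped with their file line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "core_id,site_id,depth_top_cm,depth_bottom_cm,mid_date,bulk_density_gcm3,percent_n,percent_c",
    "c1,s1,0,1,2010,0.5,1.0,10",
    "c1,s1,1,3,oops,0.5,1.0,10"
  ), path)
  expect_warning(cores <- read_core_table(path), "line\\(s\\) 3")
  expect_equal(nrow(cores[["c1"]]$slices), 1L)
})

test_that("write/read round trip preserves numeric fields", {
  co <- generate_core(default_site_templates()$Pin, "Pin-1", seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_core_table(co, path)
  back <- read_core_table(path)[["Pin-1"]]
  for (col in c("depth_top", "depth_bottom", "mid_date", "bulk_density",
                "n_fraction", "c_fraction", "d15n", "d34s")) {
    expect_equal(back$slices[[col]], co$slices[[col]], tolerance = 1e-12)
  }
})

test_that("slice invariants are enforced", {
  base <- data.frame(depth_top = 0, depth_bottom = 1, mid_date = 2000,
                     bulk_density = 0.5, n_fraction = 0.01,
                     c_fraction = 0.2, d15n = NA_real_, d34s = NA_real_)
  bad_bd <- base; bad_bd$bulk_density <- 3
  expect_error(sediment_core("c", "s", bad_bd), "bulk density")
  bad_n <- base; bad_n$n_fraction <- 0.2
  expect_error(sediment_core("c", "s", bad_n), "n_fraction")
  inverted <- base; inverted$depth_bottom <- -1
  expect_error(sediment_core("c", "s", inverted), "thickness")
  expect_error(sediment_core("c", "s", base, sar_by_period = c(recent = 25)),
               "SAR")
  dating <- rbind(base, transform(base, depth_top = 1, depth_bottom = 2,
                                  mid_date = 2010))
  expect_error(sediment_core("c", "s", dating), "mid_date")
})

test_that("assign_period filters on half-open date windows", {
  pds <- default_periods()
  co <- sediment_core("c", "s", data.frame(
    depth_top = 0:2, depth_bottom = 1:3, mid_date = c(2000, 1980, 1950),
    bulk_density = 0.5, n_fraction = 0.01, c_fraction = 0.1,
    d15n = NA_real_, d34s = NA_real_))
  expect_equal(assign_period(co, pds$recent)$mid_date, c(2000, 1980))
  expect_equal(assign_period(co, pds$historic)$mid_date, 1950)

  boundary <- sediment_core("c", "s", data.frame(
    depth_top = 0, depth_bottom = 1, mid_date = 1970,
    bulk_density = 0.5, n_fraction = 0.01, c_fraction = 0.1,
    d15n = NA_real_, d34s = NA_real_))
  expect_equal(nrow(assign_period(boundary, pds$recent)), 1L)
  expect_equal(nrow(assign_period(boundary, pds$historic)), 0L)

  old <- sediment_core("c", "s", data.frame(
    depth_top = 0, depth_bottom = 1, mid_date = 1900,
    bulk_density = 0.5, n_fraction = 0.01, c_fraction = 0.1,
    d15n = NA_real_, d34s = NA_real_))
  expect_equal(nrow(assign_period(old, pds$recent)), 0L)
  expect_equal(nrow(assign_period(old, pds$historic)), 0L)
})

test_that("the two standard periods partition 1930-2016 slices", {
  pds <- default_periods()
  for (seed in 1:5) {
    co <- generate_core(default_site_templates()$Torr,
                        paste0("t", seed), seed = seed)
    r <- assign_period(co, pds$recent)
    h <- assign_period(co, pds$historic)
    expect_length(intersect(r$depth_top, h$depth_top), 0L)
    in_window <- co$slices$mid_date >= 1930 & co$slices$mid_date < 2016
    expect_equal(nrow(r) + nrow(h), sum(in_window))
  }
})

test_that("period_definition validates its window", {
  expect_error(period_definition("bad", 2000, 1990), "start_year")
  p <- period_definition("recent", 1970, 2016)
  expect_equal(p$duration_y, 46)
})

test_that("site and porewater tables round trip", {
  sites <- list(site_record("s1", 10, 100, 200,
                            c(A_germinans = 0.4, R_mangle = 0.6),
                            population = 1000))
  names(sites) <- "s1"
  path <- withr::local_tempfile(fileext = ".csv")
  write_site_table(sites, path)
  back <- read_site_table(path)
  expect_equal(back$s1$species_composition, sites$s1$species_composition)
  expect_equal(back$s1$population, 1000)

  expect_error(site_record("s", 10, 0, 0, c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(site_record("s", 0, 0, 0, c(a = 1)), "urban_index")

  pw <- generate_porewater(default_site_templates()$MPW, n = 3, seed = 1)
  pw_path <- withr::local_tempfile(fileext = ".csv")
  write_porewater_table(pw, pw_path)
  back_pw <- read_porewater_table(pw_path)
  expect_equal(back_pw$nh4_um, pw$nh4_um, tolerance = 1e-6)
  expect_equal(back_pw$nox_detected, pw$nox_detected)
})
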