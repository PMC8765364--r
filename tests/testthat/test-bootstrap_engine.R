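test_that("bootstrap of a constant sample is degenerate and deterministic", {
  e <- bootstrap_mean(rep(3.2, 10), n_boot = 200, seed = 1)
  expect_equal(e$mean, 3.2)
  expect_equal(c(e$lower, e$upper), c(3.2, 3.2))
  expect_equal(e$n_boot, 200L)

  c1 <- bootstrap_mean(1:15, n_boot = 500, seed = 7)
  c2 <- bootstrap_mean(1:15, n_boot = 500, seed = 7)
  expect_identical(c1, c2)
})

test_that("replicate means converge to the sample mean (binomial oracle)", {
  e <- bootstrap_mean(c(0, 1), n_boot = 1e5, seed = 5)
  # each replicate is the mean of 2 Bernoulli(1/2): se = 0.5/sqrt(2e5)
  expect_lt(abs(e$mean - 0.5), 3 * 0.5 / sqrt(2e5))
  expect_true(e$lower <= e$mean && e$mean <= e$upper)
  expect_error(bootstrap_mean(numeric(0)), "empty")
})

test_that("derived bootstrap pairs ingredients randomly and independently", {
  d <- bootstrap_derived(2, 0.5, 0.01, "accumulation", n_boot = 100, seed = 1)
  expect_equal(d$mean, 10)
  expect_equal(c(d$lower, d$upper), c(10, 10))

  # independence: E[replicate] = product of sample means x 1000
  sar <- c(1, 3); bd <- c(0.2, 0.6); fn <- c(0.005, 0.015)
  big <- bootstrap_derived(sar, bd, fn, "accumulation",
                           n_boot = 4e4, seed = 2)
  expect_equal(big$mean, mean(sar) * mean(bd) * mean(fn) * 1000,
               tolerance = 0.03)

  r1 <- bootstrap_derived(sar, bd, fn, "accumulation", n_boot = 500, seed = 3)
  r2 <- bootstrap_derived(sar, bd, fn, "accumulation", n_boot = 500, seed = 3)
  expect_identical(r1, r2)

  st <- bootstrap_derived(2, 0.5, 0.01, "stock", thickness_cm = 10,
                          n_boot = 50, seed = 1)
  expect_equal(st$mean, 0.5 * 10 * 0.01 * 100)
  expect_error(bootstrap_derived(numeric(0), bd, fn, "accumulation"),
               "non-empty")
  expect_error(bootstrap_derived(sar, bd, fn, "stock"), "thickness")
})

test_that("pooling concatenates replicates; bounds widen when cores disagree", {
  e <- bootstrap_mean(rnorm(10, 5), n_boot = 1000, seed = 4)
  pooled_same <- pool_site(e, e)
  expect_equal(pooled_same$mean, e$mean)
  expect_equal(pooled_same$n_boot, 2000L)
  expect_equal(pool_site(list(e))$mean, e$mean)
  expect_equal(pool_site(list(e))$lower, e$lower)

  a <- mangroveN:::new_boot_estimate(as.numeric(1:1000))
  b <- mangroveN:::new_boot_estimate(as.numeric(2001:3000))
  p <- pool_site(a, b)
  expect_lt(p$lower, min(a$upper, b$lower))
  expect_gt(p$upper, a$upper)
  expect_true(p$lower < a$lower + 100 && p$upper > b$upper - 100)

  bad <- a; bad$replicate_values <- NULL
  expect_error(pool_site(a, bad), "replicate_values")
})

test_that("overlap comparison uses closed intervals", {
  # half the replicates at each endpoint puts the percentile bounds
  # exactly at [lo, hi]
  mk <- function(lo, hi) mangroveN:::new_boot_estimate(c(rep(lo, 500),
                                                         rep(hi, 500)))
  expect_equal(compare_estimates(mk(1, 2), mk(3, 4)), "significant")
  expect_equal(compare_estimates(mk(1, 3), mk(2, 4)), "not_significant")
  expect_equal(compare_estimates(mk(1, 2), mk(2, 3)), "not_significant")
})

test_that("percentile bounds are ordered for arbitrary samples", {
  set.seed(31)
  for (i in 1:20) {
    x <- rexp(sample(3:30, 1)) * sample(c(1, -1, 10), 1)
    e <- bootstrap_mean(x, n_boot = 300)
    expect_true(e$lower <= e$mean + 1e-12 && e$mean <= e$upper + 1e-12)
  }
})

test_that("pooled site intervals recover the true accumulation rate", {
  tpl <- default_site_templates()$Torr
  truth <- n_accumulation_rate(tpl$recent$sar, tpl$recent$bd_mean,
                               tpl$recent$n_mean)
  pds <- default_periods()
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    ests <- lapply(1:2, function(k) {
      co <- generate_core(tpl, sprintf("rec-%d-%d", i, k), seed = 1000 + i)
      s <- assign_period(co, pds$recent)
      bootstrap_derived(tpl$recent$sar, s$bulk_density, s$n_fraction,
                        "accumulation", n_boot = 300,
                        seed = 2000 + i * 2 + k)
    })
    p <- pool_site(ests)
    if (p$lower <= truth && truth <= p$upper) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("bootstrap_cores tabulates per core, period and quantity", {
  cores <- list(`c2` = dated_core())
  out <- bootstrap_cores(cores, n_boot = 200, seed = 5)
  tab <- out$table
  expect_setequal(unique(tab$period), c("recent", "historic"))
  expect_true(all(c("n_fraction", "bulk_density", "d15n", "accumulation",
                    "stock") %in% tab$quantity))
  expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))
  again <- bootstrap_cores(cores, n_boot = 200, seed = 5)
  expect_identical(out$table, again$table)
})
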