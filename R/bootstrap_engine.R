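# Deterministic substream seed from a run seed and a label, so that the
# result for one core never depends on how many cores were processed
# before it. Kept below 2^31 - 1.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             (31 ^ (seq_along(utf8ToInt(as.character(label))) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

new_boot_estimate <- function(replicates) {
  q <- unname(stats::quantile(replicates, c(0.025, 0.975), type = 7))
  structure(list(mean = mean(replicates),
                 lower = q[1L], upper = q[2L],
                 n_boot = length(replicates),
                 replicate_values = replicates),
            class = "boot_estimate")
}

#' @export
print.boot_estimate <- function(x, ...) {
  cat(sprintf("<bootstrap> mean %.4g [%.4g, %.4g] (B = %d)\n",
              x$mean, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Percentile bootstrap of a sample mean
#'
#' Draws `n_boot` with-replacement resamples of the sample (each of the
#' original size), takes the mean of each, and reports the mean of the
#' replicate means with the empirical 2.5th and 97.5th percentiles as the
#' 95% confidence bounds. Percentiles use linear interpolation between
#' order statistics (quantile type 7). Replicate values are retained so
#' estimates from replicate cores can later be pooled.
#'
#' @param values Non-empty numeric sample.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed; identical seeds give identical
#'   estimates.
#' @return Object of class `boot_estimate` with fields `mean`, `lower`,
#'   `upper`, `n_boot`, `replicate_values`.
#' @export
bootstrap_mean <- function(values, n_boot = 1000, seed = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("bootstrap_mean: empty sample")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  reps <- colMeans(matrix(values[idx], nrow = n))
  new_boot_estimate(reps)
}

#' Bootstrap of a derived quantity by random pairing
#'
#' Propagates the uncertainty of a product-form quantity (N accumulation
#' rate or N stock) by randomly pairing its ingredients: each replicate
#' draws one accretion rate, one bulk density and one N fraction
#' independently and uniformly from the respective samples of the same
#' core and period -- not necessarily from the same depth -- and applies
#' the budget formula. Not forcing the three values to share a depth
#' folds depth/temporal mismatch between the measurements into the
#' interval. The default replicate statistic is that single derived
#' value; `draws_per_replicate > 1` instead averages that many derived
#' values per replicate (a tighter alternative, not the default).
#'
#' @param sar_values SAR sample, mm y^-1.
#' @param bd_values Bulk density sample, g cm^-3.
#' @param fn_values N mass-fraction sample.
#' @param statistic `"accumulation"` (g m^-2 y^-1) or `"stock"`
#'   (Mg ha^-1; requires `thickness_cm`).
#' @param thickness_cm Deposit thickness used by the stock formula.
#' @param n_boot,seed As in [bootstrap_mean()].
#' @param draws_per_replicate Derived values averaged per replicate
#'   (default 1).
#' @return A `boot_estimate`.
#' @export
bootstrap_derived <- function(sar_values, bd_values, fn_values,
                              statistic = c("accumulation", "stock"),
                              thickness_cm = NULL,
                              n_boot = 1000, seed = NULL,
                              draws_per_replicate = 1) {
  statistic <- match.arg(statistic)
  sar_values <- sar_values[!is.na(sar_values)]
  bd_values <- bd_values[!is.na(bd_values)]
  fn_values <- fn_values[!is.na(fn_values)]
  if (!length(sar_values) || !length(bd_values) || !length(fn_values))
    stop("bootstrap_derived: all three samples must be non-empty")
  if (statistic == "stock" && is.null(thickness_cm))
    stop("bootstrap_derived: stock statistic needs thickness_cm")
  if (!is.null(seed)) set.seed(seed)
  m <- draws_per_replicate
  total <- n_boot * m
  sar <- sar_values[sample.int(length(sar_values), total, replace = TRUE)]
  bd <- bd_values[sample.int(length(bd_values), total, replace = TRUE)]
  fn <- fn_values[sample.int(length(fn_values), total, replace = TRUE)]
  derived <- if (statistic == "accumulation") {
    n_accumulation_rate(sar, bd, fn)
  } else {
    bd * thickness_cm * fn * 100
  }
  reps <- if (m == 1L) derived else colMeans(matrix(derived, nrow = m))
  new_boot_estimate(reps)
}

#' Pool bootstrap estimates from replicate cores into a site estimate
#'
#' Concatenates the retained replicate values of each input (e.g. the
#' 1,000 replicates of each of two cores into 2,000 site values) and
#' recomputes the mean and 2.5/97.5 percentile bounds on the pooled
#' collection. When the two cores disagree the pooled bounds are wider
#' than either core's own bounds, which is the intended behaviour for
#' between-site comparisons.
#'
#' @param ... `boot_estimate` objects, or a single list of them.
#' @return A pooled `boot_estimate`.
#' @export
pool_site <- function(...) {
  ests <- list(...)
  if (length(ests) == 1L && !inherits(ests[[1L]], "boot_estimate"))
    ests <- ests[[1L]]
  if (!length(ests)) stop("pool_site: no estimates given")
  for (e in ests) {
    if (!inherits(e, "boot_estimate") || is.null(e$replicate_values))
      stop("pool_site: every input must be a boot_estimate retaining ",
           "replicate_values")
  }
  new_boot_estimate(unlist(lapply(ests, `[[`, "replicate_values"),
                           use.names = FALSE))
}

#' Overlap-based significance between two bootstrap estimates
#'
#' Two quantities are called significantly different exactly when their
#' closed 95% bootstrap intervals are disjoint. A shared endpoint counts
#' as overlap (conservative).
#'
#' @param a,b `boot_estimate` objects.
#' @return `"significant"` or `"not_significant"`.
#' @export
compare_estimates <- function(a, b) {
  stopifnot(inherits(a, "boot_estimate"), inherits(b, "boot_estimate"))
  if (a$upper < b$lower || b$upper < a$lower) "significant"
  else "not_significant"
}

#' Bootstrap estimate table for a collection of cores
#'
#' Runs the per-core bootstrap over both periods for the measured
#' parameters (%N, bulk density, d15N when present) and the derived
#' stock and accumulation quantities, with per-core substream seeds so
#' core order cannot change any result.
#'
#' @param cores List of `sediment_core` objects (with `sar_by_period`
#'   for the derived quantities).
#' @param periods Named list of periods.
#' @param n_boot Replicates per core (default 1000).
#' @param seed Run seed.
#' @return List with `estimates` (nested: `[[core]][[period]][[quantity]]`
#'   `boot_estimate`s) and `table` (flat data frame
#'   `site_id,core_id,period,quantity,mean,lower,upper,n_boot`).
#' @export
bootstrap_cores <- function(cores, periods = default_periods(),
                            n_boot = 1000, seed = 1) {
  estimates <- list()
  rows <- list()
  for (co in cores) {
    for (pd in periods) {
      s <- assign_period(co, pd)
      if (!nrow(s)) next
      sub <- substream_seed(seed, paste(co$core_id, pd$name))
      sar <- if (!is.null(co$sar_by_period) &&
                 pd$name %in% names(co$sar_by_period))
        unname(co$sar_by_period[[pd$name]]) else NULL
      qs <- list(
        n_fraction = bootstrap_mean(s$n_fraction, n_boot, seed = sub),
        bulk_density = bootstrap_mean(s$bulk_density, n_boot, seed = sub + 1L)
      )
      if (any(!is.na(s$d15n)))
        qs$d15n <- bootstrap_mean(s$d15n, n_boot, seed = sub + 2L)
      if (!is.null(sar)) {
        qs$accumulation <- bootstrap_derived(
          sar, s$bulk_density, s$n_fraction, "accumulation",
          n_boot = n_boot, seed = sub + 3L)
        thick <- max(s$depth_bottom) - min(s$depth_top)
        qs$stock <- bootstrap_derived(
          sar, s$bulk_density, s$n_fraction, "stock", thickness_cm = thick,
          n_boot = n_boot, seed = sub + 4L)
      }
      estimates[[co$core_id]][[pd$name]] <- qs
      for (qn in names(qs)) {
        e <- qs[[qn]]
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = co$site_id, core_id = co$core_id, period = pd$name,
          quantity = qn, mean = e$mean, lower = e$lower, upper = e$upper,
          n_boot = e$n_boot, stringsAsFactors = FALSE)
      }
    }
  }
  list(estimates = estimates, table = do.call(rbind, rows))
}
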