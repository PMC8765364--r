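#' Dissolved inorganic nitrogen with non-detect handling
#'
#' DIN is the sum of ammonium and nitrate+nitrite. Nitrate+nitrite is
#' often below detection in mangrove porewater; non-detects are set
#' either to 0 (default -- the more conservative estimate of
#' variability) or to the detection limit.
#'
#' @param nh4 Ammonium, uM (>= 0).
#' @param nox Nitrate+nitrite, uM (ignored where not detected).
#' @param nox_detected Logical, recycled along `nh4`.
#' @param policy `"zero"` or `"detection_limit"`.
#' @param dl Detection limit, uM (default 0.05).
#' @return DIN, uM (vectorized).
#' @export
din <- function(nh4, nox, nox_detected = TRUE,
                policy = c("zero", "detection_limit"), dl = 0.05) {
  policy <- match.arg(policy)
  if (any(nh4 < 0)) stop("din: nh4 must be >= 0")
  if (any(nox[nox_detected] < 0, na.rm = TRUE))
    stop("din: negative detected nox")
  fill <- if (policy == "zero") 0 else dl
  nox_eff <- ifelse(nox_detected, nox, fill)
  nh4 + nox_eff
}

#' Molar N:P ratio of porewater
#'
#' DIN over phosphate, both in molar concentration units (uM), so the
#' ratio is dimensionless. Ratios well below ~19:1 (the typical low
#' intertidal mangrove porewater value) suggest N limitation; very large
#' ratios suggest P limitation.
#'
#' @param din DIN, uM.
#' @param po4 Phosphate, uM; must be > 0.
#' @return Dimensionless molar ratio (vectorized).
#' @export
np_molar_ratio <- function(din, po4) {
  if (any(po4 <= 0)) stop("np_molar_ratio: po4 must be > 0")
  din / po4
}

#' Site-by-season porewater nutrient summary
#'
#' Means and standard errors of phosphate, ammonium and DIN per site and
#' season, with the molar N:P ratio of the cell means (rounded to one
#' decimal, the conventional reporting precision).
#'
#' @param samples Porewater sample data frame (see
#'   [read_porewater_table()]).
#' @param policy,dl Non-detect policy passed to [din()].
#' @return Data frame `site_id,season,n,po4_mean,po4_se,nh4_mean,nh4_se,`
#'   `din_mean,din_se,np_molar`.
#' @export
porewater_summary <- function(samples, policy = "zero", dl = 0.05) {
  samples$din_um <- din(samples$nh4_um, samples$nox_um,
                        samples$nox_detected, policy = policy, dl = dl)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  cells <- split(samples, interaction(samples$site_id, samples$season,
                                      drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(d) {
    data.frame(site_id = d$site_id[1L], season = d$season[1L], n = nrow(d),
               po4_mean = mean(d$po4_um), po4_se = se(d$po4_um),
               nh4_mean = mean(d$nh4_um), nh4_se = se(d$nh4_um),
               din_mean = mean(d$din_um), din_se = se(d$din_um),
               np_molar = round(np_molar_ratio(mean(d$din_um),
                                               mean(d$po4_um)), 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$site_id, out$season), ]
}

#' Two-way factorial comparison of porewater nutrients
#'
#' Evaluates site and seasonal effects on a porewater analyte with a
#' two-factor fixed-effects decomposition (site x season, with
#' interaction) on natural-log transformed concentrations
#' (`ln(x + dl)`, the offset guarding against zeros), reports a
#' Shapiro-Wilk residual normality check, and runs all pairwise
#' site-within-season and season-within-site contrasts with
#' Bonferroni-adjusted significance at family level `alpha`.
#'
#' @param samples Porewater sample data frame; every site x season cell
#'   must hold at least 2 replicates.
#' @param analyte `"nh4"`, `"din"` or `"po4"`.
#' @param policy,dl Non-detect policy for DIN and the log offset.
#' @param alpha Familywise significance level (default 0.05).
#' @return Object of class `porewater_comparison`: `anova` (the aov
#'   table), `shapiro_p`, `site_contrasts` and `season_contrasts`
#'   (data frames with Bonferroni-adjusted p-values and a `significant`
#'   flag), `alpha`, `analyte`.
#' @export
seasonal_site_comparison <- function(samples, analyte = c("nh4", "din", "po4"),
                                     policy = "zero", dl = 0.05,
                                     alpha = 0.05) {
  analyte <- match.arg(analyte)
  x <- switch(analyte,
              nh4 = samples$nh4_um,
              po4 = samples$po4_um,
              din = din(samples$nh4_um, samples$nox_um,
                        samples$nox_detected, policy = policy, dl = dl))
  d <- data.frame(y = log(x + dl),
                  site = factor(samples$site_id),
                  season = factor(samples$season))
  counts <- table(d$site, d$season)
  if (any(counts < 2L))
    stop("seasonal_site_comparison: every site x season cell needs >= 2 ",
         "replicates")
  if (stats::var(d$y) < 1e-12) {
    # degenerate all-equal data: nothing can be significant
    return(structure(list(anova = NULL, shapiro_p = NA_real_,
                          site_contrasts = NULL, season_contrasts = NULL,
                          any_significant = FALSE, alpha = alpha,
                          analyte = analyte),
                     class = "porewater_comparison"))
  }
  fit <- stats::aov(y ~ site * season, data = d)
  sw <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                 error = function(e) NA_real_)
  grab <- function(spec) {
    em <- emmeans::emmeans(fit, spec)
    s <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                 adjust = "bonferroni")))
    s$significant <- !is.na(s$p.value) & s$p.value < alpha
    s
  }
  structure(list(anova = summary(fit), shapiro_p = sw,
                 site_contrasts = grab(~ site | season),
                 season_contrasts = grab(~ season | site),
                 alpha = alpha, analyte = analyte),
            class = "porewater_comparison")
}

#' @export
print.porewater_comparison <- function(x, ...) {
  cat(sprintf("<porewater comparison> analyte %s (ln scale), alpha %.2f\n",
              x$analyte, x$alpha))
  if (is.null(x$anova)) {
    cat("  degenerate (constant) data: no significant effects\n")
    return(invisible(x))
  }
  cat(sprintf("  Shapiro-Wilk residual p = %.3f\n", x$shapiro_p))
  ns <- sum(x$site_contrasts$significant) + sum(x$season_contrasts$significant)
  cat(sprintf("  %d significant pairwise contrast(s)\n", ns))
  invisible(x)
}

#' Significance calls of a porewater comparison
#'
#' Flat view of the pairwise contrasts of a
#' [seasonal_site_comparison()], convenient for checking that the calls
#' are invariant to the non-detect policy.
#'
#' @param comparison A `porewater_comparison`.
#' @return Data frame `family,contrast,within,significant` (zero rows
#'   for the degenerate constant-data case).
#' @export
comparison_calls <- function(comparison) {
  stopifnot(inherits(comparison, "porewater_comparison"))
  if (is.null(comparison$site_contrasts))
    return(data.frame(family = character(), contrast = character(),
                      within = character(), significant = logical()))
  sc <- comparison$site_contrasts
  se <- comparison$season_contrasts
  rbind(
    data.frame(family = "site_within_season", contrast = sc$contrast,
               within = as.character(sc$season), significant = sc$significant,
               stringsAsFactors = FALSE),
    data.frame(family = "season_within_site", contrast = se$contrast,
               within = as.character(se$site), significant = se$significant,
               stringsAsFactors = FALSE)
  )
}
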