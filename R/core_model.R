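#' Define a deposition time period
#'
#' A named calendar window used to group dated core slices, e.g. the
#' recent (1970--2016) and historic (1930--1970) deposition periods of an
#' urbanizing estuary. Intervals are half-open on the upper bound, so a
#' slice dated exactly 1970 belongs to a period starting in 1970 and not
#' to one ending in 1970.
#'
#' @param name Short label ("recent", "historic").
#' @param start_year First calendar year of the period (inclusive).
#' @param end_year Last calendar year of the period (exclusive).
#' @return An object of class `period_definition` with fields `name`,
#'   `start_year`, `end_year` and `duration_y`.
#' @examples
#' period_definition("recent", 1970, 2016)
#' @export
period_definition <- function(name, start_year, end_year) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(start_year), is.numeric(end_year))
  if (!(start_year < end_year)) {
    stop("period '", name, "': start_year must be < end_year")
  }
  structure(
    list(name = name, start_year = as.numeric(start_year),
         end_year = as.numeric(end_year),
         duration_y = as.numeric(end_year - start_year)),
    class = "period_definition"
  )
}

#' @export
print.period_definition <- function(x, ...) {
  cat(sprintf("<period> %s: [%g, %g) (%g y)\n",
              x$name, x$start_year, x$end_year, x$duration_y))
  invisible(x)
}

#' Default deposition periods
#'
#' Recent decades 1970--2016 (46 y, roughly the upper ~18 cm of the
#' studied cores) and historic decades 1930--1970 (40 y, ~19--28 cm).
#'
#' @return Named list of two `period_definition` objects, `recent` and
#'   `historic`.
#' @export
default_periods <- function() {
  list(recent   = period_definition("recent", 1970, 2016),
       historic = period_definition("historic", 1930, 1970))
}

# required numeric slice columns (internal representation; n/c as fractions)
.slice_cols <- c("depth_top", "depth_bottom", "mid_date",
                 "bulk_density", "n_fraction", "c_fraction",
                 "d15n", "d34s")

#' Validate a slice table
#'
#' Checks the physical and ordering invariants of a core's slice table:
#' positive thickness, non-overlapping depth-ordered intervals, bulk
#' density in (0, 2.6] g cm^-3, nitrogen fraction in [0, 0.1), carbon
#' fraction in [0, 0.6), and apparent age non-increasing with depth.
#'
#' @param slices Data frame with columns `depth_top`, `depth_bottom`,
#'   `mid_date`, `bulk_density`, `n_fraction`, `c_fraction` and optional
#'   `d15n`, `d34s`.
#' @param core_id Label used in error messages.
#' @return The slice table, depth-ordered, invisibly-checked.
#' @export
validate_slices <- function(slices, core_id = "<core>") {
  stopifnot(is.data.frame(slices))
  miss <- setdiff(setdiff(.slice_cols, c("d15n", "d34s")), names(slices))
  if (length(miss)) {
    stop("core ", core_id, ": missing slice columns: ",
         paste(miss, collapse = ", "))
  }
  if (nrow(slices) < 1L) stop("core ", core_id, ": needs at least one slice")
  if (is.null(slices$d15n)) slices$d15n <- NA_real_
  if (is.null(slices$d34s)) slices$d34s <- NA_real_
  slices <- slices[order(slices$depth_top), , drop = FALSE]
  rownames(slices) <- NULL
  with(slices, {
    if (any(!(depth_top < depth_bottom)))
      stop("core ", core_id, ": slice with non-positive thickness")
    if (any(!(bulk_density > 0 & bulk_density <= 2.6)))
      stop("core ", core_id, ": bulk density outside (0, 2.6] g cm-3")
    if (any(!(n_fraction >= 0 & n_fraction < 0.1)))
      stop("core ", core_id, ": n_fraction outside [0, 0.1)")
    if (any(!(c_fraction >= 0 & c_fraction < 0.6)))
      stop("core ", core_id, ": c_fraction outside [0, 0.6)")
  })
  if (nrow(slices) > 1L) {
    ov <- slices$depth_top[-1L] < slices$depth_bottom[-nrow(slices)] - 1e-9
    if (any(ov)) {
      stop("core ", core_id, ": overlapping slices at depth_top = ",
           paste(slices$depth_top[-1L][ov], collapse = ", "), " cm")
    }
    dd <- diff(slices$mid_date)
    if (any(dd > 1e-9, na.rm = TRUE))
      stop("core ", core_id, ": mid_date increases with depth")
  }
  slices
}

#' Construct a sediment core
#'
#' @param core_id,site_id Labels.
#' @param slices Slice table (see [validate_slices()]).
#' @param sar_by_period Named numeric vector of sediment accretion rates
#'   (mm y^-1) keyed by period name; each value must lie in (0, 20).
#' @return Object of class `sediment_core`.
#' @export
sediment_core <- function(core_id, site_id, slices, sar_by_period = NULL) {
  slices <- validate_slices(slices, core_id)
  if (!is.null(sar_by_period)) {
    if (is.null(names(sar_by_period)) || any(!nzchar(names(sar_by_period))))
      stop("core ", core_id, ": sar_by_period must be named by period")
    if (any(!(sar_by_period > 0 & sar_by_period < 20)))
      stop("core ", core_id, ": SAR outside (0, 20) mm y-1")
  }
  structure(list(core_id = as.character(core_id),
                 site_id = as.character(site_id),
                 slices = slices,
                 sar_by_period = sar_by_period),
            class = "sediment_core")
}

#' @export
print.sediment_core <- function(x, ...) {
  cat(sprintf("<sediment_core> %s (site %s): %d slices, %g-%g cm\n",
              x$core_id, x$site_id, nrow(x$slices),
              min(x$slices$depth_top), max(x$slices$depth_bottom)))
  if (!is.null(x$sar_by_period)) {
    cat("  SAR (mm/y):",
        paste(sprintf("%s=%.2f", names(x$sar_by_period), x$sar_by_period),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select the slices of a core deposited in a period
#'
#' Returns the slices whose modelled calendar date falls in
#' `[start_year, end_year)`. The half-open convention puts a slice dated
#' exactly on a boundary year into the later period only, so the two
#' standard periods partition 1930--2016 slices with no double counting.
#'
#' @param core A `sediment_core`.
#' @param period A `period_definition`.
#' @return The subset of the slice table in the period (possibly 0 rows).
#' @export
assign_period <- function(core, period) {
  stopifnot(inherits(core, "sediment_core"),
            inherits(period, "period_definition"))
  s <- core$slices
  s[!is.na(s$mid_date) &
      s$mid_date >= period$start_year &
      s$mid_date < period$end_year, , drop = FALSE]
}

#' Read a sediment-core table
#'
#' Reads the long CSV interface
#' `core_id,site_id,depth_top_cm,depth_bottom_cm,mid_date,bulk_density_gcm3,percent_n,percent_c,d15n_permil,d34s_permil`
#' (isotope columns optional/blank). Percent N and C are converted to
#' mass fractions on read; all downstream arithmetic uses fractions so a
#' stray factor of 100 cannot creep in. Rows whose mandatory numeric
#' fields do not parse are dropped with a warning naming their file line
#' numbers.
#'
#' @param path CSV file path.
#' @param sar Optional data frame `core_id,period,sar_mm_y` (as written
#'   by [write_sar_table()]) used to attach accretion rates to each core.
#' @return Named list of `sediment_core` objects keyed by `core_id`.
#' @export
read_core_table <- function(path, sar = NULL) {
  if (!file.exists(path)) stop("core table not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  mandatory <- c("core_id", "site_id", "depth_top_cm", "depth_bottom_cm",
                 "mid_date", "bulk_density_gcm3", "percent_n", "percent_c")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("core table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- data.frame(
    core_id = raw$core_id, site_id = raw$site_id,
    depth_top = num(raw$depth_top_cm),
    depth_bottom = num(raw$depth_bottom_cm),
    mid_date = num(raw$mid_date),
    bulk_density = num(raw$bulk_density_gcm3),
    n_fraction = num(raw$percent_n) / 100,
    c_fraction = num(raw$percent_c) / 100,
    d15n = if ("d15n_permil" %in% names(raw)) num(raw$d15n_permil) else NA_real_,
    d34s = if ("d34s_permil" %in% names(raw)) num(raw$d34s_permil) else NA_real_,
    stringsAsFactors = FALSE
  )
  need <- c("depth_top", "depth_bottom", "mid_date",
            "bulk_density", "n_fraction", "c_fraction")
  bad <- rowSums(is.na(parsed[need])) > 0
  if (any(bad)) {
    warning("core table ", path, ": dropping unparseable row(s) at line(s) ",
            paste(which(bad) + 1L, collapse = ", "))  # +1 for the header
    parsed <- parsed[!bad, , drop = FALSE]
  }
  if (!nrow(parsed)) stop("core table ", path, ": no valid rows")
  out <- lapply(split(parsed, parsed$core_id), function(d) {
    sar_vec <- NULL
    if (!is.null(sar)) {
      sd <- sar[sar$core_id == d$core_id[1L], , drop = FALSE]
      if (nrow(sd)) sar_vec <- stats::setNames(sd$sar_mm_y, sd$period)
    }
    sediment_core(d$core_id[1L], d$site_id[1L],
                  d[, .slice_cols, drop = FALSE], sar_by_period = sar_vec)
  })
  out[order(names(out))]
}

#' Write a sediment-core table
#'
#' Inverse of [read_core_table()]: fractions are rendered as percent and
#' numbers are written with 17 significant digits so that a write/read
#' round trip reproduces every numeric field.
#'
#' @param cores List of `sediment_core` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_core_table <- function(cores, path) {
  if (inherits(cores, "sediment_core")) cores <- list(cores)
  rows <- do.call(rbind, lapply(cores, function(co) {
    s <- co$slices
    data.frame(core_id = co$core_id, site_id = co$site_id,
               depth_top_cm = s$depth_top, depth_bottom_cm = s$depth_bottom,
               mid_date = s$mid_date, bulk_density_gcm3 = s$bulk_density,
               percent_n = s$n_fraction * 100, percent_c = s$c_fraction * 100,
               d15n_permil = s$d15n, d34s_permil = s$d34s,
               stringsAsFactors = FALSE)
  }))
  numc <- vapply(rows, is.numeric, logical(1L))
  rows[numc] <- lapply(rows[numc], function(x) {
    ifelse(is.na(x), "", sprintf("%.17g", x))
  })
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-core accretion-rate tables
#'
#' CSV interface `core_id,period,sar_mm_y` holding the site-level
#' sediment accretion rates (mm y^-1) per deposition period, taken from
#' prior radiometric age-depth models.
#'
#' @param path CSV path.
#' @return `read_sar_table`: data frame with those three columns.
#' @export
read_sar_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "period", "sar_mm_y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("sar table: missing column(s) ",
                         paste(miss, collapse = ", "))
  d
}

#' @rdname read_sar_table
#' @param cores List of `sediment_core` objects carrying `sar_by_period`.
#' @export
write_sar_table <- function(cores, path) {
  rows <- do.call(rbind, lapply(cores, function(co) {
    if (is.null(co$sar_by_period)) return(NULL)
    data.frame(core_id = co$core_id, period = names(co$sar_by_period),
               sar_mm_y = unname(co$sar_by_period), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a site record
#'
#' @param site_id Label.
#' @param urban_index Integer 1 (least) to 100 (most urbanized), scored
#'   from impervious surface, population and road density in the 500 m
#'   buffer around the site.
#' @param x,y Planar site coordinates in metres.
#' @param species_composition Named proportions of stand biomass per
#'   species; must sum to 1.
#' @param buffer_radius Buffer radius in metres (default 500).
#' @param population Persons living within the buffer (optional).
#' @return Object of class `site_record`.
#' @export
site_record <- function(site_id, urban_index, x, y,
                        species_composition, buffer_radius = 500,
                        population = NA_real_) {
  if (!(urban_index >= 1 && urban_index <= 100))
    stop("site ", site_id, ": urban_index must be in [1, 100]")
  p <- species_composition
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("site ", site_id,
         ": species_composition must be named, non-negative, and sum to 1")
  structure(list(site_id = as.character(site_id),
                 urban_index = as.integer(urban_index),
                 x = as.numeric(x), y = as.numeric(y),
                 species_composition = p,
                 buffer_radius = buffer_radius,
                 population = population),
            class = "site_record")
}

#' Read / write site tables
#'
#' Long CSV interface `site_id,urban_index,x_m,y_m,species,proportion`
#' (one row per species in the stand), with optional `population`.
#'
#' @param path CSV path.
#' @return `read_site_table`: named list of `site_record` objects.
#' @export
read_site_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "urban_index", "x_m", "y_m", "species", "proportion")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("site table: missing column(s) ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(d, d$site_id), function(s) {
    site_record(s$site_id[1L], s$urban_index[1L], s$x_m[1L], s$y_m[1L],
                stats::setNames(s$proportion, s$species),
                population = if ("population" %in% names(s))
                  s$population[1L] else NA_real_)
  })
  out[order(names(out))]
}

#' @rdname read_site_table
#' @param sites Named list of `site_record` objects.
#' @export
write_site_table <- function(sites, path) {
  rows <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, urban_index = s$urban_index,
               x_m = s$x, y_m = s$y,
               species = names(s$species_composition),
               proportion = unname(s$species_composition),
               population = s$population, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a porewater sample table
#'
#' CSV interface
#' `site_id,season,nh4_um,nox_um,nox_detected,po4_um,salinity_psu,ph`.
#' `nox_detected` is logical; when FALSE the `nox_um` cell is ignored and
#' the non-detect policy of downstream functions applies. Detected
#' concentrations must be non-negative and season must be "wet" or "dry".
#'
#' @param path CSV path.
#' @return Data frame of porewater samples.
#' @export
read_porewater_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "season", "nh4_um", "nox_um", "nox_detected", "po4_um")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("porewater table: missing column(s) ",
                         paste(miss, collapse = ", "))
  d$nox_detected <- as.logical(d$nox_detected)
  if (any(!d$season %in% c("wet", "dry")))
    stop("porewater table: season must be 'wet' or 'dry'")
  conc <- c(d$nh4_um, d$po4_um, d$nox_um[d$nox_detected])
  if (any(conc < 0, na.rm = TRUE))
    stop("porewater table: negative detected concentration")
  d
}

#' @rdname read_porewater_table
#' @param samples Data frame of porewater samples.
#' @export
write_porewater_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
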