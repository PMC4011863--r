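# Locality vetting and species-level climate summaries.
#
# Locality tables carry one museum-record row per (species, lon, lat) with
# WorldClim bioclim values already extracted: bio5/bio6 (max temp of
# warmest month, min temp of coldest month), bio10/bio11 (mean temp of
# warmest/coldest quarter), bio12/bio16 (annual / wettest-quarter
# precipitation, mm), bio15 (precipitation seasonality, CV). Temperatures
# are expected in degrees C; WorldClim 1.x rasters store them x10, so the
# reader takes a mandatory unit declaration.

BIOCLIM_VARS <- c("bio5", "bio6", "bio10", "bio11", "bio12", "bio15", "bio16")
TEMP_VARS <- c("bio5", "bio6", "bio10", "bio11")

#' Read a locality table with an explicit temperature-unit declaration
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line)
#'   with columns `species`, `lon`, `lat`, optionally `elevation` and
#'   `in_range`, plus the bioclim columns.
#' @param temperature_units `"celsius"` (values used as-is) or
#'   `"worldclim-raw"` (WorldClim 1.x integer storage; temperature columns
#'   multiplied by 0.1). Mandatory because the aridity index depends on the
#'   temperature scale.
#' @return Data frame of locality records.
#' @export
read_locality_table <- function(path,
                                temperature_units = c("celsius",
                                                      "worldclim-raw")) {
  temperature_units <- match.arg(temperature_units)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (temperature_units == "worldclim-raw") {
    for (v in intersect(TEMP_VARS, names(rec))) rec[[v]] <- rec[[v]] * 0.1
  }
  validate_localities(rec)
}

validate_localities <- function(records) {
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("locality table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(records$lon < -180 | records$lon > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  if (any(records$lat < -90 | records$lat > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  for (v in intersect(c("bio12", "bio16"), names(records)))
    if (any(records[[v]] < 0, na.rm = TRUE))
      stop("negative precipitation in ", v)
  if (all(c("bio5", "bio6") %in% names(records))) {
    bad <- which(records$bio5 < records$bio6)
    if (length(bad) > 0)
      stop("bio5 < bio6 (warmest-month max below coldest-month min) in ",
           length(bad), " record(s), first at row ", bad[1])
  }
  records
}

#' Vet locality records before climate summarization
#'
#' Collapses exact duplicate localities (coordinates compared after
#' rounding to 4 decimal places, about 11 m), drops records flagged as
#' outside the species' published range (`in_range = FALSE`), and drops
#' records whose elevation falls outside the reported elevational range.
#' Records without an elevation value pass the elevation filter with a
#' logged note.
#'
#' @param records Locality data frame (see [read_locality_table()]).
#' @param elevation_min,elevation_max Finite bounds (m) of the accepted
#'   elevational range.
#' @return List with `kept` (vetted records) and `log` (one row per
#'   rejected or noted record: `species`, `lon`, `lat`, `reason`).
#' @export
vet_localities <- function(records, elevation_min, elevation_max) {
  records <- validate_localities(records)
  if (!is.finite(elevation_min) || !is.finite(elevation_max) ||
      elevation_min > elevation_max)
    stop("elevation bounds must be finite with min <= max")
  species_in <- unique(records$species)
  log_rows <- list()
  note <- function(rec, reason) {
    data.frame(species = rec$species, lon = rec$lon, lat = rec$lat,
               reason = reason, stringsAsFactors = FALSE)
  }

  key <- paste(records$species, round(records$lon, 4), round(records$lat, 4))
  dup <- duplicated(key)
  if (any(dup)) log_rows <- c(log_rows, list(note(records[dup, ],
                                                  "duplicate_locality")))
  records <- records[!dup, , drop = FALSE]

  if ("in_range" %in% names(records)) {
    out <- !is.na(records$in_range) & !records$in_range
    if (any(out)) log_rows <- c(log_rows, list(note(records[out, ],
                                                    "outside_iucn_range")))
    records <- records[!out, , drop = FALSE]
  }

  if ("elevation" %in% names(records)) {
    no_elev <- is.na(records$elevation)
    if (any(no_elev))
      log_rows <- c(log_rows, list(note(records[no_elev, ],
                                        "no_elevation_filter_skipped")))
    out <- !no_elev & (records$elevation < elevation_min |
                       records$elevation > elevation_max)
    if (any(out)) log_rows <- c(log_rows, list(note(records[out, ],
                                                    "elevation_out_of_range")))
    records <- records[!out, , drop = FALSE]
  } else if (nrow(records) > 0) {
    log_rows <- c(log_rows, list(note(records,
                                      "no_elevation_filter_skipped")))
  }

  gone <- setdiff(species_in, unique(records$species))
  if (length(gone) > 0)
    stop("all localities rejected for species: ",
         paste(gone, collapse = ", "))
  log_df <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(species = character(), lon = numeric(), lat = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  list(kept = records, log = log_df)
}

#' Aridity index logQ from range-extreme temperatures
#'
#' \deqn{Q = P / ((T_{max} + T_{min}) (T_{max} - T_{min}))}
#' with `P` the annual precipitation (mm, mean across the species'
#' localities), `tmax` the maximum bio5 across the range and `tmin` the
#' minimum bio6. Arid environments have lower Q. Returned on the log10
#' scale by convention (`base = exp(1)` for natural log).
#'
#' @param P Annual precipitation, mm (>= 0).
#' @param tmax,tmin Temperatures, degrees C, with `tmax > tmin`.
#' @param base Logarithm base (default 10).
#' @return log of Q in the requested base.
#' @export
aridity_logQ <- function(P, tmax, tmin, base = 10) {
  if (any(tmax <= tmin))
    stop("tmax must exceed tmin (got tmax = ", tmax[1], ", tmin = ",
         tmin[1], ")")
  if (any((tmax + tmin) == 0)) stop("tmax + tmin is zero; Q undefined")
  Q <- P / ((tmax + tmin) * (tmax - tmin))
  if (any(!is.finite(Q) | Q <= 0))
    stop("Q must be positive for the log (got Q = ", Q[1],
         "); check P > 0 and tmax + tmin > 0")
  log(Q, base = base)
}

#' Aridity index logQ2 from quarter-mean temperatures
#'
#' Same formula as [aridity_logQ()] but with `t_warm` the mean bio10
#' (warmest-quarter mean) and `t_cold` the mean bio11 (coldest-quarter
#' mean) across localities.
#'
#' @param P Annual precipitation, mm.
#' @param t_warm,t_cold Quarter-mean temperatures, degrees C.
#' @inheritParams aridity_logQ
#' @return log of Q2 in the requested base.
#' @export
aridity_logQ2 <- function(P, t_warm, t_cold, base = 10) {
  aridity_logQ(P, t_warm, t_cold, base = base)
}

#' Reduce vetted localities to species-level climate summaries
#'
#' Per species and per bioclim variable: minimum, maximum, mean across
#' localities and the midpoint (min + max)/2. Attaches the aridity indices
#' logQ (mean bio12; max bio5; min bio6) and logQ2 (mean bio12; mean bio10;
#' mean bio11). A variable that is entirely missing for a species yields
#' `NA` summaries, never zero.
#'
#' @param records Vetted locality data frame.
#' @param variables Bioclim columns to summarize (defaults to those
#'   present among bio5, bio6, bio10, bio11, bio12, bio15, bio16).
#' @return Data frame, one row per species: `species`, `n_localities`,
#'   `<var>_min`, `<var>_max`, `<var>_mean`, `<var>_midpoint` per
#'   variable, plus `logQ` and `logQ2` where computable.
#' @export
summarize_species <- function(records,
                              variables = intersect(BIOCLIM_VARS,
                                                    names(records))) {
  records <- validate_localities(records)
  sp <- unique(records$species)
  rows <- lapply(sp, function(s) {
    rec <- records[records$species == s, , drop = FALSE]
    out <- list(species = s, n_localities = nrow(rec))
    for (v in variables) {
      x <- rec[[v]][!is.na(rec[[v]])]
      if (length(x) == 0) {
        out[paste0(v, c("_min", "_max", "_mean", "_midpoint"))] <-
          list(NA_real_, NA_real_, NA_real_, NA_real_)
      } else {
        out[[paste0(v, "_min")]] <- min(x)
        out[[paste0(v, "_max")]] <- max(x)
        out[[paste0(v, "_mean")]] <- mean(x)
        out[[paste0(v, "_midpoint")]] <- (min(x) + max(x)) / 2
      }
    }
    q_ready <- function(...) {
      vals <- list(...)
      all(lengths(vals) == 1) && all(is.finite(unlist(vals)))
    }
    out$logQ <- if (q_ready(out$bio12_mean, out$bio5_max, out$bio6_min))
      aridity_logQ(out$bio12_mean, out$bio5_max, out$bio6_min) else NA_real_
    out$logQ2 <- if (q_ready(out$bio12_mean, out$bio10_mean, out$bio11_mean))
      aridity_logQ2(out$bio12_mean, out$bio10_mean, out$bio11_mean) else
        NA_real_
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
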