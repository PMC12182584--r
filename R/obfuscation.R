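# Coordinate obfuscation for sensitive records (e.g. bat roosts where a
# positive detection could trigger culling): truncation to a coarser grid
# or seeded jitter on a disk. Every obfuscation propagates into the
# spatial-uncertainty field (which documents systematic alterations in
# meters) and appends an auditable provenance entry. Obfuscation reduces,
# but does not eliminate, re-identification risk; deciding which records
# are sensitive is left to the researcher.

.METERS_PER_DEGREE <- 111320

.run_seeded <- function(seed, expr) {
  # evaluate expr under set.seed(seed) without disturbing the caller's RNG
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.provenance_entry <- function(method, params) {
  list(method = method, params = params,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Truncate coordinates to a fixed number of decimals
#'
#' Rounds each latitude and longitude toward zero to `decimals` decimal
#' places, so obfuscated values never imply precision beyond the grid
#' cell. Spatial uncertainty is raised to at least the half-cell diagonal
#' in meters, `sqrt((delta*111320)^2 + (delta*111320*cos(phi))^2)` with
#' `delta = 0.5 * 10^-decimals` and `phi` the truncated latitude. A
#' provenance entry recording the method, decimals, and timestamp is
#' appended.
#'
#' @param dataset a `wdds_dataset`.
#' @param decimals integer in `[0, 6]`.
#' @return The modified dataset.
#' @export
truncate_coordinates <- function(dataset, decimals) {
  stopifnot(inherits(dataset, "wdds_dataset"),
            length(decimals) == 1, decimals >= 0, decimals <= 6,
            decimals == trunc(decimals))
  rec <- dataset$records
  ok <- !is.na(rec$latitude) & !is.na(rec$longitude)
  if (any(!ok))
    dataset$findings <- rbind(dataset$findings,
      .finding("OBFUSCATION", "warning", which(!ok)[1], "latitude",
        sprintf("%d record(s) with blank coordinates skipped by truncation",
                sum(!ok))))
  scale <- 10^decimals
  lat <- trunc(rec$latitude[ok] * scale) / scale
  lon <- trunc(rec$longitude[ok] * scale) / scale
  delta <- 0.5 * 10^(-decimals)
  half_cell <- sqrt((delta * .METERS_PER_DEGREE)^2 +
                    (delta * .METERS_PER_DEGREE * cos(lat * pi / 180))^2)
  rec$latitude[ok] <- lat
  rec$longitude[ok] <- lon
  existing <- rec$spatial_uncertainty[ok]
  rec$spatial_uncertainty[ok] <- pmax(ifelse(is.na(existing), 0, existing),
                                      half_cell)
  dataset$records <- rec
  dataset$provenance <- c(dataset$provenance,
    list(.provenance_entry("truncate_coordinates",
                           list(decimals = decimals,
                                n_records = sum(ok)))))
  dataset
}

#' Jitter coordinates with seeded random noise
#'
#' Displaces each point by a uniform draw on the disk of radius
#' `radius_m` meters, in a local equirectangular approximation: radial
#' distance `r = radius_m * sqrt(u)`, angle uniform, converted to degrees
#' with `111320 * cos(latitude)` meters per degree of longitude. Spatial
#' uncertainty is raised to at least `radius_m`. The seed is a mandatory
#' argument — documented, reproducible obfuscation with no wall-clock
#' entropy; set `record_seed = FALSE` to keep the seed out of the
#' provenance log of a dataset that will be published. Records within
#' 0.1 degrees of a pole are skipped (the longitude conversion
#' degenerates); longitudes are wrapped into (-180, 180].
#'
#' @param dataset a `wdds_dataset`.
#' @param radius_m jitter radius in meters, > 0.
#' @param seed integer seed.
#' @param record_seed record the seed in the provenance entry? Default
#'   `TRUE`.
#' @return The modified dataset; identical seed gives identical output.
#' @export
jitter_coordinates <- function(dataset, radius_m, seed,
                               record_seed = TRUE) {
  stopifnot(inherits(dataset, "wdds_dataset"), length(radius_m) == 1,
            radius_m > 0)
  if (missing(seed) || is.null(seed))
    stop("jittering requires an explicit seed; no implicit randomness")
  rec <- dataset$records
  n <- nrow(rec)
  ok <- !is.na(rec$latitude) & !is.na(rec$longitude) &
    abs(rec$latitude) <= 89.9
  if (any(!ok & !is.na(rec$latitude) & !is.na(rec$longitude)))
    dataset$findings <- rbind(dataset$findings,
      .finding("OBFUSCATION", "warning", NA_integer_, "latitude",
        "record(s) within 0.1 degrees of a pole skipped by jittering"))
  draws <- .run_seeded(seed, list(u = stats::runif(n),
                                  theta = stats::runif(n, 0, 2 * pi)))
  r <- radius_m * sqrt(draws$u)
  dlat <- r * cos(draws$theta) / .METERS_PER_DEGREE
  dlon <- r * sin(draws$theta) /
    (.METERS_PER_DEGREE * cos(rec$latitude * pi / 180))
  lat <- rec$latitude + dlat
  lon <- rec$longitude + dlon
  lon <- ((lon + 180) %% 360) - 180
  lon[!is.na(lon) & lon == -180] <- 180
  rec$latitude[ok] <- pmin(pmax(lat[ok], -90), 90)
  rec$longitude[ok] <- lon[ok]
  existing <- rec$spatial_uncertainty[ok]
  rec$spatial_uncertainty[ok] <- pmax(ifelse(is.na(existing), 0, existing),
                                      radius_m)
  dataset$records <- rec
  dataset$provenance <- c(dataset$provenance,
    list(.provenance_entry("jitter_coordinates",
      list(radius_m = radius_m,
           seed = if (record_seed) seed else "withheld",
           n_records = sum(ok)))))
  dataset
}

#' Great-circle distance between points
#'
#' Haversine distance in meters with Earth radius 6,371,000 m; the
#' verification oracle for jitter displacement bounds.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return Distance(s) in meters.
#' @export
displacement_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000)
}

#' Assert that a dataset still carries raw coordinates
#'
#' Fails when the provenance log records any coordinate obfuscation; used
#' by analyses that must not run on generalized locations.
#'
#' @param dataset a `wdds_dataset`.
#' @return `TRUE` invisibly, or an error.
#' @export
assert_raw_coordinates <- function(dataset) {
  methods <- vapply(dataset$provenance, function(p) p$method, "")
  obf <- methods %in% c("truncate_coordinates", "jitter_coordinates")
  if (any(obf))
    stop("dataset coordinates have been obfuscated (",
         paste(unique(methods[obf]), collapse = ", "),
         "); raw coordinates are not available")
  invisible(TRUE)
}
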