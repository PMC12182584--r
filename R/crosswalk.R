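# Darwin Core occurrence export. Fourteen core fields carry explicit
# Darwin Core equivalences; the exported row represents the HOST organism
# occurrence (scientificName = host identification), with parasite
# evidence carried in associatedOccurrences/occurrenceStatus. Both
# host-centric and parasite-centric conventions exist in the wild; this
# package follows the host-centric reading of the standard's own term
# annotations. Unmapped fields are appended verbatim with a "wdds:"
# prefix so the export is lossless.

#' Compose an ISO 8601 event date
#'
#' `"YYYY-MM-DD"` when day, month, and year are all present; `"YYYY-MM"`
#' when the day is blank; `"YYYY"` when only the year is known; blank when
#' the year is blank. A day without a month cannot be anchored and is
#' dropped (with a warning).
#'
#' @param day,month,year integer vectors (NA = blank).
#' @return Character vector of ISO 8601 dates (NA = blank).
#' @export
#' @examples
#' compose_event_date(23, 4, 2019)   # "2019-04-23"
#' compose_event_date(NA, NA, 2019)  # "2019"
compose_event_date <- function(day, month, year) {
  n <- max(length(day), length(month), length(year))
  day <- rep_len(day, n); month <- rep_len(month, n)
  year <- rep_len(year, n)
  orphan <- !is.na(day) & is.na(month) & !is.na(year)
  if (any(orphan))
    warning(sprintf("%d record(s) have a collection day but no month; day dropped from eventDate", sum(orphan)))
  out <- rep(NA_character_, n)
  has_y <- !is.na(year)
  out[has_y] <- sprintf("%04d", year[has_y])
  has_m <- has_y & !is.na(month)
  out[has_m] <- sprintf("%04d-%02d", year[has_m], month[has_m])
  has_d <- has_m & !is.na(day)
  out[has_d] <- sprintf("%04d-%02d-%02d", year[has_d], month[has_d],
                        day[has_d])
  out
}

.dwc_status <- function(outcome) {
  low <- tolower(outcome)
  ifelse(is.na(outcome), NA_character_,
         ifelse(low == "positive", "present",
                ifelse(low == "negative", "absent", NA_character_)))
}

#' Export a dataset as a Darwin Core occurrence table
#'
#' One output row per record. The 14 mapped fields are copied under their
#' Darwin Core term names (flat GBIF convention, namespace prefix
#' omitted); `occurrenceStatus` is `"present"` for positive outcomes,
#' `"absent"` for negative, and blank for inconclusive (to avoid
#' overclaiming, `"doubtful"` is not used); `eventDate` is composed from
#' the date parts; `occurrenceID` is `Sample ID + "|" + Detection target`
#' (best-effort uniqueness). Unmapped fields follow as `wdds:`-prefixed
#' verbatim columns.
#'
#' @param dataset a `wdds_dataset` (validate first; warnings are fine).
#' @param registry field registry.
#' @param path optional CSV output path.
#' @return Data frame of occurrences.
#' @export
to_darwin_core <- function(dataset, registry = core_registry(),
                           path = NULL) {
  rec <- dataset$records
  occ <- data.frame(
    occurrenceID = ifelse(is.na(rec$sample_id), NA_character_,
      paste0(rec$sample_id, "|",
             ifelse(is.na(rec$detection_target), "",
                    rec$detection_target))),
    decimalLatitude = rec$latitude,
    decimalLongitude = rec$longitude,
    coordinateUncertaintyInMeters = rec$spatial_uncertainty,
    day = rec$collection_day,
    month = rec$collection_month,
    year = rec$collection_year,
    eventDate = suppressWarnings(
      compose_event_date(rec$collection_day, rec$collection_month,
                         rec$collection_year)),
    scientificName = rec$host_identification,
    sex = rec$organism_sex,
    lifeStage = rec$host_life_stage,
    organismQuantity = rec$organism_quantity,
    organismQuantityType = rec$organism_quantity_units,
    occurrenceStatus = .dwc_status(rec$detection_outcome),
    associatedOccurrences = rec$detection_target,
    otherCatalogNumbers = rec$genbank_accession,
    stringsAsFactors = FALSE, row.names = NULL)
  unmapped <- registry$slug[!nzchar(registry$dwc_equivalent)]
  unmapped <- setdiff(unmapped,
                      c("collection_day", "collection_month",
                        "collection_year"))
  for (slug in unmapped) occ[[paste0("wdds:", slug)]] <- rec[[slug]]
  if (nrow(occ) == 0) occ <- occ[0, , drop = FALSE]
  if (!is.null(path))
    utils::write.csv(occ, path, row.names = FALSE, na = "")
  occ
}
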