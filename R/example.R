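# Packaged worked example: a single common vampire bat (Desmodus rotundus,
# animal BZ19-114) sampled in Belize in April 2019 and tested for
# coronaviruses by semi-nested PCR on RdRp. The oral swab was positive,
# identifying a novel alphacoronavirus (GenBank OM240578); the rectal
# swab was negative, so its parasite identification is blank.

#' The packaged worked-example dataset
#'
#' Two records — one positive, one negative test on two samples from one
#' vampire bat — transcribed from a published minimum-standard example.
#' The fixture is stored as a standard-conformant CSV (including a
#' Unicode minus sign in the longitude, as printed) and parsed on access,
#' so it also exercises the reader.
#'
#' @param with_metadata attach the illustrative project metadata
#'   (synthetic, assembled for documentation)? Default `FALSE`.
#' @return A `wdds_dataset` with 2 records.
#' @export
#' @examples
#' ds <- example_dataset()
#' n_records(ds)                 # 2
#' validate_wdds(ds)$conformant  # TRUE
example_dataset <- function(with_metadata = FALSE) {
  path <- system.file("extdata", "belize_bat_example.csv",
                      package = "wdds", mustWork = TRUE)
  ds <- read_wdds_csv(path)
  if (with_metadata) ds$metadata <- example_metadata()
  ds
}

#' Illustrative project metadata for the worked example
#'
#' A complete 24-property metadata document for the worked-example
#' project. The values are synthetic (assembled for documentation with
#' placeholder identifiers such as a DOI under the registrant test
#' prefix); the canonical metadata of the real project lives with its
#' archive deposit.
#'
#' @return A `wdds_metadata`.
#' @export
example_metadata <- function() {
  path <- system.file("extdata", "belize_bat_metadata_synthetic.json",
                      package = "wdds", mustWork = TRUE)
  read_wdds_metadata(path)
}
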