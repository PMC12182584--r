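# Persistent-identifier syntax checks and project-metadata validation.
# PIDs (DOI for works, ORCID for people, ROR for organizations, Crossref
# Funder IDs for funders) create the semantic links that make a deposited
# dataset findable; checks here are syntactic only — no network resolution.

#' Validate DOI syntax
#'
#' Accepts bare DOIs and common wrappers (`doi:`, `https://doi.org/`,
#' `https://dx.doi.org/`). A DOI is directory prefix `10.`, a 4-9 digit
#' registrant code, `/`, and a non-empty suffix.
#'
#' @param s character vector.
#' @return logical vector.
#' @export
#' @examples
#' validate_doi("10.3390/v9120364")        # TRUE
#' validate_doi("doi:10.3390/v9120364")    # TRUE
#' validate_doi("11.1234/x")               # FALSE
validate_doi <- function(s) {
  s <- trimws(as.character(s))
  s <- sub("(?i)^(https?://(dx\\.)?doi\\.org/|doi:)\\s*", "", s, perl = TRUE)
  !is.na(s) & grepl("^10\\.[0-9]{4,9}/.+$", s)
}

# ISO 7064 mod 11-2 check digit over the 15 base digits of an ORCID iD
.orcid_check_digit <- function(digits15) {
  total <- 0L
  for (d in digits15) total <- (total + d) * 2L
  rem <- total %% 11L
  chk <- (12L - rem) %% 11L
  if (chk == 10L) "X" else as.character(chk)
}

#' Validate ORCID iD syntax and checksum
#'
#' An ORCID iD is four hyphen-separated groups of four characters (digits;
#' the final character may be `X`), whose last character is the ISO 7064
#' mod 11-2 check digit over the 15 base digits. The `https://orcid.org/`
#' wrapper is stripped first.
#'
#' @param s character vector.
#' @return logical vector: `TRUE` iff format and checksum are both valid.
#' @export
#' @examples
#' validate_orcid("0000-0002-1825-0097")  # TRUE
#' validate_orcid("0000-0002-1825-0098")  # FALSE (bad check digit)
validate_orcid <- function(s) {
  s <- trimws(as.character(s))
  s <- sub("(?i)^https?://(www\\.)?orcid\\.org/", "", s, perl = TRUE)
  ok <- !is.na(s) &
    grepl("^[0-9]{4}-[0-9]{4}-[0-9]{4}-[0-9]{3}[0-9X]$", s)
  for (i in which(ok)) {
    chars <- strsplit(gsub("-", "", s[i]), "")[[1]]
    base <- as.integer(chars[1:15])
    ok[i] <- .orcid_check_digit(base) == chars[16]
  }
  ok
}

#' Validate ROR identifier syntax
#'
#' A ROR ID is a leading `0`, six characters from the Crockford base32
#' alphabet (digits and lowercase letters excluding i, l, o, u), and two
#' final digits. The `https://ror.org/` wrapper is stripped first. The
#' trailing digits are a mod 97-10 checksum in the registry specification;
#' syntax only is checked here.
#'
#' @param s character vector.
#' @return logical vector.
#' @export
#' @examples
#' validate_ror("https://ror.org/03v76x132")  # TRUE
#' validate_ror("3v76x132")                   # FALSE (no leading 0)
validate_ror <- function(s) {
  s <- trimws(as.character(s))
  s <- sub("(?i)^https?://ror\\.org/", "", s, perl = TRUE)
  !is.na(s) & grepl("^0[0-9abcdefghjkmnpqrstvwxyz]{6}[0-9]{2}$", s)
}

#' Validate a funder identifier
#'
#' Accepted as either a Crossref Funder ID (a DOI under the `10.13039`
#' prefix) or a ROR identifier.
#'
#' @param s character vector.
#' @return logical vector.
#' @export
validate_funder_id <- function(s) {
  bare <- sub("(?i)^(https?://(dx\\.)?doi\\.org/|doi:)\\s*", "",
              trimws(as.character(s)), perl = TRUE)
  (validate_doi(s) & grepl("^10\\.13039/", bare)) | validate_ror(s)
}

.pid_validators <- list(doi = validate_doi, orcid = validate_orcid,
                        ror = validate_ror, funder_id = validate_funder_id)

# flatten a metadata value (string, list of strings, or list of objects)
# into the character strings found under a given key or at the top level
.metadata_strings <- function(value) {
  if (is.null(value)) return(character(0))
  if (is.character(value)) return(value)
  if (is.numeric(value)) return(as.character(value))
  if (is.list(value))
    return(unlist(lapply(value, .metadata_strings), use.names = FALSE))
  character(0)
}

.metadata_blank <- function(value) {
  v <- .metadata_strings(value)
  length(v) == 0 || all(!nzchar(trimws(v)))
}

#' Validate project metadata
#'
#' Checks that required properties are populated and that every populated
#' persistent-identifier slot matches its PID syntax. Issues use the same
#' schema as dataset validation and are merged into the dataset report by
#' [validate_wdds()] when metadata is attached.
#'
#' @param metadata a `wdds_metadata` (from [read_wdds_metadata()]).
#' @param registry metadata registry.
#' @return Data frame of issues.
#' @export
validate_metadata <- function(metadata, registry = metadata_registry()) {
  stopifnot(inherits(metadata, "wdds_metadata"))
  iss <- .empty_findings()
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    val <- metadata$values[[nm]]
    if (registry$required[i] && .metadata_blank(val))
      iss <- rbind(iss, .finding("REQ_FIELD", "error", NA_integer_,
        registry$slug[i],
        sprintf("required metadata property '%s' is missing or blank", nm)))
    pk <- registry$pid_kind[i]
    if (nzchar(pk) && !.metadata_blank(val)) {
      vals <- .metadata_strings(val)
      bad <- vals[!.pid_validators[[pk]](vals)]
      for (b in bad)
        iss <- rbind(iss, .finding("PID_SYNTAX", "error", NA_integer_,
          registry$slug[i],
          sprintf("'%s' is not a syntactically valid %s", b, toupper(pk))))
    }
  }
  iss
}
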