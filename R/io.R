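# Standard-conformant flat-file I/O. One row = one diagnostic-test result.
# Blank is a first-class state (NA in typed slots, empty cell on disk);
# placeholder tokens like "NA" never survive parsing into a typed slot.

# tokens converted to blank with a PLACEHOLDER finding (case-insensitive)
.placeholder_tokens <- c("na", "n/a", "nan", "null", "none", "-", ".")

.empty_findings <- function() {
  data.frame(rule = character(), severity = character(),
             record = integer(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

.finding <- function(rule, severity, record, field, message) {
  data.frame(rule = rule, severity = severity,
             record = as.integer(record), field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Construct a dataset object
#'
#' Low-level constructor used by the reader and the synthetic generator.
#' `records` may contain any subset of the registry's slug-named columns
#' (missing ones are created blank) plus extra columns, which are preserved
#' verbatim.
#'
#' @param records data frame of records, one row per diagnostic-test result.
#' @param registry field registry, defaults to [core_registry()].
#' @param pooled_links optional data frame with columns `sample_id`,
#'   `animal_id` linking pooled samples to individual animals.
#' @param metadata optional `wdds_metadata` object.
#' @param provenance list of provenance entries (appended to, never
#'   rewritten).
#' @param findings data frame of parse findings.
#' @param core_present slugs of core columns that were present in the
#'   source (used to report missing required columns); defaults to all.
#' @return A `wdds_dataset` object.
#' @export
wdds_dataset <- function(records, registry = core_registry(),
                         pooled_links = NULL, metadata = NULL,
                         provenance = list(), findings = .empty_findings(),
                         core_present = registry$slug) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  proto <- list(text = NA_character_, number = NA_real_,
                integer = NA_integer_, boolean = NA)
  for (i in seq_len(nrow(registry))) {
    slug <- registry$slug[i]
    if (is.null(records[[slug]]))
      records[[slug]] <- rep(proto[[registry$value_kind[i]]],
                             length.out = nrow(records))
  }
  extra <- setdiff(names(records), registry$slug)
  records <- records[, c(registry$slug, extra), drop = FALSE]
  structure(list(records = records,
                 extra_fields = extra,
                 core_present = core_present,
                 pooled_links = pooled_links,
                 metadata = metadata,
                 provenance = provenance,
                 findings = findings),
            class = "wdds_dataset")
}

#' @export
print.wdds_dataset <- function(x, ...) {
  cat(sprintf("<wdds_dataset: %d record%s, %d extra field%s%s%s>\n",
              nrow(x$records), if (nrow(x$records) == 1) "" else "s",
              length(x$extra_fields),
              if (length(x$extra_fields) == 1) "" else "s",
              if (!is.null(x$pooled_links))
                sprintf(", %d pooled link(s)", nrow(x$pooled_links)) else "",
              if (length(x$provenance))
                sprintf(", %d provenance entr%s", length(x$provenance),
                        if (length(x$provenance) == 1) "y" else "ies")
              else ""))
  invisible(x)
}

#' Number of records
#' @param x a `wdds_dataset`.
#' @export
n_records <- function(x) nrow(x$records)

# -- UTF-8 checking ---------------------------------------------------------

# first invalid byte offset (1-based) in a raw vector, or NA if valid UTF-8
.utf8_invalid_offset <- function(raw) {
  n <- length(raw)
  b <- as.integer(raw)
  i <- 1L
  while (i <= n) {
    x <- b[i]
    need <- if (x < 0x80) 0L
    else if (x >= 0xC2 && x <= 0xDF) 1L
    else if (x >= 0xE0 && x <= 0xEF) 2L
    else if (x >= 0xF0 && x <= 0xF4) 3L
    else return(i)
    if (need > 0L) {
      if (i + need > n) return(i)
      cont <- b[(i + 1L):(i + need)]
      if (any(cont < 0x80 | cont > 0xBF)) return(i)
    }
    i <- i + 1L + need
  }
  NA_integer_
}

.read_text <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(file)) stop("cannot read file: ", file)
    raw <- readBin(file, "raw", n = file.size(file))
  } else {
    raw <- charToRaw(enc2utf8(paste(text, collapse = "\n")))
  }
  if (any(raw == as.raw(0)))
    stop("undecodable input: embedded NUL at byte ",
         which(raw == as.raw(0))[1])
  off <- .utf8_invalid_offset(raw)
  if (!is.na(off))
    stop("undecodable input: invalid UTF-8 at byte ", off)
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  sub("^\ufeff", "", txt)  # strip BOM
}

# -- cell typing ------------------------------------------------------------

.parse_number <- function(x) {
  x <- gsub("−", "-", x)          # Unicode minus to ASCII hyphen
  suppressWarnings(as.numeric(x))
}

.parse_cells <- function(raw, kind, slug, rows) {
  # raw: character vector (already whitespace-stripped, placeholders blanked
  # to NA); returns list(values, findings)
  findings <- .empty_findings()
  blank <- is.na(raw) | raw == ""
  if (kind == "text") {
    v <- ifelse(blank, NA_character_, raw)
    if (slug == "detection_outcome") {
      low <- tolower(v)
      v <- ifelse(!is.na(v) & low %in% .outcome_vocab, low, v)
    }
    return(list(values = v, findings = findings))
  }
  if (kind == "boolean") {
    low <- tolower(raw)
    v <- rep(NA, length(raw))
    v[!blank & low == "true"] <- TRUE
    v[!blank & low == "false"] <- FALSE
    bad <- !blank & !(low %in% c("true", "false"))
    for (j in which(bad))
      findings <- rbind(findings, .finding("TYPE", "error", rows[j], slug,
        sprintf("value '%s' is not TRUE/FALSE", raw[j])))
    return(list(values = v, findings = findings))
  }
  num <- .parse_number(raw)
  bad <- !blank & is.na(num)
  if (kind == "integer") {
    nonint <- !blank & !is.na(num) & num != trunc(num)
    bad <- bad | nonint
    num[nonint] <- NA_real_
  }
  for (j in which(bad))
    findings <- rbind(findings, .finding("TYPE", "error", rows[j], slug,
      sprintf("value '%s' is not a valid %s", raw[j], kind)))
  num[blank] <- NA_real_
  v <- if (kind == "integer") as.integer(num) else num
  list(values = v, findings = findings)
}

# -- reader -----------------------------------------------------------------

#' Read a standard-conformant CSV file
#'
#' Reads a UTF-8, comma-separated, period-decimal flat file where each row
#' is one diagnostic-test result. Header names are matched to the registry
#' case-insensitively after slugging, so both the printed field labels
#' ("Sample ID") and their slugs ("sample_id") are accepted; unmatched
#' columns are preserved as extra fields. Leading/trailing whitespace is
#' stripped, the Unicode minus sign is normalized before numeric parsing,
#' and placeholder tokens ("NA", "N/A", "NaN", "NULL", "NONE", "-", ".")
#' are converted to blank with a warning finding — the standard requires
#' genuinely empty cells for missing or inapplicable values.
#'
#' @param file path to a CSV file (or `NULL` when `text` is given).
#' @param registry field registry, defaults to [core_registry()].
#' @param text optional literal CSV text instead of a file.
#' @param pooled_links optional path to (or data frame of) a two-column
#'   `sample_id,animal_id` side table linking pooled samples to animals.
#' @return A [wdds_dataset()]; parse findings (placeholders, type failures)
#'   are in `$findings` and are merged into reports by [validate_wdds()].
#'   Undecodable bytes, duplicate headers, and ragged rows are hard errors.
#' @export
read_wdds_csv <- function(file = NULL, registry = core_registry(),
                          text = NULL, pooled_links = NULL) {
  txt <- .read_text(file, text)
  if (!nzchar(gsub("[\r\n]", "", txt))) stop("input is empty")
  nfields <- utils::count.fields(textConnection(txt), sep = ",",
                                 quote = "\"", blank.lines.skip = TRUE)
  if (length(nfields) && any(!is.na(nfields) & nfields != nfields[1])) {
    bad <- which(!is.na(nfields) & nfields != nfields[1])[1]
    stop(sprintf("ragged row %d: %d cells, expected %d (header)",
                 bad - 1L, nfields[bad], nfields[1]))
  }
  df <- utils::read.csv(text = txt, header = TRUE, check.names = FALSE,
                        colClasses = "character",
                        na.strings = character(0), quote = "\"",
                        comment.char = "", blank.lines.skip = TRUE,
                        fileEncoding = "")
  headers <- names(df)
  if (anyDuplicated(headers))
    stop("duplicate header name: ", headers[duplicated(headers)][1])
  slugged <- wdds_slug(headers)
  is_core <- slugged %in% registry$slug
  core_slugs <- slugged[is_core]
  if (anyDuplicated(core_slugs))
    stop("duplicate header name (maps to the same standard field): ",
         core_slugs[duplicated(core_slugs)][1])

  n <- nrow(df)
  rows <- seq_len(n)
  findings <- .empty_findings()
  records <- data.frame(row.names = rows)
  for (i in seq_len(nrow(registry))) {
    slug <- registry$slug[i]
    j <- match(slug, slugged)
    if (is.na(j)) next
    raw <- trimws(df[[j]])
    ph <- !is.na(raw) & tolower(raw) %in% .placeholder_tokens
    for (k in which(ph))
      findings <- rbind(findings, .finding("PLACEHOLDER", "warning", k, slug,
        sprintf("placeholder value '%s' converted to blank; leave cells empty instead", raw[k])))
    raw[ph] <- NA_character_
    parsed <- .parse_cells(raw, registry$value_kind[i], slug, rows)
    records[[slug]] <- parsed$values
    findings <- rbind(findings, parsed$findings)
  }
  extras <- which(!is_core)
  for (j in extras) records[[headers[j]]] <- df[[j]]

  links <- NULL
  if (!is.null(pooled_links)) {
    links <- if (is.data.frame(pooled_links)) pooled_links
    else utils::read.csv(pooled_links, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
    names(links) <- wdds_slug(names(links))
    if (!all(c("sample_id", "animal_id") %in% names(links)))
      stop("pooled-links table must have columns sample_id, animal_id")
    links <- links[, c("sample_id", "animal_id")]
  }
  wdds_dataset(records, registry, pooled_links = links,
               findings = findings, core_present = core_slugs)
}

# -- writer -----------------------------------------------------------------

# shortest decimal representation that round-trips the double exactly
.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in 1:17) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

.csv_quote <- function(x) {
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write a dataset as a standard-conformant CSV
#'
#' UTF-8, comma delimiter, period decimal separator, LF line endings.
#' Blank cells are written empty, never as "NA". Core columns come first in
#' registry order (printed field labels as headers), then extra fields in
#' first-seen order. Reading the output back recovers all typed slots and
#' extras exactly.
#'
#' @param dataset a `wdds_dataset`.
#' @param path optional output path; when `NULL` the CSV text is returned.
#' @param registry field registry, defaults to [core_registry()].
#' @return The CSV text (invisibly when `path` is given).
#' @export
write_wdds_csv <- function(dataset, path = NULL, registry = core_registry()) {
  rec <- dataset$records
  cols <- character(0)
  headers <- character(0)
  body <- list()
  for (i in seq_len(nrow(registry))) {
    slug <- registry$slug[i]
    v <- rec[[slug]]
    cell <- switch(registry$value_kind[i],
      text = ifelse(is.na(v), "", v),
      number = .fmt_num(v),
      integer = ifelse(is.na(v), "", format(v, trim = TRUE)),
      boolean = ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE")))
    body[[length(body) + 1L]] <- cell
    headers <- c(headers, registry$name[i])
  }
  for (ex in dataset$extra_fields) {
    v <- rec[[ex]]
    body[[length(body) + 1L]] <- ifelse(is.na(v), "", as.character(v))
    headers <- c(headers, ex)
  }
  lines <- paste(c(
    paste(.csv_quote(headers), collapse = ","),
    if (nrow(rec)) vapply(seq_len(nrow(rec)), function(r)
      paste(vapply(body, function(col) .csv_quote(col[r]), ""),
            collapse = ","), "")),
    collapse = "\n")
  out <- paste0(lines, "\n")
  if (is.null(path)) return(out)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(out)), con)
  invisible(out)
}

# -- project metadata -------------------------------------------------------

#' Read a project-metadata JSON document
#'
#' Properties are matched to the metadata registry by name
#' (case-insensitively after slugging); unknown properties are preserved in
#' `$extras`. Values are kept as parsed (strings, numbers, or lists for
#' multi-valued properties such as creators).
#'
#' @param file path to a JSON document (or `NULL` when `text` given).
#' @param registry metadata registry, defaults to [metadata_registry()].
#' @param text optional literal JSON text.
#' @return A `wdds_metadata` object: list with `$values` (named by registry
#'   property name) and `$extras`.
#' @export
read_wdds_metadata <- function(file = NULL, registry = metadata_registry(),
                               text = NULL) {
  txt <- if (is.null(text)) .read_text(file) else paste(text, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed metadata JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (!is.list(doc)) stop("metadata JSON must be an object")
  values <- stats::setNames(vector("list", nrow(registry)), registry$name)
  extras <- list()
  slugs <- registry$slug
  for (nm in names(doc)) {
    j <- match(wdds_slug(nm), slugs)
    if (is.na(j)) extras[[nm]] <- doc[[nm]]
    else values[[registry$name[j]]] <- doc[[nm]]
  }
  structure(list(values = values, extras = extras), class = "wdds_metadata")
}

#' @export
print.wdds_metadata <- function(x, ...) {
  filled <- sum(!vapply(x$values, is.null, TRUE))
  cat(sprintf("<wdds_metadata: %d/%d properties populated, %d extra>\n",
              filled, length(x$values), length(x$extras)))
  invisible(x)
}

# -- JSON record serialization (convert + schema checking) ------------------

#' Serialize records as JSON-ready objects
#'
#' One named list per record, one member per core field in registry order;
#' blank cells become `NULL` (JSON `null`). Extra fields are appended after
#' the core fields. These objects are what the emitted JSON Schema
#' validates.
#'
#' @param dataset a `wdds_dataset`.
#' @param registry field registry.
#' @param extras include extra fields? default `TRUE`.
#' @return A list of named lists.
#' @export
as_record_objects <- function(dataset, registry = core_registry(),
                              extras = TRUE) {
  rec <- dataset$records
  cols <- registry$slug
  if (extras) cols <- c(cols, dataset$extra_fields)
  lapply(seq_len(nrow(rec)), function(r) {
    obj <- lapply(cols, function(cl) {
      v <- rec[[cl]][r]
      if (is.na(v)) NULL else if (is.integer(v)) as.integer(v) else v
    })
    names(obj) <- cols
    obj
  })
}
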