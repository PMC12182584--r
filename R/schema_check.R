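# Minimal evaluator for the JSON Schema subset the package emits
# (object type, nullable/union types, enum, required, allOf with
# if/then). It walks the schema DOCUMENT — typically re-parsed from its
# serialized JSON — rather than the field registry, so it provides an
# independent route for checking that the emitted schema and the native
# validator make the same accept/reject decisions on a record.

.js_type_ok <- function(val, types) {
  any(vapply(types, function(t) switch(t,
    "null" = is.null(val),
    "string" = is.character(val) && length(val) == 1,
    "number" = is.numeric(val) && length(val) == 1 && !is.logical(val),
    "integer" = is.numeric(val) && length(val) == 1 && !is.logical(val) &&
      val == trunc(val),
    "boolean" = is.logical(val) && length(val) == 1,
    "object" = is.list(val),
    FALSE), TRUE))
}

.js_subschema_ok <- function(sub, val) {
  if (!is.null(sub$type) && !.js_type_ok(val, unlist(sub$type)))
    return(FALSE)
  if (!is.null(sub$enum)) {
    hit <- vapply(sub$enum, function(e)
      (is.null(e) && is.null(val)) || identical(e, val), TRUE)
    if (!any(hit)) return(FALSE)
  }
  TRUE
}

#' Check a record object against a JSON Schema document
#'
#' Evaluates the schema subset emitted by [emit_json_schema()] (types
#' including unions with `"null"`, `enum`, `required`, `allOf`/`if`/
#' `then`) against one record serialized as a named list with `NULL` for
#' blank cells (see [as_record_objects()]).
#'
#' @param schema schema as a nested list, e.g.
#'   `jsonlite::fromJSON(wdds_schema_json(), simplifyVector = FALSE)`.
#' @param record named list, one member per field, `NULL` = blank.
#' @return `TRUE` iff the record satisfies the schema.
#' @export
schema_accepts <- function(schema, record) {
  if (!is.null(schema$required) &&
      !all(unlist(schema$required) %in% names(record)))
    return(FALSE)
  props <- schema$properties
  for (nm in intersect(names(props), names(record)))
    if (!.js_subschema_ok(props[[nm]], record[[nm]]))
      return(FALSE)
  for (sub in schema$allOf) {
    if (!is.null(sub$`if`)) {
      cond <- sub$`if`$properties
      applies <- all(vapply(names(cond), function(nm)
        .js_subschema_ok(cond[[nm]], record[[nm]]), TRUE))
      if (applies && !is.null(sub$then)) {
        thenp <- sub$then$properties
        okth <- all(vapply(names(thenp), function(nm)
          .js_subschema_ok(thenp[[nm]], record[[nm]]), TRUE))
        if (!is.null(sub$then$required) &&
            !all(unlist(sub$then$required) %in% names(record)))
          okth <- FALSE
        if (!okth) return(FALSE)
      }
    } else if (!schema_accepts(sub, record)) return(FALSE)
  }
  TRUE
}

#' Generate fuzzed raw record cells for validator testing
#'
#' Produces `n` records as named character vectors of raw CSV cells over
#' the core fields, mixing valid values, blanks, junk tokens in typed
#' slots, and out-of-vocabulary outcomes. Used to check that the emitted
#' JSON Schema and the native validator agree on accept/reject decisions
#' (restricted to requiredness, vocabulary, and type rules).
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param registry field registry.
#' @return List of named character vectors (slug -> raw cell).
#' @export
fuzz_record_cells <- function(n, seed, registry = core_registry()) {
  .run_seeded(seed, {
    base <- c(sample_id = "S-001", animal_id = "A-001",
              latitude = "17.5", longitude = "-88.5",
              collection_day = "23", collection_month = "4",
              collection_year = "2019",
              sample_collection_method = "swab",
              host_identification = "Desmodus rotundus",
              live_capture = "TRUE",
              mass = "0.023", mass_units = "kg",
              detection_target = "Coronaviridae",
              detection_method = "PCR",
              detection_outcome = "positive",
              parasite_identification = "Alphacoronavirus sp.")
    pool <- list(
      text = c("", "open text", "swab"),
      number = c("", "1.5", "-3.25", "abc", "42"),
      integer = c("", "7", "2.5", "abc"),
      boolean = c("", "TRUE", "false", "maybe"))
    outcome_pool <- c("positive", "negative", "inconclusive", "Positive",
                      "detected", "", "0")
    lapply(seq_len(n), function(i) {
      cells <- stats::setNames(rep("", nrow(registry)), registry$slug)
      cells[names(base)] <- base
      k <- sample(1:5, 1)
      for (slug in sample(registry$slug, k)) {
        kind <- registry$value_kind[registry$slug == slug]
        cells[slug] <- if (slug == "detection_outcome")
          sample(outcome_pool, 1) else sample(pool[[kind]], 1)
      }
      cells
    })
  })
}

#' Convert raw cells to a JSON-style record object
#'
#' Independent of the CSV parser: numbers and booleans are converted
#' where they parse, anything else is kept as a string (which the schema
#' will reject in a typed slot); blanks become `NULL`; the detection
#' outcome is case-folded when it matches the closed vocabulary, as a
#' serializer of parsed records would do.
#'
#' @param cells named character vector (slug -> raw cell).
#' @param registry field registry.
#' @return Named list, `NULL` = blank.
#' @export
cells_to_object <- function(cells, registry = core_registry()) {
  obj <- lapply(registry$slug, function(slug) {
    v <- trimws(cells[[slug]])
    if (!nzchar(v)) return(NULL)
    kind <- registry$value_kind[registry$slug == slug]
    if (slug == "detection_outcome" && tolower(v) %in% .outcome_vocab)
      return(tolower(v))
    if (kind %in% c("number", "integer")) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) return(num)
      return(v)
    }
    if (kind == "boolean") {
      if (tolower(v) == "true") return(TRUE)
      if (tolower(v) == "false") return(FALSE)
      return(v)
    }
    v
  })
  names(obj) <- registry$slug
  obj
}
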