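# Rule-based validator. Every rule derivable from the field definitions and
# the standard's best-practice guidance is applied to a parsed dataset and
# reported as an addressable, rule-tagged issue. A dataset is conformant
# iff its report contains zero error-severity issues; warnings flag
# best-practice deviations without blocking conformance.

#' The validation rule registry
#'
#' Closed registry of rule identifiers used in validation reports.
#' `scope` says where a rule fires: `parse` rules are detected while
#' reading a file, `record` rules on single rows, `dataset` rules across
#' rows or side tables, `metadata` rules on project metadata.
#'
#' @return A data frame with columns `rule_id`, `severity`, `scope`,
#'   `description`.
#' @export
wdds_rules <- function() {
  r <- function(rule_id, severity, scope, description)
    data.frame(rule_id = rule_id, severity = severity, scope = scope,
               description = description, stringsAsFactors = FALSE)
  rbind(
    r("REQ_FIELD", "error", "record",
      "A required column is missing, or a required cell is blank (detection target/method/outcome are exempt on records of untested samples; parasite identification is governed by POS_NO_ID)."),
    r("TYPE", "error", "parse",
      "A cell could not be parsed into the field's declared type (number, integer, or TRUE/FALSE)."),
    r("VOCAB", "error", "record",
      "Detection outcome is outside the closed vocabulary {positive, negative, inconclusive} (case-insensitive)."),
    r("UNITS_PAIR", "error", "record",
      "A measurement (age, mass, length, organism quantity) is populated but its units field (and, for length, the measurement axis) is blank."),
    r("COORD_RANGE", "error", "record",
      "Latitude outside [-90, 90] or longitude outside [-180, 180]."),
    r("UNCERT_RANGE", "error", "record",
      "Spatial uncertainty is negative."),
    r("DATE_VALID", "error", "record",
      "Collection day/month/year name an impossible calendar date; partial dates (blank day and/or month) are legal."),
    r("PLACEHOLDER", "warning", "record",
      "A placeholder token ('NA', 'NULL', ...) was found where a blank cell belongs, or coordinates are exactly (0, 0)."),
    r("POS_NO_ID", "warning", "record",
      "Detection outcome is positive but no parasite identification is given."),
    r("NEG_WITH_ID", "error", "record",
      "Detection outcome is negative but a parasite identification is present; parasite identity must be empty for negative results."),
    r("DUP_ROW", "warning", "dataset",
      "A row duplicates another row exactly (one sample may legitimately be tested several times, so duplicates are flagged, not rejected)."),
    r("XREC_CONFLICT", "warning", "dataset",
      "Rows sharing an Animal ID disagree on host identification or organism sex (life stage and measurements may legitimately change)."),
    r("POOL_LINK", "error", "dataset",
      "A pooled-links side-table entry references a Sample ID absent from the records."),
    r("NEST_CYCLE", "error", "dataset",
      "Nested detections (Parasite ID reused as Animal ID) form a cycle."),
    r("PID_SYNTAX", "error", "metadata",
      "A persistent identifier (DOI, ORCID, ROR, funder ID) does not match its required syntax."),
    r("OBFUSCATION", "warning", "process",
      "A record was skipped during coordinate obfuscation (blank coordinates, or latitude too close to a pole to jitter).")
  )
}

.units_pairs <- function(registry) {
  dep <- registry[nzchar(registry$depends_on), c("slug", "depends_on")]
  dep
}

# record: named list or one-row data frame with typed slots
.validate_record_row <- function(rec, registry, row) {
  iss <- .empty_findings()
  add <- function(rule, sev, field, msg)
    rbind(iss, .finding(rule, sev, row, field, msg))
  blank <- function(slug) is.na(rec[[slug]])
  tested <- !blank("detection_outcome")

  # required cells
  for (i in which(registry$required)) {
    slug <- registry$slug[i]
    cond <- registry$cell_required_when[i]
    need <- if (cond == "tested") tested
            else if (cond == "outcome_positive") FALSE  # POS_NO_ID handles
            else TRUE
    if (need && blank(slug))
      iss <- add("REQ_FIELD", "error", slug,
                 sprintf("required field '%s' is blank", registry$name[i]))
  }

  # closed vocabulary
  out <- rec[["detection_outcome"]]
  if (!is.na(out) && !(tolower(out) %in% .outcome_vocab))
    iss <- add("VOCAB", "error", "detection_outcome",
               sprintf("detection outcome '%s' is not one of positive/negative/inconclusive", out))

  # units accompany measurements
  dep <- .units_pairs(registry)
  for (k in seq_len(nrow(dep)))
    if (!blank(dep$depends_on[k]) && blank(dep$slug[k]))
      iss <- add("UNITS_PAIR", "error", dep$slug[k],
                 sprintf("'%s' is populated but '%s' is blank",
                         dep$depends_on[k], dep$slug[k]))

  # coordinates
  lat <- rec[["latitude"]]; lon <- rec[["longitude"]]
  if (!is.na(lat) && (lat < -90 || lat > 90))
    iss <- add("COORD_RANGE", "error", "latitude",
               sprintf("latitude %s outside [-90, 90]", format(lat)))
  if (!is.na(lon) && (lon < -180 || lon > 180))
    iss <- add("COORD_RANGE", "error", "longitude",
               sprintf("longitude %s outside [-180, 180]", format(lon)))
  if (!is.na(lat) && !is.na(lon) && lat == 0 && lon == 0)
    iss <- add("PLACEHOLDER", "warning", "latitude",
               "coordinates are exactly (0, 0); likely a placeholder location")
  su <- rec[["spatial_uncertainty"]]
  if (!is.na(su) && su < 0)
    iss <- add("UNCERT_RANGE", "error", "spatial_uncertainty",
               sprintf("spatial uncertainty %s is negative", format(su)))

  # calendar date; partial dates are legal
  d <- rec[["collection_day"]]; m <- rec[["collection_month"]]
  y <- rec[["collection_year"]]
  if (!is.na(m) && (m < 1 || m > 12))
    iss <- add("DATE_VALID", "error", "collection_month",
               sprintf("month %d outside [1, 12]", m))
  if (!is.na(d) && (d < 1 || d > 31))
    iss <- add("DATE_VALID", "error", "collection_day",
               sprintf("day %d outside [1, 31]", d))
  if (!is.na(d) && !is.na(m) && !is.na(y) &&
      d >= 1 && d <= 31 && m >= 1 && m <= 12) {
    if (is.na(as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")))
      iss <- add("DATE_VALID", "error", "collection_day",
                 sprintf("%d-%02d-%02d is not a real calendar date", y, m, d))
  }

  # parasite identity vs outcome
  pid <- rec[["parasite_identification"]]
  if (!is.na(out) && tolower(out) == "positive" && is.na(pid))
    iss <- add("POS_NO_ID", "warning", "parasite_identification",
               "positive outcome without a parasite identification")
  if (!is.na(out) && tolower(out) == "negative" && !is.na(pid))
    iss <- add("NEG_WITH_ID", "error", "parasite_identification",
               sprintf("negative outcome but parasite identification '%s' is present", pid))
  iss
}

#' Validate a single record
#'
#' Applies all record-scope rules to one record (a named list or one-row
#' data frame with typed slots, as produced by [read_wdds_csv()]).
#'
#' @param record named list / one-row data frame of typed slots.
#' @param registry field registry.
#' @param row source row number used in issue addresses.
#' @return A data frame of issues (possibly empty).
#' @export
validate_record <- function(record, registry = core_registry(), row = 1L) {
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  for (slug in registry$slug) if (is.null(record[[slug]]))
    record[[slug]] <- NA
  .validate_record_row(record, registry, row)
}

# nesting adjacency: host animal_id -> parasite_ids that reappear as animal
# ids. Animal-ID and Parasite-ID share one identifier namespace.
.nesting_edges <- function(records) {
  pid <- records$parasite_id
  aid <- records$animal_id
  has <- !is.na(pid) & pid %in% aid[!is.na(aid)]
  host <- aid[has]
  child <- pid[has]
  keep <- !is.na(host) & host != child
  unique(data.frame(host = host[keep], child = child[keep],
                    stringsAsFactors = FALSE))
}

# TRUE when directed edges contain a cycle
.has_cycle <- function(edges) {
  if (nrow(edges) == 0) return(FALSE)
  nodes <- unique(c(edges$host, edges$child))
  indeg <- stats::setNames(numeric(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.numeric(tab)
  remaining <- edges
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- remaining$child[remaining$host == v]
    remaining <- remaining[remaining$host != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  seen < length(nodes)
}

#' Validate a dataset
#'
#' Runs all per-record rules, cross-record checks (duplicate rows,
#' conflicting animal attributes, pooled-link integrity, nesting cycles),
#' merges parse-time findings, and validates project metadata when
#' present. The dataset is conformant iff no error-severity issue is
#' found.
#'
#' @param dataset a `wdds_dataset`.
#' @param registry field registry.
#' @return A `wdds_report`: list with `issues` (data frame), `n_errors`,
#'   `n_warnings`, and `conformant`.
#' @export
validate_wdds <- function(dataset, registry = core_registry()) {
  stopifnot(inherits(dataset, "wdds_dataset"))
  rec <- dataset$records
  iss <- dataset$findings

  # required columns must exist
  missing_cols <- setdiff(registry$slug[registry$required],
                          dataset$core_present)
  for (slug in missing_cols)
    iss <- rbind(iss, .finding("REQ_FIELD", "error", NA_integer_, slug,
      sprintf("required column '%s' is missing",
              registry$name[registry$slug == slug])))

  # record-scope rules (skip cell-level REQ for absent columns already
  # reported above: the cells are uniformly blank)
  for (r in seq_len(nrow(rec))) {
    ri <- .validate_record_row(as.list(rec[r, registry$slug, drop = FALSE]),
                               registry, r)
    if (length(missing_cols))
      ri <- ri[!(ri$rule == "REQ_FIELD" & ri$field %in% missing_cols), ,
               drop = FALSE]
    iss <- rbind(iss, ri)
  }

  # duplicate rows (byte-identical across all columns)
  if (nrow(rec) > 1) {
    key <- do.call(paste, c(lapply(rec, function(v)
      ifelse(is.na(v), "\x01", as.character(v))), sep = "\x02"))
    for (r in which(duplicated(key)))
      iss <- rbind(iss, .finding("DUP_ROW", "warning", r, NA_character_,
        sprintf("row %d duplicates row %d exactly", r, match(key[r], key))))
  }

  # cross-record consistency per animal
  aid <- rec$animal_id
  for (a in unique(aid[!is.na(aid)])) {
    rows <- which(!is.na(aid) & aid == a)
    if (length(rows) < 2) next
    for (fld in c("host_identification", "organism_sex")) {
      vals <- unique(stats::na.omit(rec[[fld]][rows]))
      if (length(vals) > 1)
        iss <- rbind(iss, .finding("XREC_CONFLICT", "warning", rows[2], fld,
          sprintf("animal '%s' has conflicting %s values: %s", a, fld,
                  paste(sQuote(vals, q = FALSE), collapse = ", "))))
    }
  }

  # pooled-links integrity
  if (!is.null(dataset$pooled_links) && nrow(dataset$pooled_links)) {
    dangling <- !(dataset$pooled_links$sample_id %in% rec$sample_id)
    for (k in which(dangling))
      iss <- rbind(iss, .finding("POOL_LINK", "error", NA_integer_,
        "sample_id",
        sprintf("pooled-links entry references unknown sample '%s'",
                dataset$pooled_links$sample_id[k])))
  }

  # nesting cycles
  if (.has_cycle(.nesting_edges(rec)))
    iss <- rbind(iss, .finding("NEST_CYCLE", "error", NA_integer_,
      "parasite_id",
      "nested detections form a cycle of Parasite ID / Animal ID reuse"))

  # project metadata
  if (!is.null(dataset$metadata))
    iss <- rbind(iss, validate_metadata(dataset$metadata))

  rownames(iss) <- NULL
  new_wdds_report(iss)
}

#' @rdname validate_wdds
#' @export
validate_dataset <- validate_wdds

new_wdds_report <- function(issues) {
  n_err <- sum(issues$severity == "error")
  n_warn <- sum(issues$severity == "warning")
  structure(list(issues = issues, n_errors = n_err, n_warnings = n_warn,
                 conformant = n_err == 0L),
            class = "wdds_report")
}

#' @export
print.wdds_report <- function(x, ...) {
  cat(sprintf("Validation report: %s (%d error%s, %d warning%s)\n",
              if (x$conformant) "CONFORMANT" else "NOT conformant",
              x$n_errors, if (x$n_errors == 1) "" else "s",
              x$n_warnings, if (x$n_warnings == 1) "" else "s"))
  if (nrow(x$issues)) {
    iss <- x$issues
    addr <- ifelse(is.na(iss$record), "dataset",
                   paste0("row ", iss$record))
    addr <- ifelse(is.na(iss$field), addr, paste0(addr, ":", iss$field))
    cat(sprintf("  [%s] %-13s %-28s %s\n", substr(iss$severity, 1, 1),
                iss$rule, addr, iss$message), sep = "")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `wdds_report`.
#' @param path optional output path.
#' @return JSON text (invisibly when `path` given).
#' @export
report_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(
    list(conformant = report$conformant, n_errors = report$n_errors,
         n_warnings = report$n_warnings, issues = report$issues),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Advisory fit-for-purpose check
#'
#' Summarizes whether the dataset carries the elements every record of a
#' wildlife disease dataset should include — host identification,
#' diagnostic method, test outcome, a parasite-identification column, the
#' date, and the location of sampling — and at what completeness. Purely
#' advisory; does not affect conformance.
#'
#' @param dataset a `wdds_dataset`.
#' @param registry field registry.
#' @return Data frame with columns `element`, `present`, `completeness`
#'   (fraction of records populated; for parasite identification, the
#'   fraction of positive records identified).
#' @export
check_fit_for_purpose <- function(dataset, registry = core_registry()) {
  rec <- dataset$records
  n <- nrow(rec)
  frac <- function(ok) if (n == 0) 0 else sum(ok) / n
  out <- rec$detection_outcome
  pos <- !is.na(out) & tolower(out) == "positive"
  pid_comp <- if (!any(pos)) frac(!is.na(rec$parasite_identification))
              else sum(pos & !is.na(rec$parasite_identification)) / sum(pos)
  res <- data.frame(
    element = c("host identification", "diagnostic method",
                "detection outcome", "parasite identification",
                "sampling date", "sampling location"),
    completeness = c(frac(!is.na(rec$host_identification)),
                     frac(!is.na(rec$detection_method)),
                     frac(!is.na(out)),
                     if (n == 0) 0 else pid_comp,
                     frac(!is.na(rec$collection_year)),
                     frac(!is.na(rec$latitude) & !is.na(rec$longitude))),
    stringsAsFactors = FALSE)
  res$present <- res$completeness > 0
  res[, c("element", "present", "completeness")]
}
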