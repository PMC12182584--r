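# Machine-readable registry of the minimum wildlife disease data standard:
# 40 core fields (11 sampling, 13 host, 16 parasite) and 24 project-metadata
# properties. The registry is the single source of truth for parsing,
# validation, schema emission, templates, and the data dictionary.

#' Slug a printed field name
#'
#' Lower snake case of the human-readable field label
#' (e.g. "Sample collection method" becomes "sample_collection_method").
#'
#' @param x character vector of field names.
#' @return character vector of machine-safe identifiers.
#' @export
#' @examples
#' wdds_slug("Sample collection method")
wdds_slug <- function(x) {
  s <- tolower(trimws(x))
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

#' Core field registry of the data standard
#'
#' Returns the 40 core fields of the standard in table order: sampling
#' information first, then host identification and traits, then detection
#' methods and parasite identification. Nine fields are required; required
#' status is two-level (the column must exist, and cells must be non-blank
#' unless a conditional exemption named in `cell_required_when` applies).
#'
#' @return A data frame with one row per field and columns `name`, `slug`,
#'   `category` (sampling/host/parasite), `value_kind`
#'   (text/number/integer/boolean), `required`, `cell_required_when`
#'   (`""`, `"tested"`, or `"outcome_positive"`), `depends_on` (slug of the
#'   companion measurement field that makes this field mandatory when
#'   populated), `dwc_equivalent` (Darwin Core term or `""`),
#'   `vocabulary` (closed value set, `|`-separated, or `""`), and
#'   `description`.
#' @export
#' @examples
#' reg <- core_registry()
#' nrow(reg)            # 40
#' sum(reg$required)    # 9
core_registry <- function() {
  f <- function(name, category, value_kind, required = FALSE,
                cell_required_when = "", depends_on = "",
                dwc_equivalent = "", vocabulary = "", description = "") {
    data.frame(name = name, slug = wdds_slug(name), category = category,
               value_kind = value_kind, required = required,
               cell_required_when = cell_required_when,
               depends_on = depends_on, dwc_equivalent = dwc_equivalent,
               vocabulary = vocabulary, description = description,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    # -- sampling -----------------------------------------------------------
    f("Sample ID", "sampling", "text", required = TRUE,
      description = "Researcher-generated unique identifier for the sample; mixed character/integer strings avoid merge collisions."),
    f("Animal ID", "sampling", "text",
      description = "Researcher-generated unique identifier for the individual animal sampled; blank when animals are not individually identified (e.g. pooled testing). Multiple IDs may be separated by ';' for pools."),
    f("Latitude", "sampling", "number", required = TRUE,
      dwc_equivalent = "decimalLatitude",
      description = "Latitude of the collection site in decimal degrees."),
    f("Longitude", "sampling", "number", required = TRUE,
      dwc_equivalent = "decimalLongitude",
      description = "Longitude of the collection site in decimal degrees."),
    f("Spatial uncertainty", "sampling", "number",
      dwc_equivalent = "coordinateUncertaintyInMeters",
      description = "Coordinate uncertainty in meters, from GPS error, digitization, or deliberate alteration such as rounding or jittering."),
    f("Collection day", "sampling", "integer", dwc_equivalent = "day",
      description = "Day of the month on which the specimen was collected."),
    f("Collection month", "sampling", "integer", dwc_equivalent = "month",
      description = "Numeric month in which the specimen was collected."),
    f("Collection year", "sampling", "integer", dwc_equivalent = "year",
      description = "Year in which the specimen was collected."),
    f("Sample collection method", "sampling", "text", required = TRUE,
      description = "Technique used to acquire the sample and/or the tissue it came from (e.g. 'swab', 'wing punch', 'necropsy')."),
    f("Sample collection body part", "sampling", "text",
      description = "Part of the animal body the sample was collected from (e.g. 'rectum', 'wing')."),
    f("Sample material", "sampling", "text",
      description = "Organic tissue or fluid collected (e.g. 'liver', 'blood', 'whole organism')."),
    # -- host ---------------------------------------------------------------
    f("Host identification", "host", "text", required = TRUE,
      dwc_equivalent = "scientificName",
      description = "Linnaean classification of the sampled animal at the lowest level possible, ideally a species binomial."),
    f("Organism sex", "host", "text", dwc_equivalent = "sex",
      description = "Sex of the sampled animal."),
    f("Live capture", "host", "boolean", vocabulary = "TRUE|FALSE",
      description = "Whether the animal was alive at the time of capture (TRUE/FALSE); lethal sampling is TRUE since the field describes the organism at capture."),
    f("Host life stage", "host", "text", dwc_equivalent = "lifeStage",
      description = "Life stage of the sampled animal as appropriate for the organism (e.g. 'juvenile', 'adult')."),
    f("Age", "host", "number",
      description = "Numeric age of the animal at sample collection, if known."),
    f("Age units", "host", "text", depends_on = "age",
      description = "Units in which age is measured (usually years); must accompany a populated Age."),
    f("Mass", "host", "number",
      description = "Mass of the animal at sample collection."),
    f("Mass units", "host", "text", depends_on = "mass",
      description = "Units mass is recorded in (e.g. 'kg'); must accompany a populated Mass."),
    f("Length", "host", "number",
      description = "Numeric length of the animal at sample collection."),
    f("Length measurement", "host", "text", depends_on = "length",
      description = "Axis of measurement (e.g. 'snout-vent length', 'wing length'); must accompany a populated Length."),
    f("Length units", "host", "text", depends_on = "length",
      description = "Units length is recorded in (e.g. 'meters'); must accompany a populated Length."),
    f("Organism quantity", "host", "number",
      dwc_equivalent = "organismQuantity",
      description = "Number or enumeration value for the quantity of organisms (e.g. the size of a pooled sample)."),
    f("Organism quantity units", "host", "text",
      depends_on = "organism_quantity",
      dwc_equivalent = "organismQuantityType",
      description = "Units organism quantity is recorded in (e.g. 'individuals', 'kg'); must accompany a populated Organism quantity."),
    # -- parasite -----------------------------------------------------------
    f("Detection target", "parasite", "text", required = TRUE,
      cell_required_when = "tested",
      dwc_equivalent = "associatedOccurrences",
      description = "Taxonomic identity of the parasite screened for; often coarser than the parasite identified (e.g. a whole family for viral screening)."),
    f("Detection method", "parasite", "text", required = TRUE,
      cell_required_when = "tested",
      description = "Type of test performed to detect the parasite or a parasite-specific antibody (e.g. 'PCR', 'ELISA')."),
    f("Forward primer sequence", "parasite", "text",
      description = "Sequence of the forward primer used for detection, where applicable (e.g. PCR)."),
    f("Reverse primer sequence", "parasite", "text",
      description = "Sequence of the reverse primer used for detection, where applicable (e.g. PCR)."),
    f("Gene target", "parasite", "text",
      description = "Parasite gene targeted by the primers (e.g. 'RdRp')."),
    f("Primer citation", "parasite", "text",
      description = "Citation(s) for the primer(s); ideally a DOI or other persistent work identifier."),
    f("Probe target", "parasite", "text",
      description = "Antibody or antigen targeted for detection, where applicable (e.g. ELISA)."),
    f("Probe type", "parasite", "text",
      description = "Antibody or antigen used for detection, where applicable (e.g. ELISA)."),
    f("Probe citation", "parasite", "text",
      description = "Citation(s) for the probe(s); ideally a DOI or other persistent work identifier."),
    f("Detection outcome", "parasite", "text", required = TRUE,
      cell_required_when = "tested",
      dwc_equivalent = "occurrenceStatus",
      vocabulary = "positive|negative|inconclusive",
      description = "The test result: 'positive', 'negative', or 'inconclusive'; these strings are preferred over numeric codes. Blank for records of untested samples."),
    f("Detection measurement", "parasite", "number",
      description = "Numeric measurement of detection beyond positive/negative (e.g. viral titer, parasite count, sequence reads)."),
    f("Detection measurement units", "parasite", "text",
      description = "Units for quantitative detection measurements (e.g. 'Ct', 'TCID50/mL', 'parasite count')."),
    f("Parasite identification", "parasite", "text", required = TRUE,
      cell_required_when = "outcome_positive",
      description = "Identity of a parasite detected by the test, at the lowest taxonomic level possible; always blank for negative results."),
    f("Parasite ID", "parasite", "text",
      description = "Researcher-generated unique identifier for an individual parasite; in nested cases this ID is reused as an Animal ID in another row."),
    f("Parasite life stage", "parasite", "text",
      description = "Life stage of the parasite, as appropriate for the organism."),
    f("GenBank accession", "parasite", "text",
      dwc_equivalent = "otherCatalogNumbers",
      description = "GenBank accession for any parasite genetic sequence; identifiers on other platforms belong in additional fields.")
  )
  rownames(reg) <- NULL
  reg
}

#' Project-metadata property registry
#'
#' Returns the 24 project-level metadata properties (7 required), derived
#' from the DataCite metadata kernel plus generalist-repository
#' recommendations. The exact composition is provisional: the standard's
#' supplementary material defines the canonical list, and this registry
#' reproduces the documented 24/7 structure with DataCite-mandatory
#' properties marked required.
#'
#' @return A data frame with columns `name`, `slug`, `required`,
#'   `value_kind`, `pid_kind` (`""`, `"doi"`, `"orcid"`, `"ror"`, or
#'   `"funder_id"`), and `description`.
#' @export
#' @examples
#' m <- metadata_registry()
#' nrow(m)           # 24
#' sum(m$required)   # 7
metadata_registry <- function() {
  p <- function(name, required = FALSE, value_kind = "text", pid_kind = "",
                description = "") {
    data.frame(name = name, slug = wdds_slug(name), required = required,
               value_kind = value_kind, pid_kind = pid_kind,
               description = description, stringsAsFactors = FALSE)
  }
  reg <- rbind(
    p("Title", TRUE, description = "Name by which the dataset is known."),
    p("Description", TRUE, description = "Written description of the data, intended use, and known limitations (including any coordinate obfuscation applied)."),
    p("Creators", TRUE, description = "People or organizations that produced the dataset."),
    p("Creator ORCID", pid_kind = "orcid", description = "ORCID iD(s) of the creators."),
    p("Creator affiliation", description = "Institutional affiliation(s) of the creators."),
    p("Affiliation ROR", pid_kind = "ror", description = "Research Organization Registry identifier(s) for creator affiliations."),
    p("Publication year", TRUE, value_kind = "integer", description = "Year the dataset was (or will be) made publicly available."),
    p("Publisher", description = "Repository or platform holding the dataset."),
    p("Resource type", TRUE, description = "General type of the resource (typically 'Dataset')."),
    p("Identifier", TRUE, pid_kind = "doi", description = "Persistent identifier of the dataset, ideally a DOI."),
    p("License", TRUE, description = "License under which the dataset is distributed."),
    p("Subjects", description = "Keywords or classification codes describing the dataset."),
    p("Language", description = "Primary language of the dataset."),
    p("Version", description = "Version number of the dataset."),
    p("Funder name", description = "Name(s) of the funding body supporting the work."),
    p("Funder identifier", pid_kind = "funder_id", description = "Persistent identifier of the funder (Crossref Funder ID DOI or ROR)."),
    p("Award number", description = "Grant or award number(s)."),
    p("Related identifier", description = "Persistent identifier of a related work (e.g. the associated publication)."),
    p("Related identifier type", description = "Type of the related identifier (e.g. 'DOI')."),
    p("Relation type", description = "Relation of the dataset to the related work (e.g. 'IsSupplementTo')."),
    p("Contributors", description = "People or organizations that contributed other than as creators."),
    p("Contributor type", description = "Role of each contributor (e.g. 'DataCurator')."),
    p("Coverage dates", description = "Temporal coverage of sampling (start/end dates)."),
    p("Geographic coverage description", description = "Free-text description of the spatial coverage of sampling.")
  )
  rownames(reg) <- NULL
  reg
}

# closed vocabulary helpers
.outcome_vocab <- c("positive", "negative", "inconclusive")

#' Emit a CSV template for the standard
#'
#' One header row with the 40 core columns in registry order and no data
#' rows; fill one row per diagnostic-test result.
#'
#' @param registry field registry, defaults to [core_registry()].
#' @param path optional file path; when `NULL` the template is returned as a
#'   single string.
#' @return Invisibly (or visibly when `path` is `NULL`) the template text.
#' @export
emit_template <- function(registry = core_registry(), path = NULL) {
  txt <- paste0(paste(registry$name, collapse = ","), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "", useBytes = TRUE)
  invisible(txt)
}

#' Emit the data dictionary
#'
#' One row per field: name, type, required flag, description, closed
#' vocabulary (if any), and the equivalent Darwin Core term. A data
#' dictionary should accompany every published dataset so that fields can
#' be interpreted without reference to the producing project.
#'
#' @param registry field registry, defaults to [core_registry()].
#' @return A data frame with columns `name`, `type`, `required`,
#'   `vocabulary`, `dwc_term`, `description`.
#' @export
emit_data_dictionary <- function(registry = core_registry()) {
  if (!is.data.frame(registry) || nrow(registry) == 0)
    stop("registry is empty; cannot build a data dictionary")
  data.frame(name = registry$name, type = registry$value_kind,
             required = registry$required, vocabulary = registry$vocabulary,
             dwc_term = registry$dwc_equivalent,
             description = registry$description, stringsAsFactors = FALSE)
}

#' Emit a JSON Schema implementing the standard
#'
#' Builds a JSON Schema (draft 2020-12 dialect) that validates one record
#' serialized as a JSON object with one member per core field (blank cells
#' as `null`). Types, the 9-member required list, and the closed
#' vocabularies mirror the registry. Conditional cell-level rules are
#' encoded with `allOf`/`if`/`then`: detection target, method, and outcome
#' may be null together (a record of an untested sample), and parasite
#' identification may be null unless hard requirements elsewhere apply.
#' Additional properties are permitted so that datasets may carry extra
#' fields beyond the minimum. Output is byte-stable for a given registry.
#'
#' @param registry field registry, defaults to [core_registry()].
#' @param path optional file path to write the schema JSON to.
#' @return The schema as a named list (invisibly when `path` given); use
#'   [wdds_schema_json()] for the serialized text.
#' @export
emit_json_schema <- function(registry = core_registry(), path = NULL) {
  if (!is.data.frame(registry) || nrow(registry) == 0)
    stop("registry is empty")
  json_type <- c(text = "string", number = "number", integer = "integer",
                 boolean = "boolean")
  props <- list()
  for (i in seq_len(nrow(registry))) {
    fs <- registry[i, ]
    tp <- json_type[[fs$value_kind]]
    # unconditionally-required fields are non-nullable; everything else
    # admits null (= blank cell)
    nullable <- !(fs$required && fs$cell_required_when == "")
    prop <- list(type = if (nullable) c(tp, "null") else tp,
                 description = fs$description)
    if (nzchar(fs$vocabulary) && fs$slug == "detection_outcome") {
      vals <- strsplit(fs$vocabulary, "|", fixed = TRUE)[[1]]
      prop$enum <- c(as.list(vals), list(NULL))
      prop$type <- NULL
    }
    props[[fs$slug]] <- prop
  }
  list(
    `$schema` = "https://json-schema.org/draft/2020-12/schema",
    `$id` = "https://example.org/wdds/record.schema.json",
    title = "Wildlife disease surveillance record",
    description = "One row of a standard-conformant dataset: the outcome of one diagnostic test on one sample.",
    type = "object",
    properties = props,
    required = as.list(registry$slug[registry$required]),
    additionalProperties = TRUE,
    allOf = list(
      # a tested record (non-null outcome) must name its target and method
      list(`if` = list(properties = list(detection_outcome = list(type = "string"))),
           then = list(properties = list(
             detection_target = list(type = "string"),
             detection_method = list(type = "string"))))
    )
  )
}

#' Serialize the JSON Schema to text
#'
#' @inheritParams emit_json_schema
#' @return A single JSON string (pretty-printed, deterministic).
#' @export
wdds_schema_json <- function(registry = core_registry(), path = NULL) {
  sch <- emit_json_schema(registry)
  txt <- jsonlite::toJSON(sch, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                          null = "null")
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
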