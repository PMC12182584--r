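# Seeded generator of standard-conformant surveillance datasets across the
# relationship designs a validator must handle (simple one-to-one rows,
# repeat sampling, repeat testing, nested detections, pooled samples), and
# targeted corruptions for mutation-testing the validator. The generator's
# contract is that its output always validates conformant.

.species_pool_default <- c("Desmodus rotundus", "Artibeus jamaicensis",
                           "Pteronotus mesoamericanus",
                           "Odocoileus virginianus", "Rattus rattus",
                           "Sturnira parvidens")

.sample_prefixes <- c("OS", "RS", "BS", "WS", "US", "FS")
.body_parts <- c(OS = "Mouth", RS = "Rectum", BS = "Wing vein",
                 WS = "Wing", US = "Urogenital area", FS = "Mouth")
.sample_materials <- c(OS = "saliva", RS = "feces", BS = "blood",
                       WS = "skin", US = "urine", FS = "saliva")

#' Generate a synthetic surveillance dataset
#'
#' Deterministic under `seed`; every required field is populated, so the
#' generated dataset always validates conformant (the generator/validator
#' closure property). Designs:
#' \describe{
#'   \item{simple}{one animal, one sample, one test per row.}
#'   \item{multisample}{`samples_per_animal` samples per animal.}
#'   \item{multitest}{each sample tested `tests_per_sample` times against
#'     different targets.}
#'   \item{nested}{each host yields an ectoparasite (positive detection
#'     with a Parasite ID) that is itself tested in a child record reusing
#'     that ID as its Animal ID.}
#'   \item{pooled}{each record is a pooled sample with blank Animal ID and
#'     `organism_quantity = pool_size`; half the pools get per-animal
#'     links in the pooled-links side table.}
#' }
#' Test outcomes are i.i.d. Bernoulli(`prevalence`); positives receive a
#' target-derived parasite identification and a deliberately
#' non-resolvable accession string (prefix "SYN"). A fraction of records
#' get blank day/month to exercise the partial-date path (archival
#' samples).
#'
#' @param n_animals number of animals (pools for the pooled design).
#' @param design one of `"simple"`, `"multisample"`, `"multitest"`,
#'   `"nested"`, `"pooled"`.
#' @param prevalence per-test probability of a positive outcome.
#' @param samples_per_animal samples per animal (multisample design).
#' @param tests_per_sample tests per sample (multitest design).
#' @param pool_size animals per pool (pooled design).
#' @param species_pool host binomials to draw from.
#' @param target detection target label.
#' @param bbox sampling bounding box,
#'   `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param date_range sampling period, two `Date`-coercible values.
#' @param partial_date_frac fraction of records with blank day/month.
#' @param seed integer seed (required; no implicit randomness).
#' @return A `wdds_dataset`.
#' @export
wdds_simulate <- function(n_animals = 100,
                          design = c("simple", "multisample", "multitest",
                                     "nested", "pooled"),
                          prevalence = 0.1,
                          samples_per_animal = 2,
                          tests_per_sample = 2,
                          pool_size = 30,
                          species_pool = .species_pool_default,
                          target = "Coronaviridae",
                          bbox = c(17.0, 18.0, -89.2, -88.0),
                          date_range = c("2019-01-01", "2019-12-31"),
                          partial_date_frac = 0.1,
                          seed) {
  design <- match.arg(design)
  if (missing(seed) || is.null(seed))
    stop("wdds_simulate requires an explicit seed")
  if (!(n_animals >= 1 && prevalence >= 0 && prevalence <= 1 &&
        samples_per_animal >= 1 && tests_per_sample >= 1 &&
        pool_size >= 1))
    stop("invalid config: counts must be >= 1 and prevalence in [0, 1]")
  if (!(bbox[1] >= -90 && bbox[2] <= 90 && bbox[1] <= bbox[2] &&
        bbox[3] >= -180 && bbox[4] <= 180 && bbox[3] <= bbox[4]))
    stop("invalid config: bbox outside valid coordinate ranges")
  dates <- as.Date(date_range)
  if (any(is.na(dates)) || dates[1] > dates[2])
    stop("invalid config: bad date range")
  .run_seeded(seed, .simulate_impl(n_animals, design, prevalence,
                                   samples_per_animal, tests_per_sample,
                                   pool_size, species_pool, target, bbox,
                                   dates, partial_date_frac))
}

.accession <- function(n) sprintf("SYN%06d", sample.int(999999, n))

.simulate_impl <- function(n_animals, design, prevalence,
                           samples_per_animal, tests_per_sample, pool_size,
                           species_pool, target, bbox, dates,
                           partial_date_frac) {
  animal_ids <- sprintf("SYN25-%04d", seq_len(n_animals))
  species <- sample(species_pool, n_animals, replace = TRUE)
  sex <- sample(c("male", "female"), n_animals, replace = TRUE)
  stage <- sample(c("adult", "subadult", "juvenile"), n_animals,
                  replace = TRUE, prob = c(0.6, 0.25, 0.15))
  mass <- round(exp(stats::rnorm(n_animals, log(0.03), 0.3)), 4)
  lat <- round(stats::runif(n_animals, bbox[1], bbox[2]), 5)
  lon <- round(stats::runif(n_animals, bbox[3], bbox[4]), 5)
  date <- dates[1] + sample.int(as.integer(dates[2] - dates[1]) + 1L,
                                n_animals, replace = TRUE) - 1L

  # vectorized row builder: a, prefix, tgt, outcome are parallel vectors
  base_row <- function(a, prefix, tgt, outcome) {
    data.frame(
      sample_id = paste0(prefix, " ", animal_ids[a]),
      animal_id = animal_ids[a],
      latitude = lat[a], longitude = lon[a],
      spatial_uncertainty = NA_real_,
      collection_day = as.integer(format(date[a], "%d")),
      collection_month = as.integer(format(date[a], "%m")),
      collection_year = as.integer(format(date[a], "%Y")),
      sample_collection_method = "swab",
      sample_collection_body_part = unname(.body_parts[prefix]),
      sample_material = unname(.sample_materials[prefix]),
      host_identification = species[a],
      organism_sex = sex[a], live_capture = TRUE,
      host_life_stage = stage[a],
      mass = mass[a], mass_units = "kg",
      organism_quantity = NA_real_,
      organism_quantity_units = NA_character_,
      detection_target = tgt, detection_method = "PCR",
      gene_target = "RdRp",
      detection_outcome = outcome,
      parasite_identification = NA_character_,
      parasite_id = NA_character_,
      genbank_accession = NA_character_,
      stringsAsFactors = FALSE)
  }
  draw_outcome <- function(n) ifelse(stats::rbinom(n, 1, prevalence) == 1,
                                     "positive", "negative")

  links <- NULL
  if (design %in% c("simple", "multisample", "multitest")) {
    n_samp <- if (design == "multisample") samples_per_animal else 1L
    n_test <- if (design == "multitest") tests_per_sample else 1L
    targets <- rep_len(c(target, "Paramyxoviridae", "Filoviridae",
                         "Rhabdoviridae"), n_test)
    a_idx <- rep(seq_len(n_animals), each = n_samp * n_test)
    s_idx <- rep(rep(seq_len(n_samp), each = n_test), times = n_animals)
    t_idx <- rep(seq_len(n_test), times = n_animals * n_samp)
    prefix <- .sample_prefixes[(s_idx - 1L) %% length(.sample_prefixes) + 1L]
    rec <- base_row(a_idx, prefix, targets[t_idx],
                    draw_outcome(length(a_idx)))
  } else if (design == "nested") {
    flea_ids <- sprintf("SYNP25-%04d", seq_len(n_animals))
    a <- seq_len(n_animals)
    host <- base_row(a, "FS", "Siphonaptera", "positive")
    host$sample_collection_method <- "visual inspection"
    host$sample_collection_body_part <- "Fur"
    host$sample_material <- "whole organism"
    host$detection_method <- "morphological identification"
    host$gene_target <- NA_character_
    host$parasite_identification <- "Ctenocephalides felis"
    host$parasite_id <- flea_ids
    child <- base_row(a, "WS", "Yersinia pestis",
                      draw_outcome(n_animals))
    child$sample_id <- paste0("HG ", flea_ids)
    child$animal_id <- flea_ids
    child$host_identification <- "Ctenocephalides felis"
    child$sample_collection_method <- "homogenization"
    child$sample_collection_body_part <- "Whole body"
    child$sample_material <- "whole organism"
    child$mass <- NA_real_; child$mass_units <- NA_character_
    child$host_life_stage <- "adult"
    rec <- rbind(host, child)
    rec <- rec[order(rep(a, 2), rep(1:2, each = n_animals)), , drop = FALSE]
  } else if (design == "pooled") {
    a <- seq_len(n_animals)
    rec <- base_row(a, "US", "West Nile virus", draw_outcome(n_animals))
    rec$sample_id <- sprintf("POOL SYN25-%04d", a)
    rec$animal_id <- NA_character_
    rec$host_identification <- "Culex quinquefasciatus"
    rec$sample_collection_method <- "CDC light trap"
    rec$sample_collection_body_part <- "Whole body"
    rec$sample_material <- "whole organism"
    rec$organism_sex <- NA_character_
    rec$host_life_stage <- "adult"
    rec$mass <- NA_real_; rec$mass_units <- NA_character_
    rec$organism_quantity <- as.numeric(pool_size)
    rec$organism_quantity_units <- "individuals"
    linked <- a[a %% 2 == 0]
    if (length(linked))
      links <- data.frame(
        sample_id = rep(rec$sample_id[linked], each = pool_size),
        animal_id = sprintf("SYNM25-%04d-%02d",
                            rep(linked, each = pool_size),
                            rep(seq_len(pool_size), times = length(linked))),
        stringsAsFactors = FALSE)
  }
  rownames(rec) <- NULL

  # positives get a target-derived identification and a synthetic,
  # deliberately non-resolvable accession; nested host rows already carry
  # a morphological identification
  pos <- rec$detection_outcome == "positive" &
    is.na(rec$parasite_identification)
  rec$parasite_identification[pos] <- paste(rec$detection_target[pos], "sp.")
  rec$genbank_accession[pos] <- .accession(sum(pos))

  # archival records: blank day and month
  partial <- stats::runif(nrow(rec)) < partial_date_frac
  rec$collection_day[partial] <- NA_integer_
  rec$collection_month[partial] <- NA_integer_

  wdds_dataset(rec, pooled_links = links)
}

# rules that wdds_corrupt() can inject; kept in sync with wdds_rules()
.corruptible_rules <- c("REQ_FIELD", "VOCAB", "UNITS_PAIR", "COORD_RANGE",
                        "UNCERT_RANGE", "DATE_VALID", "PLACEHOLDER",
                        "POS_NO_ID", "NEG_WITH_ID", "DUP_ROW",
                        "XREC_CONFLICT", "POOL_LINK", "NEST_CYCLE")

#' Corrupt a dataset so that one validation rule fires
#'
#' Minimally edits a seeded, randomly chosen record (or side table) so
#' that exactly the targeted rule should be reported by
#' [validate_wdds()]. Used to mutation-test the validator: a sound
#' validator reports the injected rule on the corrupted dataset and
#' nothing blocking on the original.
#'
#' @param dataset a conformant `wdds_dataset`.
#' @param rule_id one of the record/dataset-scope rule ids (see
#'   [wdds_rules()]).
#' @param seed integer seed for the choice of record.
#' @return The corrupted dataset.
#' @export
wdds_corrupt <- function(dataset, rule_id, seed) {
  stopifnot(inherits(dataset, "wdds_dataset"))
  if (!(rule_id %in% .corruptible_rules))
    stop("rule '", rule_id, "' is not injectable by wdds_corrupt")
  .run_seeded(seed, .corrupt_impl(dataset, rule_id))
}

.corrupt_impl <- function(dataset, rule_id) {
  rec <- dataset$records
  pick <- function(eligible) {
    idx <- which(eligible)
    if (!length(idx))
      stop("no record eligible for rule ", rule_id, " in this dataset")
    if (length(idx) == 1) idx else sample(idx, 1)
  }
  out <- tolower(rec$detection_outcome)
  switch(rule_id,
    REQ_FIELD = {
      r <- pick(!is.na(rec$host_identification))
      rec$host_identification[r] <- NA_character_
    },
    VOCAB = {
      r <- pick(!is.na(rec$detection_outcome))
      rec$detection_outcome[r] <- "detected"
    },
    UNITS_PAIR = {
      pairs <- .units_pairs(core_registry())
      hit <- FALSE
      for (k in seq_len(nrow(pairs))) {
        elig <- !is.na(rec[[pairs$depends_on[k]]]) &
          !is.na(rec[[pairs$slug[k]]])
        if (any(elig)) {
          r <- pick(elig)
          rec[[pairs$slug[k]]][r] <- NA_character_
          hit <- TRUE
          break
        }
      }
      if (!hit) stop("no record eligible for rule UNITS_PAIR")
    },
    COORD_RANGE = {
      r <- pick(rep(TRUE, nrow(rec)))
      rec$latitude[r] <- 91
    },
    UNCERT_RANGE = {
      r <- pick(rep(TRUE, nrow(rec)))
      rec$spatial_uncertainty[r] <- -5
    },
    DATE_VALID = {
      r <- pick(!is.na(rec$collection_day) & !is.na(rec$collection_month) &
                !is.na(rec$collection_year))
      rec$collection_day[r] <- 30L
      rec$collection_month[r] <- 2L
    },
    PLACEHOLDER = {
      r <- pick(rep(TRUE, nrow(rec)))
      rec$latitude[r] <- 0
      rec$longitude[r] <- 0
    },
    POS_NO_ID = {
      r <- pick(!is.na(out) & out == "positive" &
                !is.na(rec$parasite_identification))
      rec$parasite_identification[r] <- NA_character_
    },
    NEG_WITH_ID = {
      r <- pick(!is.na(out) & out == "negative" &
                is.na(rec$parasite_identification))
      rec$parasite_identification[r] <- "Alphacoronavirus"
    },
    DUP_ROW = {
      r <- pick(rep(TRUE, nrow(rec)))
      rec <- rbind(rec, rec[r, , drop = FALSE])
    },
    XREC_CONFLICT = {
      aid <- rec$animal_id
      multi <- !is.na(aid) & aid %in% names(which(table(aid) >= 2))
      r <- pick(multi)
      other <- setdiff(.species_pool_default, rec$host_identification[r])[1]
      rows <- which(!is.na(aid) & aid == aid[r])
      rec$host_identification[rows[2]] <- other
    },
    POOL_LINK = {
      dataset$pooled_links <- rbind(dataset$pooled_links,
        data.frame(sample_id = "SYN-NO-SUCH-SAMPLE",
                   animal_id = "SYN25-9999", stringsAsFactors = FALSE))
    },
    NEST_CYCLE = {
      edges <- .nesting_edges(rec)
      if (nrow(edges) == 0)
        stop("no record eligible for rule NEST_CYCLE (no nested detections)")
      k <- if (nrow(edges) == 1) 1 else sample(nrow(edges), 1)
      child_rows <- which(!is.na(rec$animal_id) &
                          rec$animal_id == edges$child[k])
      rec$parasite_id[child_rows[1]] <- edges$host[k]
    })
  rownames(rec) <- NULL
  dataset$records <- rec
  dataset
}
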