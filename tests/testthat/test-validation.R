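make_record <- function(...) {
  reg <- core_registry()
  cells <- stats::setNames(rep("", 40), reg$slug)
  cells[c("sample_id", "latitude", "longitude",
          "sample_collection_method", "host_identification",
          "detection_target", "detection_method", "detection_outcome",
          "parasite_identification")] <-
    c("S1", "17.5", "-88.5", "swab", "Desmodus rotundus",
      "Coronaviridae", "PCR", "positive", "Alphacoronavirus sp.")
  over <- list(...)
  cells[names(over)] <- unlist(over)
  cells
}

validate_cells <- function(...) {
  ds <- read_wdds_csv(text = csv_from_cells(list(make_record(...))))
  validate_wdds(ds)
}

test_that("the worked example is conformant, including its negative row", {
  rep <- validate_wdds(example_dataset())
  expect_true(rep$conformant)
  expect_equal(rep$n_errors, 0)
  expect_equal(rep$n_warnings, 0)
  # per-record: the negative row's blank parasite identity is legal
  rec2 <- example_dataset()$records[2, ]
  expect_equal(nrow(validate_record(rec2)), 0)
})

test_that("record rules fire on their violations and only then", {
  r <- validate_cells(age = "3", age_units = "")
  expect_true("UNITS_PAIR" %in% rules_fired(r))
  expect_false(r$conformant)

  r <- validate_cells(latitude = "91")
  expect_equal(rules_fired(r), "COORD_RANGE")

  r <- validate_cells(longitude = "-181")
  expect_equal(rules_fired(r), "COORD_RANGE")

  r <- validate_cells(spatial_uncertainty = "-1")
  expect_equal(rules_fired(r), "UNCERT_RANGE")

  r <- validate_cells(detection_outcome = "detected",
                      parasite_identification = "")
  expect_equal(rules_fired(r), "VOCAB")

  r <- validate_cells(detection_outcome = "negative",
                      parasite_identification = "Alphacoronavirus")
  expect_equal(rules_fired(r), "NEG_WITH_ID")

  r <- validate_cells(parasite_identification = "")
  expect_equal(rules_fired(r), "POS_NO_ID")
  expect_true(r$conformant)  # warning only

  r <- validate_cells(host_identification = "")
  expect_equal(rules_fired(r), "REQ_FIELD")

  r <- validate_cells(latitude = "0", longitude = "0")
  expect_equal(rules_fired(r), "PLACEHOLDER")
  expect_true(r$conformant)
})

test_that("impossible dates are errors, partial dates are legal", {
  r <- validate_cells(collection_day = "30", collection_month = "2",
                      collection_year = "2019")
  expect_equal(rules_fired(r), "DATE_VALID")
  r <- validate_cells(collection_day = "29", collection_month = "2",
                      collection_year = "2020")  # leap day
  expect_true(r$conformant)
  r <- validate_cells(collection_month = "13", collection_year = "2019")
  expect_equal(rules_fired(r), "DATE_VALID")
  r <- validate_cells(collection_day = "42")
  expect_equal(rules_fired(r), "DATE_VALID")
  # archival record: year only
  r <- validate_cells(collection_year = "1987")
  expect_true(r$conformant)
})

test_that("untested-sample rows validate with blank outcome and methods", {
  r <- validate_cells(detection_outcome = "", detection_target = "",
                      detection_method = "", parasite_identification = "")
  expect_true(r$conformant)
  expect_equal(r$n_errors, 0)
  # but a tested row must name target and method
  r <- validate_cells(detection_target = "", detection_method = "")
  expect_equal(sum(rules_fired(r) == "REQ_FIELD"), 1)
  expect_equal(sum(r$issues$rule == "REQ_FIELD"), 2)
})

test_that("missing required columns are reported once, dataset-level", {
  ds <- read_wdds_csv(text = c("Sample ID,Latitude,Longitude",
                               "S1,17.5,-88.5", "S2,18.0,-88.1"))
  r <- validate_wdds(ds)
  expect_false(r$conformant)
  miss <- r$issues[r$issues$rule == "REQ_FIELD", ]
  expect_setequal(miss$field,
                  c("sample_collection_method", "host_identification",
                    "detection_target", "detection_method",
                    "detection_outcome", "parasite_identification"))
  expect_true(all(is.na(miss$record)))
})

test_that("cross-record checks: conflicts, duplicates, pool links", {
  ds <- example_dataset()
  ds$records$host_identification[2] <- "Desmodus youngi"
  r <- validate_wdds(ds)
  expect_true("XREC_CONFLICT" %in% rules_fired(r))
  expect_true(r$conformant)  # warning, not error

  ds <- example_dataset()
  ds$records <- rbind(ds$records, ds$records[1, ])
  r <- validate_wdds(ds)
  expect_true("DUP_ROW" %in% rules_fired(r))

  ds <- example_dataset()
  ds$pooled_links <- data.frame(sample_id = "NO-SUCH", animal_id = "A1")
  r <- validate_wdds(ds)
  expect_true("POOL_LINK" %in% rules_fired(r))
  expect_false(r$conformant)
})

test_that("validation is idempotent and monotone under conformant growth", {
  ds <- wdds_simulate(n_animals = 25, design = "multitest", seed = 14)
  r1 <- validate_wdds(ds)
  r2 <- validate_wdds(ds)
  expect_identical(r1$issues, r2$issues)
  expect_true(r1$conformant)
  extra <- wdds_simulate(n_animals = 1, design = "simple", seed = 15)
  extra$records$sample_id <- "XX SYN25-9999"
  extra$records$animal_id <- "SYN25-9999"
  ds$records <- rbind(ds$records, extra$records)
  r3 <- validate_wdds(ds)
  expect_equal(r3$n_errors, 0)
})

test_that("report invariants hold: counts, conformance, serialization", {
  ds <- wdds_corrupt(base_for_rule("COORD_RANGE"), "COORD_RANGE", 3)
  r <- validate_wdds(ds)
  expect_equal(r$n_errors, sum(r$issues$severity == "error"))
  expect_equal(r$n_warnings, sum(r$issues$severity == "warning"))
  expect_equal(r$conformant, r$n_errors == 0)
  js <- jsonlite::fromJSON(report_json(r))
  expect_equal(js$n_errors, r$n_errors)
  expect_false(js$conformant)
  expect_output(print(r), "COORD_RANGE")
})

test_that("every reported rule id belongs to the published registry", {
  rules <- wdds_rules()$rule_id
  for (rule in mutation_rules()) {
    r <- validate_wdds(wdds_corrupt(base_for_rule(rule), rule, 7))
    expect_true(all(rules_fired(r) %in% rules))
  }
})

test_that("fit-for-purpose summary tracks element completeness", {
  fp <- check_fit_for_purpose(example_dataset())
  expect_true(all(fp$present))
  expect_equal(fp$completeness[fp$element == "sampling date"], 1)

  ds <- example_dataset()
  ds$records$collection_year <- NA_integer_
  fp <- check_fit_for_purpose(ds)
  expect_false(fp$present[fp$element == "sampling date"])

  fp <- check_fit_for_purpose(wdds_dataset(data.frame()))
  expect_true(all(!fp$present))
})
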