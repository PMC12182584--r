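test_that("generator is deterministic and honors forced outcomes", {
  d1 <- wdds_simulate(n_animals = 1, design = "simple", prevalence = 1,
                      seed = 7)
  expect_equal(n_records(d1), 1)
  expect_equal(d1$records$detection_outcome, "positive")
  expect_true(validate_wdds(d1)$conformant)
  expect_match(d1$records$animal_id, "^SYN25-")
  expect_match(d1$records$genbank_accession, "^SYN")

  d0 <- wdds_simulate(n_animals = 5, design = "simple", prevalence = 0,
                      seed = 7)
  expect_true(all(d0$records$detection_outcome == "negative"))
  expect_true(all(is.na(d0$records$parasite_identification)))

  a <- wdds_simulate(n_animals = 50, design = "multitest", seed = 123)
  b <- wdds_simulate(n_animals = 50, design = "multitest", seed = 123)
  expect_identical(a$records, b$records)
})

test_that("positive fraction falls in the exact binomial 99% band", {
  ds <- wdds_simulate(n_animals = 1000, design = "simple",
                      prevalence = 0.2, seed = 1)
  k <- sum(ds$records$detection_outcome == "positive")
  expect_gte(k, qbinom(0.005, 1000, 0.2))
  expect_lte(k, qbinom(0.995, 1000, 0.2))
})

test_that("prevalence is recovered at large n", {
  fracs <- vapply(1:3, function(s) {
    ds <- wdds_simulate(n_animals = 10000, design = "simple",
                        prevalence = 0.1, seed = s)
    mean(ds$records$detection_outcome == "positive")
  }, 0)
  expect_lt(abs(mean(fracs) - 0.1), 0.01)
})

test_that("designs produce their advertised structures", {
  ms <- wdds_simulate(n_animals = 10, design = "multisample", seed = 2,
                      samples_per_animal = 3)
  expect_equal(n_records(ms), 30)
  expect_equal(unname(table(ms$records$animal_id)), rep(3L, 10),
               ignore_attr = TRUE)

  mt <- wdds_simulate(n_animals = 10, design = "multitest", seed = 2,
                      tests_per_sample = 2)
  expect_equal(n_records(mt), 20)
  expect_equal(length(unique(mt$records$detection_target)), 2)
  expect_equal(length(unique(mt$records$sample_id)), 10)

  nest <- wdds_simulate(n_animals = 10, design = "nested", seed = 2)
  expect_equal(n_records(nest), 20)
  expect_equal(nrow(wdds:::.nesting_edges(nest$records)), 10)

  pool <- wdds_simulate(n_animals = 10, design = "pooled", seed = 2,
                        pool_size = 4)
  expect_equal(n_records(pool), 10)
  expect_true(all(is.na(pool$records$animal_id)))
  expect_equal(pool$records$organism_quantity, rep(4, 10))
  expect_equal(nrow(pool$pooled_links), 5 * 4)  # half the pools linked
})

test_that("invalid configurations fail before any generation", {
  expect_error(wdds_simulate(n_animals = 0, seed = 1), "invalid config")
  expect_error(wdds_simulate(prevalence = 1.2, seed = 1), "invalid config")
  expect_error(wdds_simulate(bbox = c(17, 95, -89, -88), seed = 1),
               "bbox")
  expect_error(wdds_simulate(date_range = c("2020-01-01", "2019-01-01"),
                             seed = 1), "date range")
  expect_error(wdds_simulate(n_animals = 5), "seed")
})

test_that("corruptions are targeted, seeded, and fail when ineligible", {
  ds <- base_for_rule("VOCAB")
  c1 <- wdds_corrupt(ds, "VOCAB", 9)
  c2 <- wdds_corrupt(ds, "VOCAB", 9)
  expect_identical(c1$records, c2$records)
  expect_true(any(c1$records$detection_outcome == "detected"))
  # exactly one cell changed
  expect_equal(sum(c1$records$detection_outcome !=
                   ds$records$detection_outcome), 1)

  cc <- wdds_corrupt(ds, "COORD_RANGE", 9)
  expect_true(any(cc$records$latitude == 91))

  cn <- wdds_corrupt(ds, "NEG_WITH_ID", 9)
  neg_with <- cn$records$detection_outcome == "negative" &
    !is.na(cn$records$parasite_identification)
  expect_equal(sum(neg_with), 1)

  # no nested detections in a simple design: NEST_CYCLE is ineligible
  simple <- wdds_simulate(n_animals = 5, design = "simple", seed = 1)
  expect_error(wdds_corrupt(simple, "NEST_CYCLE", 1), "eligible")
  expect_error(wdds_corrupt(ds, "NOT_A_RULE", 1), "not injectable")
})

test_that("partial dates appear at roughly the configured fraction", {
  ds <- wdds_simulate(n_animals = 2000, design = "simple", seed = 13,
                      partial_date_frac = 0.25)
  frac <- mean(is.na(ds$records$collection_day))
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.3)
  expect_true(all(!is.na(ds$records$collection_year)))
  expect_true(validate_wdds(ds)$conformant)
})
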