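# two-row host/ectoparasite fixture: a flea sampled from a rat is itself
# tested for plague in a second row that reuses the Parasite ID
rat_flea <- function(third_level = FALSE, cyclic = FALSE) {
  rec <- data.frame(
    sample_id = c("VI RAT1", "HG FLEA1"),
    animal_id = c("RAT1", "FLEA1"),
    latitude = 40.0, longitude = -105.1,
    sample_collection_method = c("visual inspection", "homogenization"),
    host_identification = c("Rattus rattus", "Ctenocephalides felis"),
    detection_target = c("Siphonaptera", "Yersinia pestis"),
    detection_method = c("morphological identification", "PCR"),
    detection_outcome = "positive",
    parasite_identification = c("Ctenocephalides felis", "Yersinia pestis"),
    parasite_id = c("FLEA1", NA),
    stringsAsFactors = FALSE)
  if (third_level) {
    rec$parasite_id[2] <- "YP1"
    rec <- rbind(rec, data.frame(
      sample_id = "CX YP1", animal_id = "YP1", latitude = 40.0,
      longitude = -105.1, sample_collection_method = "culture",
      host_identification = "Yersinia pestis",
      detection_target = "phage", detection_method = "plaque assay",
      detection_outcome = "positive", parasite_identification = "phage P1",
      parasite_id = NA, stringsAsFactors = FALSE))
  }
  if (cyclic) rec$parasite_id[2] <- "RAT1"
  wdds_dataset(rec)
}

test_that("worked example graph: 2 samples, 1 animal, 2 test edges", {
  g <- build_link_graph(example_dataset())
  expect_equal(sum(g$nodes$type == "sample"), 2)
  expect_equal(sum(g$nodes$type == "animal"), 1)
  expect_equal(sum(g$edges$type == "tests"), 2)
  expect_equal(sum(g$edges$type == "nests"), 0)
  # empty dataset: empty graph
  g0 <- build_link_graph(wdds_dataset(data.frame()))
  expect_equal(nrow(g0$nodes), 0)
  expect_equal(nrow(g0$edges), 0)
})

test_that("nested detections are recovered as chains", {
  g <- build_link_graph(rat_flea())
  nest <- g$edges[g$edges$type == "nests", ]
  expect_equal(nrow(nest), 1)
  expect_equal(nest$from, "RAT1")
  expect_equal(nest$to, "FLEA1")
  ch <- nested_chains(g)
  expect_equal(ch, list(c("RAT1", "FLEA1")))
  # the flea is both a parasite node and an animal node
  expect_true(all(c("parasite", "animal") %in%
                  g$nodes$type[g$nodes$id == "FLEA1"]))

  ch3 <- nested_chains(build_link_graph(rat_flea(third_level = TRUE)))
  expect_equal(ch3, list(c("RAT1", "FLEA1", "YP1")))
})

test_that("cyclic nesting is an error and a NEST_CYCLE issue", {
  bad <- rat_flea(cyclic = TRUE)
  expect_error(nested_chains(build_link_graph(bad)), "NEST_CYCLE")
  r <- validate_wdds(bad)
  expect_true("NEST_CYCLE" %in% rules_fired(r))
  expect_false(r$conformant)
})

test_that("generated nested chains are recovered exactly", {
  nest <- wdds_simulate(n_animals = 12, design = "nested", seed = 31)
  ch <- nested_chains(build_link_graph(nest))
  expected <- lapply(1:12, function(a)
    c(sprintf("SYN25-%04d", a), sprintf("SYNP25-%04d", a)))
  expect_setequal(lapply(ch, paste, collapse = ">"),
                  lapply(expected, paste, collapse = ">"))
})

test_that("pool summary counts linked animals and flags unidentified pools", {
  rec <- data.frame(
    sample_id = c("P1", "P2", "S1"),
    animal_id = c(NA, "M1;M2;M3", "A1"),
    organism_quantity = c(30, NA, NA),
    organism_quantity_units = c("individuals", NA, NA),
    stringsAsFactors = FALSE)
  ps <- pool_summary(wdds_dataset(rec))
  expect_equal(ps$n_linked_animals[ps$sample_id == "P1"], 0L)
  expect_true(ps$unidentified[ps$sample_id == "P1"])
  expect_true(ps$pooled[ps$sample_id == "P1"])
  expect_equal(ps$n_linked_animals[ps$sample_id == "P2"], 3L)
  expect_false(ps$unidentified[ps$sample_id == "P2"])
  expect_equal(ps$n_linked_animals[ps$sample_id == "S1"], 1L)
  expect_false(ps$pooled[ps$sample_id == "S1"])

  # worked example: one animal per sample, not pooled
  ps <- pool_summary(example_dataset())
  expect_equal(ps$n_linked_animals, c(1L, 1L))
  expect_false(any(ps$pooled))

  # side-table links count toward the pool
  pool <- wdds_simulate(n_animals = 4, design = "pooled", seed = 8,
                        pool_size = 5)
  ps <- pool_summary(pool)
  expect_setequal(ps$n_linked_animals, c(0L, 5L))
  expect_equal(ps$unidentified, ps$n_linked_animals == 0)
})

test_that("graph structure is invariant under record reordering", {
  ds <- wdds_simulate(n_animals = 20, design = "multisample", seed = 12)
  g1 <- build_link_graph(ds)
  set.seed(1)
  ds$records <- ds$records[sample(nrow(ds$records)), ]
  g2 <- build_link_graph(ds)
  expect_equal(table(g1$nodes$type), table(g2$nodes$type))
  expect_equal(table(g1$edges$type), table(g2$edges$type))
})

test_that("graph construction scales to large datasets", {
  ds <- wdds_simulate(n_animals = 20000, design = "simple", seed = 2)
  t <- system.time(g <- build_link_graph(ds))
  expect_lt(t[["elapsed"]], 30)
  expect_equal(sum(g$nodes$type == "sample"), 20000)
})

test_that("edge list exports as CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  e <- edge_list(build_link_graph(rat_flea()), f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(e))
  expect_true("nests" %in% back$type)
})
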