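test_that("truncation rounds toward zero and propagates uncertainty", {
  ds <- example_dataset()
  t2 <- truncate_coordinates(ds, 2)
  expect_equal(t2$records$latitude[1], 17.76)
  expect_equal(t2$records$longitude[1], -88.65)
  t0 <- truncate_coordinates(ds, 0)
  expect_equal(t0$records$longitude[1], -88)   # toward zero, not -89
  expect_equal(t0$records$latitude[1], 17)

  # half-cell diagonal formula, against an independent evaluation
  for (dec in c(0, 2, 4)) {
    td <- truncate_coordinates(ds, dec)
    delta <- 0.5 * 10^(-dec)
    phi <- td$records$latitude[1] * pi / 180
    oracle <- sqrt((delta * 111320)^2 + (delta * 111320 * cos(phi))^2)
    expect_equal(td$records$spatial_uncertainty[1], oracle,
                 tolerance = 1e-6)
  }
  # at the equator the diagonal is sqrt(2) * delta * 111320
  eq <- wdds_dataset(data.frame(sample_id = "S", latitude = 0.0049,
                                longitude = 10.12345))
  te <- truncate_coordinates(eq, 2)
  expect_equal(te$records$spatial_uncertainty, sqrt(2) * 0.005 * 111320,
               tolerance = 1e-6)
  expect_error(truncate_coordinates(ds, 9))
})

test_that("uncertainty never decreases under obfuscation", {
  ds <- example_dataset()
  ds$records$spatial_uncertainty <- 50000  # already coarse
  t2 <- truncate_coordinates(ds, 2)
  expect_equal(t2$records$spatial_uncertainty, rep(50000, 2))
  j <- jitter_coordinates(ds, radius_m = 100, seed = 1)
  expect_equal(j$records$spatial_uncertainty, rep(50000, 2))
  j2 <- jitter_coordinates(example_dataset(), radius_m = 100, seed = 1)
  expect_equal(j2$records$spatial_uncertainty, rep(100, 2))
})

test_that("jitter is seeded, bounded, and uniform on the disk", {
  ds <- wdds_simulate(n_animals = 2000, design = "simple", seed = 6,
                      bbox = c(-60, 60, -179, 179))
  R <- 250
  j1 <- jitter_coordinates(ds, radius_m = R, seed = 17)
  j2 <- jitter_coordinates(ds, radius_m = R, seed = 17)
  expect_identical(j1$records, j2$records)
  j3 <- jitter_coordinates(ds, radius_m = R, seed = 18)
  expect_false(identical(j1$records$latitude, j3$records$latitude))

  d <- displacement_m(ds$records$latitude, ds$records$longitude,
                      j1$records$latitude, j1$records$longitude)
  expect_true(all(d <= R * 1.005))
  # radial CDF is r^2/R^2, so (d/R)^2 is uniform
  expect_gt(stats::ks.test((d / R)^2, "punif")$p.value, 0.01)
  # tiny radius: displacement bounded by it
  jt <- jitter_coordinates(ds, radius_m = 0.001, seed = 3)
  dt <- displacement_m(ds$records$latitude, ds$records$longitude,
                       jt$records$latitude, jt$records$longitude)
  expect_true(all(dt <= 0.0011))
})

test_that("jitter needs a seed and skips polar records", {
  ds <- example_dataset()
  expect_error(jitter_coordinates(ds, radius_m = 100), "seed")
  polar <- wdds_dataset(data.frame(sample_id = c("P", "Q"),
                                   latitude = c(89.95, 45),
                                   longitude = c(10, 10)))
  j <- jitter_coordinates(polar, radius_m = 100, seed = 4)
  expect_equal(j$records$latitude[1], 89.95)  # untouched
  expect_false(j$records$latitude[2] == 45 &&
               j$records$longitude[2] == 10)
  expect_true("OBFUSCATION" %in% j$findings$rule)
  # longitudes wrap across the antimeridian into (-180, 180]
  am <- wdds_dataset(data.frame(sample_id = "A", latitude = 0,
                                longitude = 179.9999999))
  ja <- jitter_coordinates(am, radius_m = 5000, seed = 10)
  expect_true(ja$records$longitude > -180 & ja$records$longitude <= 180)
})

test_that("haversine oracle behaves like a metric", {
  expect_equal(displacement_m(10, 20, 10, 20), 0)
  expect_equal(displacement_m(0, 0, 0, 1), 111194.9, tolerance = 1e-4)
  set.seed(2)
  a <- cbind(runif(50, -80, 80), runif(50, -180, 180))
  b <- cbind(runif(50, -80, 80), runif(50, -180, 180))
  expect_equal(displacement_m(a[, 1], a[, 2], b[, 1], b[, 2]),
               displacement_m(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_equal(displacement_m(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_oracle(a[, 1], a[, 2], b[, 1], b[, 2]),
               tolerance = 1e-9)
})

test_that("obfuscation leaves an auditable provenance trail", {
  ds <- example_dataset()
  expect_true(assert_raw_coordinates(ds))
  t2 <- truncate_coordinates(ds, 2)
  expect_equal(length(t2$provenance), 1)
  expect_equal(t2$provenance[[1]]$method, "truncate_coordinates")
  expect_equal(t2$provenance[[1]]$params$decimals, 2)
  expect_error(assert_raw_coordinates(t2), "obfuscated")

  j <- jitter_coordinates(t2, radius_m = 100, seed = 5)
  expect_equal(length(j$provenance), 2)
  expect_equal(j$provenance[[2]]$params$seed, 5)
  jw <- jitter_coordinates(ds, radius_m = 100, seed = 5,
                           record_seed = FALSE)
  expect_equal(jw$provenance[[1]]$params$seed, "withheld")
})
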