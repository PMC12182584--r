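# shared fixtures and independent oracles for the test suite

# CSV text from a list of named raw-cell vectors (slug headers)
csv_from_cells <- function(cells_list, registry = core_registry()) {
  paste(c(paste(registry$slug, collapse = ","),
          vapply(cells_list, function(cl) paste(cl, collapse = ","), "")),
        collapse = "\n")
}

# independent ISO 7064 mod 11-2 oracle: the full 16-character string
# (X = 10) is valid iff sum(d_i * 2^(n-i)) mod 11 == 1
orcid_oracle <- function(s) {
  s <- gsub("-", "", s)
  if (!grepl("^[0-9]{15}[0-9X]$", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  vals <- match(chars, c(as.character(0:9), "X")) - 1L
  total <- 0L; pow <- 1L
  for (i in rev(seq_along(vals))) {
    total <- (total + vals[i] * pow) %% 11L
    pow <- (pow * 2L) %% 11L
  }
  total == 1L
}

# closed-form haversine, written independently of displacement_m()
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlmb <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlmb / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# the record/dataset-scope rules that wdds_corrupt() can inject
mutation_rules <- function()
  c("REQ_FIELD", "VOCAB", "UNITS_PAIR", "COORD_RANGE", "UNCERT_RANGE",
    "DATE_VALID", "PLACEHOLDER", "POS_NO_ID", "NEG_WITH_ID", "DUP_ROW",
    "XREC_CONFLICT", "POOL_LINK", "NEST_CYCLE")

# conformant base dataset on which a given rule is injectable
base_for_rule <- function(rule, seed = 99) {
  design <- switch(rule, NEST_CYCLE = "nested", POOL_LINK = "pooled",
                   "multisample")
  wdds_simulate(n_animals = 30, design = design, seed = seed,
                prevalence = 0.3)
}

expect_same_records <- function(a, b) {
  expect_identical(names(a), names(b))
  for (cl in names(a)) expect_equal(a[[cl]], b[[cl]], ignore_attr = TRUE)
}

rules_fired <- function(report) unique(report$issues$rule)
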