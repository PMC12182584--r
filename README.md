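# wdds

Tools for validating, sharing, and simulating wildlife disease
surveillance data against a minimum data standard.

## The problem

Wildlife disease studies — bats screened for coronaviruses, fleas pulled
off rats and tested for plague, mosquito pools assayed for arboviruses —
are mostly published as summary prevalence tables. Those summaries cannot
be disaggregated back to the individual test, which makes it impossible
to compare prevalence across populations, years, or species, and negative
results are routinely lost. The remedy is a *minimum data standard*:
share the raw data as a rectangular ("tidy") table in which **each row is
the outcome of one diagnostic test on one sample**, with a small set of
standardized columns and project-level metadata.

This package implements that standard as software, for field biologists
and data managers who want their datasets checked and packaged before
deposit, and for synthesis researchers who want to validate what they
ingest:

* a typed registry of the **40 core fields** (11 sampling, 13 host, 16
  parasite; 9 required) and **24 project-metadata properties** (7
  required, DataCite-derived), with emitters for a JSON Schema (draft
  2020-12), a CSV template, and a data dictionary;
* a **rule-based validator** producing record-addressed, rule-tagged
  error/warning reports (requiredness with its conditional exemptions,
  closed vocabularies, units pairing, coordinate and calendar checks,
  placeholder detection, cross-record consistency, pooled-link integrity,
  nesting cycles); a dataset is *conformant* iff it has zero errors;
* standard-conformant **CSV/JSON I/O**: UTF-8, comma-separated, period
  decimal, blank cells as first-class missing values (never `"NA"`),
  Unicode-minus normalization, extra columns preserved;
* PID syntax checks for **DOI, ORCID (ISO 7064 mod 11-2 checksum), ROR,
  and Crossref Funder IDs**;
* a **Darwin Core occurrence crosswalk** over the standard's 14 annotated
  term equivalences;
* **coordinate obfuscation** for sensitive records (truncation toward
  zero, seeded uniform-disk jitter) with uncertainty propagation and an
  auditable provenance log;
* a **linkage graph** for multi-sample, multi-test, pooled, and nested
  host–parasite records;
* a seeded **synthetic-data generator** covering all of those designs,
  plus targeted corruptions for mutation-testing the validator.

## Worked example

The package ships the standard's published worked example: one vampire
bat (*Desmodus rotundus*, animal BZ19-114) sampled in Belize in April
2019, whose oral swab was positive for a novel alphacoronavirus
(GenBank OM240578) and whose rectal swab was negative.

```r
library(wdds)

ds <- example_dataset()
ds
#> <wdds_dataset: 2 records, 0 extra fields>

validate_wdds(ds)
#> Validation report: CONFORMANT (0 errors, 0 warnings)
```

Note what conformance means here: the negative row's blank parasite
identification is *legal* (parasite identity must be empty for negative
results), and the longitude was printed with a Unicode minus sign, which
the reader normalizes to −88.6521.

Export to a Darwin Core occurrence table (host-centric: `scientificName`
is the host; the parasite evidence lives in `associatedOccurrences` /
`occurrenceStatus`):

```r
occ <- to_darwin_core(ds)
occ[, c("occurrenceID", "eventDate", "scientificName",
        "occurrenceStatus", "otherCatalogNumbers")]
#>               occurrenceID  eventDate    scientificName occurrenceStatus
#> 1 OS BZ19-95|Coronaviridae 2019-04-23 Desmodus rotundus          present
#> 2 RS BZ19-95|Coronaviridae 2019-04-23 Desmodus rotundus           absent
#>   otherCatalogNumbers
#> 1            OM240578
#> 2                <NA>
```

Obfuscate the roost location before sharing — coordinates are truncated
toward zero and the spatial uncertainty is raised to the half-cell
diagonal in meters, with a provenance entry recording the operation:

```r
obf <- truncate_coordinates(ds, 2)
obf$records[1, c("latitude", "longitude", "spatial_uncertainty")]
#>   latitude longitude spatial_uncertainty
#> 1    17.76    -88.65            768.6234
```

Simulate a surveillance campaign and mutation-test the validator:

```r
sim <- wdds_simulate(n_animals = 500, design = "multisample",
                     prevalence = 0.1, seed = 42)
sum(sim$records$detection_outcome == "positive")  # 106 of 1000 tests

validate_wdds(wdds_corrupt(sim, "UNITS_PAIR", seed = 1))
#> Validation report: NOT conformant (1 error, 0 warnings)
#>   [e] UNITS_PAIR    row 836:mass_units  'mass' is populated but 'mass_units' is blank
```

## Documentation

The methods vignette (`vignettes/wdds-methods.Rmd`) describes the
validation rule set and its severity policy, the conditional-requiredness
semantics, the obfuscation math, what the synthetic generator does and
does not emulate, and the design decisions taken where the standard
leaves choices open.
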