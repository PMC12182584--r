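---
title: "Methods: the data standard, its validator, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the data standard, its validator, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdds)
```

## The data model

The unit of observation is one diagnostic-test outcome: each row of a
dataset records one test, on one sample, from one animal (or a pool of
animals). Three categories of columns describe it — sampling context
(where, when, how the sample was taken), the host organism, and the
parasite side (what was screened for, how, and what was found). The core
registry (`core_registry()`) encodes all 40 fields with their value kind
(text/number/integer/boolean), requiredness, conditional-dependency
links, closed vocabularies, and Darwin Core equivalences; it is the
single source of truth from which the CSV template, the data dictionary,
the JSON Schema, the parser, and the validator are all derived, so they
cannot drift apart.

Relationships between rows are deliberately flexible: the same animal
may contribute several samples, one sample may be tested several times,
a pooled sample may link to zero or many animals, and a detected
parasite may itself be the "animal" of another row (a flea pulled off a
rat, then tested for *Yersinia pestis*). Animal IDs and Parasite IDs are
treated as one shared identifier namespace so those nested detections
can be joined; the cost of that choice is that an accidental collision
(the same string used for an unrelated animal) is undetectable, which we
document rather than guard against.

## Requiredness is two-level, and conditional

Nine fields are required. For a column, "required" means it must exist;
for a cell, it means non-blank — with two deliberate exemptions that
make real datasets validatable:

* **Parasite identification** is required as a column, but its cells
  must be empty for negative results. A positive result without an
  identification is a warning (`POS_NO_ID`), not an error, since the
  identification may be pending; a negative result *with* one is an
  error (`NEG_WITH_ID`).
* **Detection target, method, and outcome** are exempt on records of
  untested samples (blank outcome), which researchers may legitimately
  include — e.g. captured animals that were never sampled. The exemption
  must cover all three fields at once or such rows could never validate;
  this is an artifact decision the standard's text does not settle.

Blank is a first-class state: on disk an empty cell, in memory `NA`,
in JSON `null`. Placeholder tokens (`NA`, `N/A`, `NaN`, `NULL`, `NONE`,
`-`, `.`, case-insensitive) are converted to blank at parse time with a
warning finding, so no placeholder ever inhabits a typed slot. The
standard names only `"NA"`; the rest are common equivalents we add.

## The rule registry and severity policy

Every check has a stable rule id (`wdds_rules()`), and a dataset is
conformant iff its report has zero error-severity issues. The severity
policy: violations of an explicit statement of the standard are errors
(requiredness, vocabulary, units pairing, coordinate/calendar ranges,
negative-with-identity, dangling pool links, nesting cycles); deviations
from best-practice advice are warnings (placeholders, exact (0, 0)
coordinates — a null-island heuristic of ours, not the standard's —
duplicate rows, positive-without-identity, cross-record disagreement on
host identity or sex). Duplicate full rows are only warned about because
one sample genuinely may be tested twice; life stage and body
measurements may change between captures, so only host identification
and sex are cross-checked per animal.

Calendar checking fires only on the parts present: partial dates (blank
day/month, as with archival museum material) are legal, and an
impossible combination (February 30th) is an error only when day, month,
and year are all given.

`TYPE` (unparseable cell) and `PID_SYNTAX` (malformed persistent
identifier) are parse-time and metadata-scope rules; they are exercised
by direct tests rather than by `wdds_corrupt()`, which can only inject
faults into an already-typed dataset. The other thirteen rules are all
injectable, and the mutation suite checks each one fires on a corrupted
dataset and not on its conformant original.

## JSON Schema equivalence

`emit_json_schema()` renders the registry as a draft 2020-12 schema over
records serialized as JSON objects (blank = `null`). The required list
names the nine required fields; conditional cell semantics are encoded
with nullable union types plus an `allOf`/`if`/`then` block (a non-null
outcome forces non-null target and method). `schema_accepts()` is a
small evaluator of exactly that schema subset which walks the emitted
document — not the registry — giving an independent second route. The
test suite and acceptance script fuzz 1,000 records and require the two
routes to agree record-by-record on the requiredness/vocabulary/type
verdict. Out-of-scope rules (units pairing, ranges, cross-record checks)
are intentionally absent from the schema, which validates records in
isolation.

## Coordinate obfuscation

Two generalizations are offered for sensitive locations, both of which
raise `spatial_uncertainty` (meters) and append a provenance entry.

*Truncation* rounds toward zero to `decimals` places (so values never
imply precision beyond the cell even in magnitude), and sets the
uncertainty to at least the half-cell diagonal
$\sqrt{(\Delta \cdot 111320)^2 + (\Delta \cdot 111320 \cos\varphi)^2}$
with $\Delta = 0.5\cdot 10^{-\text{decimals}}$ and $\varphi$ the
truncated latitude; 111,320 m/degree is the equatorial scale of the
local equirectangular approximation.

*Jitter* displaces each point uniformly on a disk of radius `radius_m`:
$r = R\sqrt{u}$, $\theta \sim U(0, 2\pi)$, converted to degrees with the
same local approximation. The seed is a mandatory argument — the
operation is reproducible by the data owner (as documented obfuscation
should be) while `record_seed = FALSE` keeps the seed out of the
provenance of a published copy. Records within 0.1° of a pole are
skipped (the longitude conversion degenerates as $1/\cos\varphi$);
longitudes are wrapped into (−180, 180]. The local approximation
overshoots the great-circle radius by under 0.5 % for latitudes within
±60°, which is the tolerance the displacement-bound test uses against
the haversine oracle (Earth radius 6,371,000 m, via `geosphere`).

## What the synthetic generator emulates — and what it does not

`wdds_simulate()` produces standard-conformant datasets under a fixed
seed, across five relationship designs: `simple` (one row per animal),
`multisample` (default 2 samples/animal), `multitest` (default 2
targets/sample), `nested` (each host yields a positively identified
ectoparasite whose Parasite ID is reused as the Animal ID of a child
record tested for *Yersinia pestis*), and `pooled` (blank Animal ID,
`organism_quantity = pool_size`, default 30, with a pooled-links side
table for every second pool — exercising both the "unidentified pool"
and the "per-animal data in an additional file" conventions).

Defaults are chosen to look like a realistic small vector-borne/wildlife
surveillance campaign: test outcomes are i.i.d. Bernoulli with
`prevalence = 0.1` (a typical order for viral screening of wild hosts);
hosts are drawn from a short list of real binomials (including
*Desmodus rotundus*); coordinates are uniform over a Belize-sized
bounding box matching the worked example's region; dates are uniform
over 2019 with 10 % of records given blank day/month to exercise the
archival partial-date path; masses are log-normal around 30 g (bats) in
kg; identifiers follow the exemplar convention prefix-year-serial
(`SYN25-0001`), and accession strings carry the prefix `SYN` so they are
deliberately non-resolvable.

The generator makes no claim of epidemiological realism: outcomes are
independent (no transmission dynamics, no spatial or temporal
autocorrelation, no host-species effects), prevalence is homogeneous,
and pool-level outcomes ignore pool size. Passing tests therefore show
that the machinery (parsing, validation, round-trips, graphs, exports)
is correct on structurally realistic data — not that the package has
been exercised against the messiness of real field data beyond the
dialect quirks it explicitly normalizes.

## Numerical and formatting choices

* CSV numbers are written with the shortest decimal representation that
  round-trips the double exactly, so `read(write(x))` is lossless.
* Unicode minus (U+2212) is normalized to ASCII before numeric parsing;
  the packaged worked example retains the typeset minus to pin this.
* Vocabulary matching is case-insensitive with canonicalization to
  lowercase at parse time, warning-free.
* Boolean cells accept TRUE/True/true spellings; canonical output is
  TRUE/FALSE.
* Degenerate inputs: an empty dataset yields a header-only CSV, an empty
  graph, an all-absent fit-for-purpose summary; an empty registry is a
  hard error for artifact emitters.
* `wdds_corrupt()` picks its victim record with a seeded draw and errors
  explicitly when no record is eligible (e.g. a nesting cycle cannot be
  injected into a design without nested detections).

## Open choices made here

* **Metadata composition.** The 24-property/7-required structure is
  documented, but the canonical property list lives in the standard's
  supplementary material; the registry here is a provisional DataCite
  kernel + generalist-repository composition constrained to those
  counts, and is flagged as provisional in its help page.
* **Darwin Core orientation.** An export row represents the *host*
  occurrence (`scientificName` = host identification), following the
  standard's own term annotations; the parasite-centric convention also
  exists in the wild, so the choice is stated prominently in
  `to_darwin_core()`'s documentation. `occurrenceStatus` maps
  positive→present, negative→absent, inconclusive→blank (not
  "doubtful", to avoid overclaiming).
* **Pooled-sample encodings.** The standard mentions an "additional
  file" for per-animal pool data without a format; we accept both a
  `;`-separated Animal ID list and a two-column `sample_id,animal_id`
  side table. A pool is "unidentified" when it has an organism quantity
  but zero linked animals from either encoding.
* **ROR checksum.** ROR IDs are validated by syntax (leading 0, six
  Crockford base32 characters, two digits); the registry's mod 97-10
  checksum is not recomputed, since the standard asks that PIDs be used,
  not verified.
* **Exit codes.** 0/1/2/3 (conformant / warnings under strict / errors /
  unusable input) for CI pipelines.

## Problem sizes

The test suite and acceptance script size their simulations to keep a
full run fast while leaving the statistical checks meaningful: 50 random
generator configurations for closure, 1,000 fuzzed records for schema
equivalence, 10,000 records for the jitter bound and radial KS test and
for prevalence recovery, 10,000 random candidates for the ORCID
checksum cross-check, and 20,000 records for the graph-scaling check.

## Known limitations

Taxonomic names are not checked against any backbone (GBIF/NCBI);
GenBank accessions are not resolved; PID validation is syntactic only
and never touches the network; obfuscation offers no formal privacy
guarantee (no k-anonymity or differential privacy) and deciding *which*
records are sensitive remains the researcher's call; XLSX templates and
Darwin Core Archive packaging are out of scope (CSV only); and identifier
collisions across the shared Animal/Parasite ID namespace cannot be
detected.
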