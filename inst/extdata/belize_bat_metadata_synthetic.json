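{
  "Title": "Coronavirus screening of common vampire bats in Belize (worked example)",
  "Description": "Worked-example project metadata for the packaged two-record dataset: one Desmodus rotundus sampled in Belize in 2019, with an oral swab positive for a novel alphacoronavirus and a rectal swab negative. Illustrative values assembled for documentation; not the deposited metadata of any real archive record.",
  "Creators": ["Example, Alice", "Example, Benjamin"],
  "Creator ORCID": ["0000-0002-1825-0097"],
  "Creator affiliation": ["Georgetown University"],
  "Affiliation ROR": ["https://ror.org/05vzafd60"],
  "Publication year": 2025,
  "Publisher": "Zenodo",
  "Resource type": "Dataset",
  "Identifier": "10.5072/zenodo.0000000",
  "License": "CC-BY-4.0",
  "Subjects": ["wildlife disease", "coronavirus", "Chiroptera", "surveillance"],
  "Language": "en",
  "Version": "1.0",
  "Funder name": "Example Science Foundation",
  "Funder identifier": "10.13039/100000001",
  "Award number": "ABC-1234567",
  "Related identifier": "10.3390/v9120364",
  "Related identifier type": "DOI",
  "Relation type": "IsSupplementTo",
  "Contributors": ["Example, Carol"],
  "Contributor type": "DataCurator",
  "Coverage dates": "2019-04-23/2019-04-23",
  "Geographic coverage description": "Orange Walk District, Belize"
}
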