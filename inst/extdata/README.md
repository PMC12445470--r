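# Reference tables

Published forecast tables for 12 western Chinese provinces, 2024-2040, used
as printed-arithmetic inputs by the worked examples, the test suite and
`scripts/acceptance.R`. Values are in units of 万 (10,000) persons except
the concentration table (percent).

- `table1_school_age_population.csv` — projected school-age population by
  grade age-label (3-14) with per-stage totals, all 12 regions combined.
- `table2_rural_concentration.csv` — projected rural share of enrollment
  (percent) per education stage.
- `table3_preschool_rural.csv`, `table4_primary_rural.csv`,
  `table5_junior_rural.csv` — projected rural student numbers per region
  and stage. (The source labels these as teacher numbers while printing
  values that equal the rural enrollments quoted alongside them; they are
  stored here under the internally consistent student reading, and teacher
  requirements are derived by dividing by the staffing ratios.)
- `reference_endpoints.csv` — endpoint pairs quoted in the running text
  together with the decline percentages printed for them.

A handful of entries contained typographic digit-spacing artifacts in the
extracted source (e.g. "30.9 0"); they are stored here as the evident
numbers (30.90).
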