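# Input file schemas

All tables are UTF-8, comma-delimited CSV with required headers. Category
labels are lowercase snake_case enumerations; unknown labels are rejected
with the offending value and line number. Vocabularies:

- `sex`: `male`, `female`
- `age_band`: `under_35`, `35_44`, `45_54`, `55_64`, `65_plus`
- `location`: `urban`, `rural`
- `status`: `full_time`, `part_time`, `temporary_exit`, `permanent_exit`
  (active statuses only where noted)
- `chapter`: free condition-chapter vocabulary (ICPC-2 chapter headings in
  practice); `prevent_admin` is reserved for the preventive/administrative
  consultation share
- `type` (entries): `graduate`, `migrant`

Run configurations are YAML (see `read_run_config()`); reports are JSON.

| file | columns | notes |
|---|---|---|
| `stock.csv` | `year,sex,age_band,location,status,headcount` | headcounts >= 0; fractional allowed |
| `hours.csv` | `sex,age_band,status,weekly_hours` | active statuses; part-time mean < 35 <= full-time mean |
| `transitions.csv` | `sex,age_band,from_location,from_status,to_location,to_status,probability` | probabilities in [0,1]; only allowed moves (see `transition_table()`) |
| `entries.csv` | `[year,]type,count` | counts held at base-year values when `year` is absent |
| `priors.csv` | `sex,age_band,from_location,from_status,to_location,to_status,alpha,beta,mult_low,mult_high` | beta shapes > 0; multiplier range within [-0.10, 0.10] by convention |
| `targets.csv` | `year,sex,age_band,location,status,headcount` | >= 2 years per stratum (linear smoothing) |
| `population.csv` | `year,sex,age_band,persons` | must cover every projected year |
| `burden.csv` | `chapter,sex,age_band,incident_cases,prevalent_cases` | base-year cases |
| `mix.csv` | `chapter,sex,age_band,proportion` | shares >= 0; may sum above 1 across chapters (multiple problems per consultation) |
| `lengths.csv` | `sex,age_band,mean_minutes` | mean consultation length, minutes > 0 |
| `attendances.csv` | `year,sex,age_band,consultations` | observed consultation totals |
| `mapping.csv` | `source_category,icpc2_chapter` | burden-category to chapter crosswalk |

Stable CLI flags across subcommands: `--seed`, `--tolerance`,
`--n-samples`, `--scenario`, `--out`.
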