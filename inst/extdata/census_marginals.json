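{
  "population_size": 1863,
  "income_distribution": {
    "nil_or_negative": 0.08,
    "1-149": 0.10,
    "150-299": 0.16,
    "300-399": 0.14,
    "400-599": 0.22,
    "600-799": 0.12,
    "800-999": 0.09,
    "1000_plus": 0.09
  },
  "language_at_home": 0.067,
  "education_year10": 0.8027,
  "_comment": "Gender-by-age strata from the 2016 Census profile of the study community; income_distribution is a synthetic band distribution whose median band (400-599) is consistent with the published census median weekly income of $420."
}
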