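# Example column-mapping dialect for read_cohort_csv().
# One `file header = canonical field` pair per line.
ID = subject_id
Group = cohort
Subtype = diagnosis_subtype
Seafood servings/month = seafood_meals_per_month
AA (20:4n-6) = AA
DGLA (20:3n-6) = DGLA
DHA (22:6n-3) = DHA
EPA (20:5n-3) = EPA
Elaidic acid = elaidic
Linoleic acid = LA
Oleic acid = oleic
Palmitelaidic acid = palmitelaidic
Palmitic acid = palmitic
Palmitoleic acid = palmitoleic
Stearic acid = stearic
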