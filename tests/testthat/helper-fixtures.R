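# Small hand-built cohort fixtures used across test files.

# measured panel rows that sum well below 100 so closure never warns
tiny_measured_row <- function(aa = 20, dgla = 2, dha = 3.7, epa = 0.35,
                              la = 14) {
  data.frame(AA = aa, DGLA = dgla, DHA = dha, EPA = epa, elaidic = 0.18,
             LA = la, oleic = 13.9, palmitelaidic = 0.02, palmitic = 20.4,
             palmitoleic = 0.21, stearic = 19.5)
}

tiny_cohort <- function(n_asd = 3, n_neu = 3, seed = 42) {
  set.seed(seed)
  n <- n_asd + n_neu
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    tiny_measured_row(aa = 20 + rnorm(1), dgla = 2 + 0.2 * rnorm(1),
                      dha = 3.7 + 0.3 * rnorm(1),
                      epa = 0.35 + 0.05 * abs(rnorm(1)),
                      la = 14 + rnorm(1))))
  tab <- cbind(
    data.frame(subject_id = sprintf("T%02d", seq_len(n)),
               cohort = rep(c("ASD", "NEU"), c(n_asd, n_neu)),
               diagnosis_subtype = c(rep("autism", n_asd), rep("none", n_neu)),
               seafood_meals_per_month = rpois(n, 4)),
    rows)
  compute_derived(cohort_table(tab, provenance = "test fixture"))
}

# a default-condition synthetic cohort shared by several files
default_tab <- function(seed = 11) generate_cohort(default_study_spec(seed))
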