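# Small deterministic fixtures shared across test files.

tiny_schema <- function() {
  feature_schema(
    D = list(age = "numeric", sex = c("female", "male")),
    C = list(bmi = "numeric", glucose = "numeric"),
    S_lif = list(smoke = c("never", "former", "current"),
                 diet = c("low", "high")),
    S_gen = list(fh_diab = c("no", "yes"))
  )
}

tiny_cohort <- function() {
  dat <- data.frame(
    age = c(40, 55, 62, 48, 70, 35),
    sex = c("female", "male", "female", "female", "male", "male"),
    bmi = c(21, 28, 31, 24, 27, 23),
    glucose = c(90, 130, 160, 100, 145, 95),
    smoke = c("never", "current", "former", NA, "never", "current"),
    diet = c("low", "high", NA, "low", "high", "low"),
    fh_diab = c("no", "yes", "yes", "no", NA, "no"),
    stringsAsFactors = FALSE
  )
  y <- c("non_MAFLD", "nondiabetic_MAFLD", "diabetic_MAFLD",
         "non_MAFLD", "diabetic_MAFLD", "non_MAFLD")
  cohort_table(dat, y, tiny_schema())
}

# moderate synthetic cohort for pipeline-level tests
small_sim <- function(n = 300, rho = 0.8, seed = 1, ...) {
  generate_cohort(synthetic_config(n = n, rho = rho, seed = seed, ...))
}
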