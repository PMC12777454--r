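# Fixtures built in code. Small handcrafted raw tables exercising the
# cleaning rules, plus cached synthetic cohorts so expensive generation runs
# once per test session.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# four hand-written patients: one clean single-visit, one clean three-visit
# with a medication switch, one under-age, one whose records start at visit 2
tiny_raw_tables <- function() {
  patients <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    gender = c("M", "F", "M", "F"),
    ethnicity = c("WHITE - RUSSIAN", "BLACK/AFRICAN AMERICAN",
                  "HISPANIC/LATINO - PUERTO RICAN", "ASIAN"),
    age = c(25, 32, 17, 30),
    icd_code = c("295.70", "F20.0", "295.30,296.20", "295.90"))
  visits <- tibble::tibble(
    patient_id = c("A", "B", "B", "B", "D", "D"),
    admit_time = ts(c("2019-01-01 08:00:00", "2019-02-01 09:00:00",
                      "2019-03-10 10:00:00", "2019-06-01 11:00:00",
                      "2019-05-01 08:00:00", "2019-07-01 08:00:00")),
    discharge_time = ts(c("2019-01-08 08:00:00", "2019-02-08 09:00:00",
                          "2019-03-20 10:00:00", "2019-06-11 11:00:00",
                          "2019-05-06 08:00:00", "2019-07-08 08:00:00")),
    comorbidity_count = c(2, 1, 3, 2, 0, 1),
    visit_number = c(1, 1, 2, 3, 2, 3))
  prescriptions <- tibble::tibble(
    patient_id = c("A", "B", "B"),
    admit_time = ts(c("2019-01-01 08:00:00", "2019-02-01 09:00:00",
                      "2019-03-10 10:00:00")),
    drug = c("olanzapine", "risperidone", "haloperidol"),
    start_time = ts(c("2019-01-01 10:00:00", "2019-02-01 12:00:00",
                      "2019-03-11 09:00:00")))
  list(patients = patients, visits = visits, prescriptions = prescriptions)
}

# session-cached synthetic cohorts (generation + assembly is the slow part)
.fixture_cache <- new.env(parent = emptyenv())

cached_synth <- function(n, seed, effect_size = 1, n_subgroups = 4) {
  key <- sprintf("synth_%d_%d_%s_%d", n, seed, format(effect_size),
                 n_subgroups)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_cohort(cohort_spec(
      n_patients = n, seed = seed, effect_size = effect_size,
      n_subgroups = n_subgroups))
  }
  .fixture_cache[[key]]
}

cached_cohort <- function(n, seed, effect_size = 1, n_subgroups = 4) {
  key <- sprintf("cohort_%d_%d_%s_%d", n, seed, format(effect_size),
                 n_subgroups)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- as_cohort(
      cached_synth(n, seed, effect_size, n_subgroups))
  }
  .fixture_cache[[key]]
}

# a feature row with every schema column present (visit-3 style)
full_feature_row <- function(age = 30, comorb = 2, gender = "M",
                             ethnicity = "White") {
  tibble::tibble(
    gender = gender, ethnicity = ethnicity, age_years = age,
    comorbidity_count = comorb,
    los_1 = 7, gap_1 = 30, drug_1 = "olanzapine", switch_1 = 0,
    los_2 = 5, gap_2 = 60, drug_2 = "risperidone", switch_2 = 1)
}

# hand-built srx_cohort where patients form tight feature clusters with
# cluster-constant outcomes; used for neighbourhood-size selection checks
clustered_cohort <- function(n_clusters = 13, cluster_size = 10,
                             seed = 99, jitter = 0.1,
                             identical_outcomes = FALSE) {
  withr::with_seed(seed, {
    n <- n_clusters * cluster_size
    cl <- rep(seq_len(n_clusters), each = cluster_size)
    pid <- sprintf("C%03d", seq_len(n))
    age <- 20 + cl * 1.5 + rnorm(n, 0, jitter)
    comorb <- cl * 2 + rnorm(n, 0, jitter)
    los <- if (identical_outcomes) rep(10, n) else
      (cl - 1) / (n_clusters - 1) * 40 + rnorm(n, 0, jitter)
    patients <- tibble::tibble(
      patient_id = pid, gender = "M", ethnicity = "White",
      age_years = as.integer(round(age)), diagnosis_icd10 = "F20.9")
    admit <- ts("2019-01-01 00:00:00") + seq_len(n) * 3600
    visits <- tibble::tibble(
      patient_id = pid, visit_index = 1L, admit_time = admit,
      discharge_time = admit + pmax(los, 0.5) * 86400,
      length_of_stay_days = pmax(los, 0.5), comorbidity_count = comorb)
    consultations <- tibble::tibble(
      patient_id = pid, visit_index = 1L, arm = "olanzapine",
      history_max_visit = 0L,
      gender = "M", ethnicity = "White", age_years = age,
      comorbidity_count = comorb,
      los_1 = NA_real_, gap_1 = NA_real_, drug_1 = NA_character_,
      switch_1 = NA_real_, los_2 = NA_real_, gap_2 = NA_real_,
      drug_2 = NA_character_, switch_2 = NA_real_)
    instances <- tibble::tibble(
      patient_id = pid, drug = "olanzapine", init_visit = 1L,
      switch_count = 0L, switch_days = NA_real_, gap_days = NA_real_,
      los_days = pmax(los, 0.5), n_visits = 1L)
    structure(list(patients = patients, visits = visits,
                   consultations = consultations, instances = instances,
                   exclusions = tibble::tibble(reason = character(),
                                               n = integer())),
              class = "srx_cohort")
  })
}
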