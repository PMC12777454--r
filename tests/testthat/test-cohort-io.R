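test_that("first code extraction splits on comma and trims", {
  expect_identical(first_code("295.30,296.20"), "295.30")
  expect_identical(first_code("F20.0"), "F20.0")
  # split-then-trim oracle
  raw <- " F25.9 , F32.9"
  expect_identical(first_code(raw),
                   trimws(strsplit(raw, ",")[[1]][1]))
  expect_error(first_code("   "), class = "srx_empty_field_error")
  expect_error(first_code(character(0)), class = "srx_empty_field_error")
})

test_that("ICD-9 schizophrenia codes map to ICD-10 and mapping is idempotent", {
  expect_identical(map_icd9_to_icd10("295.70"), "F25.9")
  expect_identical(map_icd9_to_icd10("295.3"), "F20.0")
  expect_identical(map_icd9_to_icd10("F20.0"), "F20.0")
  expect_error(map_icd9_to_icd10("296.20"), class = "srx_unknown_code_error")
  codes <- c("295.10", "295.2", "295.30", "295.4", "295.5", "295.70",
             "295.90", "F20.1", "F25.9", "F21")
  once <- map_icd9_to_icd10(codes)
  expect_identical(map_icd9_to_icd10(once), once)
  expect_true(all(grepl("^F2", once)))
})

test_that("ethnicity consolidation follows the dialect table", {
  expect_identical(consolidate_ethnicity("WHITE - RUSSIAN"), "White")
  expect_identical(consolidate_ethnicity("HISPANIC/LATINO - PUERTO RICAN"),
                   "Hispanic/Latino")
  expect_identical(consolidate_ethnicity("MULTIRACIAL"), "EXCLUDE")
  expect_error(consolidate_ethnicity("KLINGON"),
               class = "srx_unknown_label_error")
})

test_that("inclusion criteria retain 18-40 F2x patients and drop broken visit sequences", {
  raw <- tiny_raw_tables()
  out <- apply_inclusion_criteria(raw$patients, raw$visits)
  # C is under-age, D has no initial visit record
  expect_setequal(out$patients$patient_id, c("A", "B"))
  expect_true(all(out$patients$age_years >= 18 & out$patients$age_years <= 40))
  expect_true(all(grepl("^F2", out$patients$diagnosis_icd10)))
  # exclusion-reason counts account for every dropped patient
  pat_reasons <- out$exclusions[out$exclusions$reason != "visits_beyond_third_dropped", ]
  expect_identical(sum(pat_reasons$n),
                   nrow(raw$patients) - nrow(out$patients))
})

test_that("admissions are capped at the third visit, patient kept", {
  raw <- tiny_raw_tables()
  extra <- tibble::tibble(
    patient_id = "B",
    admit_time = ts(c("2019-08-01 08:00:00", "2019-09-01 08:00:00")),
    discharge_time = ts(c("2019-08-05 08:00:00", "2019-09-05 08:00:00")),
    comorbidity_count = c(1, 1), visit_number = c(4, 5))
  out <- apply_inclusion_criteria(raw$patients,
                                  dplyr::bind_rows(raw$visits, extra))
  expect_true("B" %in% out$patients$patient_id)
  expect_identical(max(out$visits$visit_index[out$visits$patient_id == "B"]), 3L)
  dropped <- out$exclusions$n[out$exclusions$reason == "visits_beyond_third_dropped"]
  expect_identical(dropped, 2L)
})

test_that("feature vectors respect the per-visit schema and temporal guard", {
  pat <- tibble::tibble(gender = "M", ethnicity = "White", age_years = 28L)
  cur2 <- list(visit_index = 2L, admit_time = ts("2019-02-07 08:00:00"),
               comorbidity_count = 3)
  hist1 <- tibble::tibble(
    visit_index = 1L, admit_time = ts("2019-01-01 08:00:00"),
    discharge_time = ts("2019-01-08 08:00:00"), length_of_stay_days = 7,
    arm = "olanzapine", multi_init = FALSE)

  v1 <- build_feature_vector(pat, hist1[0, ],
                             list(visit_index = 1L,
                                  admit_time = ts("2019-01-01 08:00:00"),
                                  comorbidity_count = 2))
  expect_false(anyNA(v1[c("gender", "ethnicity", "age_years",
                          "comorbidity_count")]))
  expect_true(all(is.na(v1[c("los_1", "gap_1", "drug_1", "switch_1",
                             "los_2", "gap_2", "drug_2", "switch_2")])))

  v2 <- build_feature_vector(pat, hist1, cur2)
  expect_equal(v2$los_1, 7)
  expect_equal(v2$gap_1, 30)  # 2019-01-08 -> 2019-02-07
  expect_identical(v2$drug_1, "olanzapine")
  expect_equal(v2$switch_1, 0)
  expect_true(all(is.na(v2[c("los_2", "gap_2", "drug_2", "switch_2")])))

  hist_bad <- hist1
  hist_bad$visit_index <- 3L
  hist_bad$admit_time <- ts("2019-05-01 08:00:00")
  expect_error(build_feature_vector(pat, hist_bad, cur2),
               class = "srx_temporal_leakage_error")
})

test_that("cohort assembly derives arms, switches and utilisation quantities", {
  raw <- tiny_raw_tables()
  co <- build_cohort(raw$patients, raw$visits, raw$prescriptions)
  # A: single visit on olanzapine, no switch
  ia <- co$instances[co$instances$patient_id == "A", ]
  expect_identical(ia$drug, "olanzapine")
  expect_identical(ia$switch_count, 0L)
  expect_true(is.na(ia$gap_days))
  expect_equal(ia$los_days, 7)
  # B: risperidone initiated visit 1, haloperidol visit 2 = one switch
  ib <- co$instances[co$instances$patient_id == "B", ]
  expect_setequal(ib$drug, c("risperidone", "haloperidol"))
  expect_identical(ib$switch_count[ib$drug == "risperidone"], 1L)
  expect_identical(ib$switch_count[ib$drug == "haloperidol"], 0L)
  # B visit 3 has no new start: arm carried forward
  cb <- co$consultations[co$consultations$patient_id == "B", ]
  expect_identical(cb$arm, c("risperidone", "haloperidol", "haloperidol"))
  expect_equal(cb$switch_2[cb$visit_index == 3], 1)  # arm changed at visit 2
  # no feature vector references the current or a future visit
  expect_true(all(co$consultations$history_max_visit <
                    co$consultations$visit_index))
})

test_that("cleaned cohort round-trips through CSV bit-for-bit", {
  co <- cached_cohort(60, seed = 5)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(dir)
  num <- names(co$consultations)[vapply(co$consultations, is.numeric,
                                        logical(1))]
  chr <- setdiff(names(co$consultations), num)
  expect_identical(back$consultations[chr], co$consultations[chr])
  for (cn in num) {
    expect_equal(back$consultations[[cn]], as.numeric(co$consultations[[cn]]),
                 tolerance = 1e-9, label = cn)
  }
  expect_equal(back$instances$los_days, co$instances$los_days,
               tolerance = 1e-9)
})

test_that("synthetic tables pass cleaning with zero exclusions", {
  synth <- cached_synth(60, seed = 5)
  co <- cached_cohort(60, seed = 5)
  pat_excl <- co$exclusions[co$exclusions$reason != "visits_beyond_third_dropped", ]
  expect_identical(sum(pat_excl$n), 0L)
  expect_identical(nrow(co$patients), nrow(synth$patients))
})
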