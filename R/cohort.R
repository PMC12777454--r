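# Cohort assembly: raw patient/visit/prescription tables -> cleaned cohort of
# consultations (one decision point per patient-visit) and patient-drug
# instances (one treatment episode per distinct drug initiation, carrying the
# raw utilisation quantities that feed the affinity score).

.feature_cols_categorical <- c("gender", "ethnicity", "drug_1", "drug_2")
.feature_cols_numeric <- c("age_years", "comorbidity_count",
                           "los_1", "gap_1", "switch_1",
                           "los_2", "gap_2", "switch_2")

#' Names of the consultation feature columns
#'
#' The per-consultation feature schema: four baseline fields available at any
#' admission (gender, ethnicity, age, comorbidity count of the current
#' admission) plus, for second and third visits, the prior visits' length of
#' stay, inter-admission gap, prescribed arm and a switch indicator. History
#' fields that do not exist yet for a visit are `NA` by construction.
#'
#' @return List with elements `categorical` and `numeric`.
#' @export
feature_schema <- function() {
  list(categorical = .feature_cols_categorical,
       numeric = .feature_cols_numeric)
}

all_feature_cols <- function() {
  c("gender", "ethnicity", "age_years", "comorbidity_count",
    "los_1", "gap_1", "drug_1", "switch_1",
    "los_2", "gap_2", "drug_2", "switch_2")
}

days_between <- function(a, b) as.numeric(difftime(b, a, units = "days"))

#' Read the three raw cohort CSV tables
#'
#' @param patients_csv,visits_csv,prescriptions_csv Paths to UTF-8 CSV files
#'   with header rows. `patients.csv`: patient_id, gender, ethnicity, age,
#'   icd_code. `visits.csv`: patient_id, admit_time, discharge_time,
#'   comorbidity_count (optional visit_number). `prescriptions.csv`:
#'   patient_id, admit_time, drug, start_time. Timestamps are ISO-8601.
#' @return List of three tibbles `patients`, `visits`, `prescriptions`.
#' @export
read_cohort_tables <- function(patients_csv, visits_csv, prescriptions_csv) {
  ts <- readr::col_datetime(format = "")
  patients <- readr::read_csv(
    patients_csv,
    col_types = readr::cols(patient_id = "c", gender = "c", ethnicity = "c",
                            age = "d", icd_code = "c"),
    progress = FALSE)
  visits <- readr::read_csv(
    visits_csv,
    col_types = readr::cols(patient_id = "c", admit_time = ts,
                            discharge_time = ts, comorbidity_count = "d",
                            .default = "d"),
    progress = FALSE)
  prescriptions <- readr::read_csv(
    prescriptions_csv,
    col_types = readr::cols(patient_id = "c", admit_time = ts, drug = "c",
                            start_time = ts),
    progress = FALSE)
  list(patients = patients, visits = visits, prescriptions = prescriptions)
}

#' Apply the cohort inclusion criteria
#'
#' Retains patients aged 18-40 with a schizophrenia-spectrum diagnosis
#' (ICD-10 `F2x` after ICD-9 mapping) and a retained ethnicity category;
#' drops patients whose recorded visit sequence lacks the initial visit;
#' caps admissions at the third visit. Exclusions are counted by the first
#' matching reason so reason counts sum to the number of dropped patients.
#'
#' @param patients,visits Raw tibbles as from [read_cohort_tables()].
#' @param dialect Ethnicity dialect table ([default_ethnicity_dialect()]).
#' @return List: `patients` (cleaned, with `ethnicity` consolidated,
#'   `diagnosis_icd10`, integer `age_years`), `visits` (ordered, capped,
#'   with `visit_index` and `length_of_stay_days`), `exclusions` (tibble of
#'   reason/n, plus `visits_dropped` attribute behaviour via its own row).
#' @export
apply_inclusion_criteria <- function(patients, visits,
                                     dialect = default_ethnicity_dialect()) {
  stopifnot(is.data.frame(patients), is.data.frame(visits))
  n_in <- nrow(patients)

  pat <- tibble::as_tibble(patients)
  pat$icd_first <- first_code(pat$icd_code)
  pat$diagnosis_icd10 <- vapply(pat$icd_first, function(x) {
    tryCatch(map_icd9_to_icd10(x), schizrec_error = function(e) NA_character_)
  }, character(1))
  pat$ethnicity_cat <- consolidate_ethnicity(pat$ethnicity, dialect)

  vis <- tibble::as_tibble(visits)
  if (any(vis$discharge_time < vis$admit_time)) {
    srx_abort("srx_invalid_visit_error",
              "discharge_time precedes admit_time for at least one visit")
  }
  vis <- dplyr::arrange(vis, .data$patient_id, .data$admit_time)
  has_vn <- "visit_number" %in% names(vis)
  vis <- dplyr::group_by(vis, .data$patient_id)
  vis <- dplyr::mutate(vis, visit_index = dplyr::row_number())
  first_recorded <- dplyr::summarise(
    vis, first_vn = if (has_vn) min(.data$visit_number) else 1)
  vis <- dplyr::ungroup(vis)

  # one exclusion reason per patient, applied in a fixed order
  reason <- rep(NA_character_, n_in)
  bad_dx <- is.na(pat$diagnosis_icd10) | !grepl("^F2", pat$diagnosis_icd10)
  reason[bad_dx] <- "diagnosis_not_f2x"
  bad_age <- is.na(pat$age) | pat$age < 18 | pat$age > 40
  reason[is.na(reason) & bad_age] <- "age_outside_18_40"
  bad_eth <- pat$ethnicity_cat == "EXCLUDE"
  reason[is.na(reason) & bad_eth] <- "ethnicity_excluded"
  no_first <- pat$patient_id %in% first_recorded$patient_id[first_recorded$first_vn > 1]
  reason[is.na(reason) & no_first] <- "missing_initial_visit"
  no_visit <- !(pat$patient_id %in% vis$patient_id)
  reason[is.na(reason) & no_visit] <- "no_visit_records"

  keep <- is.na(reason)
  cleaned_pat <- tibble::tibble(
    patient_id = pat$patient_id[keep],
    gender = pat$gender[keep],
    ethnicity = pat$ethnicity_cat[keep],
    age_years = as.integer(round(pat$age[keep])),
    diagnosis_icd10 = pat$diagnosis_icd10[keep]
  )

  vis <- vis[vis$patient_id %in% cleaned_pat$patient_id, , drop = FALSE]
  n_vis_before <- nrow(vis)
  vis <- vis[vis$visit_index <= 3L, , drop = FALSE]
  vis$length_of_stay_days <- days_between(vis$admit_time, vis$discharge_time)
  vis <- vis[, c("patient_id", "visit_index", "admit_time", "discharge_time",
                 "length_of_stay_days", "comorbidity_count")]

  excl <- table(factor(reason[!keep]))
  exclusions <- tibble::tibble(
    reason = c(names(excl), "visits_beyond_third_dropped"),
    n = c(as.integer(excl), n_vis_before - nrow(vis))
  )
  list(patients = cleaned_pat, visits = vis, exclusions = exclusions)
}

#' Build one consultation feature vector
#'
#' Assembles the temporally admissible feature vector for a single decision
#' point: the patient's baseline demographics, the current admission's
#' comorbidity count, and (for later visits) the earlier visits' length of
#' stay, inter-admission gap, prescribed arm and switch indicator.
#'
#' @param patient One-row tibble with `gender`, `ethnicity`, `age_years`.
#' @param history Tibble of strictly earlier visits (possibly empty) with
#'   `visit_index`, `admit_time`, `discharge_time`, `length_of_stay_days`,
#'   `arm`, `multi_init` (logical: several drug starts within the visit).
#' @param current List or one-row tibble with `visit_index`, `admit_time`,
#'   `comorbidity_count` for the admission being decided.
#' @return One-row tibble with the columns of [feature_schema()]; history
#'   slots not yet observed are `NA`.
#' @export
build_feature_vector <- function(patient, history, current) {
  v <- current$visit_index
  if (nrow(history) > 0 &&
      (any(history$visit_index >= v) ||
       any(history$admit_time >= current$admit_time))) {
    srx_abort("srx_temporal_leakage_error",
              sprintf("history for a visit-%d consultation contains visit >= %d or a non-past timestamp", v, v))
  }
  out <- tibble::tibble(
    gender = patient$gender,
    ethnicity = patient$ethnicity,
    age_years = as.numeric(patient$age_years),
    comorbidity_count = as.numeric(current$comorbidity_count),
    los_1 = NA_real_, gap_1 = NA_real_, drug_1 = NA_character_,
    switch_1 = NA_real_,
    los_2 = NA_real_, gap_2 = NA_real_, drug_2 = NA_character_,
    switch_2 = NA_real_
  )
  if (nrow(history) > 0) {
    history <- history[order(history$visit_index), , drop = FALSE]
    n_h <- min(nrow(history), 2L)
    arms_seq <- history$arm
    for (h in seq_len(n_h)) {
      nxt_admit <- if (h < nrow(history)) history$admit_time[h + 1L] else current$admit_time
      out[[paste0("los_", h)]] <- history$length_of_stay_days[h]
      out[[paste0("gap_", h)]] <- days_between(history$discharge_time[h], nxt_admit)
      out[[paste0("drug_", h)]] <- arms_seq[h]
      switched <- isTRUE(history$multi_init[h]) ||
        (h >= 2 && !identical(arms_seq[h], arms_seq[h - 1L]))
      out[[paste0("switch_", h)]] <- as.numeric(switched)
    }
  }
  out
}

# per-patient drug initiation sequence: first start of each distinct drug, in
# chronological order; a visit-1 admission with no prescription initiates NONE
initiation_sequence <- function(pat_visits, pat_rx) {
  inits <- NULL
  if (nrow(pat_rx) > 0) {
    pat_rx <- pat_rx[order(pat_rx$start_time), , drop = FALSE]
    firsts <- !duplicated(pat_rx$drug)
    inits <- pat_rx[firsts, c("drug", "start_time", "visit_index"), drop = FALSE]
  }
  v1 <- pat_visits[pat_visits$visit_index == 1L, , drop = FALSE]
  v1_has_rx <- !is.null(inits) && any(inits$visit_index == 1L)
  if (!v1_has_rx) {
    none_row <- tibble::tibble(drug = "NONE",
                               start_time = v1$admit_time[1L],
                               visit_index = 1L)
    inits <- if (is.null(inits)) none_row else dplyr::bind_rows(none_row, inits)
  }
  inits[order(inits$start_time), , drop = FALSE]
}

#' Assemble a cleaned cohort from raw tables
#'
#' Applies [apply_inclusion_criteria()], determines each visit's prescribed
#' arm (first drug started within the visit, carried forward when no new
#' drug is started), extracts one patient-drug instance per distinct drug
#' initiation with its raw utilisation quantities, and builds the
#' consultation feature vectors under the temporal discipline.
#'
#' @inheritParams apply_inclusion_criteria
#' @param prescriptions Raw prescriptions tibble; drug names are
#'   lower-cased and must belong to [antipsychotic_arms()].
#' @return An object of class `srx_cohort`: a list with `patients`,
#'   `visits` (now including `arm` and `multi_init`), `consultations`,
#'   `instances` and `exclusions`.
#' @export
build_cohort <- function(patients, visits, prescriptions,
                         dialect = default_ethnicity_dialect()) {
  cleaned <- apply_inclusion_criteria(patients, visits, dialect)
  pat <- cleaned$patients
  vis <- cleaned$visits

  rx <- tibble::as_tibble(prescriptions)
  rx$drug <- tolower(trimws(rx$drug))
  bad <- setdiff(unique(rx$drug), antipsychotic_arms())
  if (length(bad) > 0) {
    srx_abort("srx_unknown_arm_error",
              paste("unknown drug name(s) in prescriptions:",
                    paste(bad, collapse = ", ")))
  }
  rx <- rx[rx$patient_id %in% pat$patient_id, , drop = FALSE]
  # attach visit_index; prescriptions outside retained visits are dropped
  rx <- dplyr::inner_join(
    rx, vis[, c("patient_id", "admit_time", "visit_index")],
    by = c("patient_id", "admit_time"))

  cons_list <- vector("list", nrow(pat))
  inst_list <- vector("list", nrow(pat))
  vis_split <- split(vis, vis$patient_id)
  rx_split <- split(rx, rx$patient_id)

  for (i in seq_len(nrow(pat))) {
    pid <- pat$patient_id[i]
    pv <- vis_split[[pid]]
    pv <- pv[order(pv$visit_index), , drop = FALSE]
    pr <- rx_split[[pid]]
    if (is.null(pr)) pr <- rx[0, , drop = FALSE]
    inits <- initiation_sequence(pv, pr)

    # per-visit arm: first initiation within the visit, else carry-forward
    n_v <- nrow(pv)
    arm <- character(n_v)
    multi_init <- logical(n_v)
    cur <- "NONE"
    for (v in seq_len(n_v)) {
      here <- inits[inits$visit_index == v, , drop = FALSE]
      if (nrow(here) > 0) cur <- here$drug[1L]
      arm[v] <- cur
      multi_init[v] <- nrow(here) >= 2L
    }
    pv$arm <- arm
    pv$multi_init <- multi_init

    # patient-level utilisation quantities
    gap_days <- if (n_v >= 2) {
      sum(days_between(pv$discharge_time[-n_v], pv$admit_time[-1L]))
    } else NA_real_
    los_days <- sum(pv$length_of_stay_days)

    # one instance per initiation
    n_i <- nrow(inits)
    sw_count <- integer(n_i)
    sw_days <- rep(NA_real_, n_i)
    for (j in seq_len(n_i)) {
      later <- inits$start_time[seq_len(n_i) > j]
      k <- min(length(later), 2L)
      sw_count[j] <- k
      if (k > 0) sw_days[j] <- days_between(inits$start_time[j], later[k])
    }
    inst_list[[i]] <- tibble::tibble(
      patient_id = pid,
      drug = inits$drug,
      init_visit = inits$visit_index,
      switch_count = sw_count,
      switch_days = sw_days,
      gap_days = gap_days,
      los_days = los_days,
      n_visits = n_v
    )

    # consultations with temporally disciplined features
    rows <- vector("list", n_v)
    for (v in seq_len(n_v)) {
      hist <- pv[pv$visit_index < v, , drop = FALSE]
      fv <- build_feature_vector(
        pat[i, , drop = FALSE], hist,
        list(visit_index = v, admit_time = pv$admit_time[v],
             comorbidity_count = pv$comorbidity_count[v]))
      rows[[v]] <- dplyr::bind_cols(
        tibble::tibble(patient_id = pid, visit_index = v, arm = arm[v],
                       history_max_visit = if (nrow(hist)) max(hist$visit_index) else 0L),
        fv)
    }
    cons_list[[i]] <- dplyr::bind_rows(rows)
  }

  structure(
    list(
      patients = pat,
      visits = vis,
      consultations = dplyr::bind_rows(cons_list),
      instances = dplyr::bind_rows(inst_list),
      exclusions = cleaned$exclusions
    ),
    class = "srx_cohort"
  )
}

#' @export
print.srx_cohort <- function(x, ...) {
  cat("<srx_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$visits), " visits, ", nrow(x$consultations),
      " consultations, ", nrow(x$instances), " drug instances\n", sep = "")
  invisible(x)
}

#' Write / read the cleaned cohort
#'
#' Serialises the cleaned cohort to plain CSV (full precision) so that
#' re-reading reproduces identical consultations and instances; also writes
#' `exclusions.log`.
#'
#' @param cohort An `srx_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort_csv()` returns `dir` invisibly; `read_cohort_csv()`
#'   returns a list with `consultations` and `instances`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$consultations, file.path(dir, "cohort.csv"))
  readr::write_csv(cohort$instances, file.path(dir, "instances.csv"))
  writeLines(sprintf("%s: %d", cohort$exclusions$reason, cohort$exclusions$n),
             file.path(dir, "exclusions.log"))
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  cons <- readr::read_csv(
    file.path(dir, "cohort.csv"),
    col_types = readr::cols(
      patient_id = "c", visit_index = "i", arm = "c",
      history_max_visit = "i", gender = "c", ethnicity = "c",
      drug_1 = "c", drug_2 = "c", .default = "d"),
    progress = FALSE)
  inst <- readr::read_csv(
    file.path(dir, "instances.csv"),
    col_types = readr::cols(patient_id = "c", drug = "c", init_visit = "i",
                            switch_count = "i", n_visits = "i",
                            .default = "d"),
    progress = FALSE)
  list(consultations = cons, instances = inst)
}
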