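# Synthetic EHR cohort generator. Emulates the development cohort's
# marginals (n = 1,152 patients; age 27.9 +/- 6.4 in [18, 40]; 65.8% male;
# visit counts 57.3/21.8/20.9% for 1/2/3; length of stay 6.6 +/- 10.5 days;
# the printed treatment-arm prevalence profile) and plants a latent
# subgroup-by-drug response structure that drives the raw admission records:
# a good (subgroup, drug) match yields long inter-admission gaps, short
# stays and no medication switch; a bad match short gaps, long stays and one
# or two switches. Patient features (age, comorbidity burden, gender,
# ethnicity) are tilted by subgroup so that similarity methods can recover
# the structure. The truth (subgroups, response matrix) is emitted
# separately and is never read by the pipeline under evaluation.

.default_drug_prev <- function() {
  named <- c(NONE = 0.558, risperidone = 0.174, olanzapine = 0.170,
             haloperidol = 0.151, aripiprazole = 0.096, clozapine = 0.049)
  others <- setdiff(treatment_arms(), names(named))
  prev <- c(named, setNames(rep(0.026 / length(others), length(others)),
                            others))
  prev[treatment_arms()]
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the development cohort's published marginals; the
#' planted-structure knobs (`n_subgroups`, `effect_size`, `noise_sd`,
#' `subgroup_sep`) control how strongly latent drug response shapes the
#' records and how visible the subgroups are in the features.
#'
#' @param n_patients Number of patients.
#' @param age_mean,age_sd Age distribution (years), truncated to 18-40.
#' @param male_frac Fraction of male patients.
#' @param ethnicity_probs Named probabilities over the four retained
#'   categories (sum 1).
#' @param visit_probs Probabilities of 1/2/3 recorded visits.
#' @param los_mean,los_sd Length-of-stay moments (days); stays are drawn
#'   log-normal to match the strong right skew.
#' @param drug_prev Named prevalence over [treatment_arms()] used (after
#'   renormalisation) as the visit-1 arm distribution.
#' @param n_subgroups Number of latent response subgroups.
#' @param effect_size Strength of the planted response (0 = none, 1 =
#'   strong: good matches respond at 0.9, bad at 0.3).
#' @param noise_sd SD of per-patient response noise.
#' @param subgroup_sep How strongly features are tilted by subgroup.
#' @param seed Integer seed; generation is byte-deterministic given it.
#' @return An `srx_cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 1152L,
                        age_mean = 27.9, age_sd = 6.4,
                        male_frac = 0.658,
                        ethnicity_probs = c(
                          "White" = 0.444, "Black/African American" = 0.396,
                          "Hispanic/Latino" = 0.081, "Asian" = 0.079),
                        visit_probs = c(0.573, 0.218, 0.209),
                        los_mean = 6.6, los_sd = 10.5,
                        drug_prev = .default_drug_prev(),
                        n_subgroups = 4L, effect_size = 1,
                        noise_sd = 0.1, subgroup_sep = 1,
                        seed = 1L) {
  if (n_patients < 1 || age_sd <= 0 || los_mean <= 0 || los_sd <= 0 ||
      male_frac < 0 || male_frac > 1 || n_subgroups < 1 ||
      effect_size < 0 || noise_sd < 0 ||
      any(ethnicity_probs < 0) || any(visit_probs < 0) ||
      any(drug_prev < 0) ||
      abs(sum(ethnicity_probs) - 1) > 1e-6 ||
      abs(sum(visit_probs) - 1) > 1e-6) {
    srx_abort("srx_invalid_spec_error", "invalid cohort specification")
  }
  if (!setequal(names(drug_prev), treatment_arms())) {
    srx_abort("srx_invalid_spec_error",
              "drug_prev must cover exactly the treatment arms")
  }
  structure(list(
    n_patients = as.integer(n_patients), age_mean = age_mean,
    age_sd = age_sd, male_frac = male_frac,
    ethnicity_probs = ethnicity_probs, visit_probs = visit_probs,
    los_mean = los_mean, los_sd = los_sd,
    drug_prev = drug_prev[treatment_arms()] / sum(drug_prev),
    n_subgroups = as.integer(n_subgroups), effect_size = effect_size,
    noise_sd = noise_sd, subgroup_sep = subgroup_sep,
    seed = as.integer(seed)), class = "srx_cohort_spec")
}

# representative source-dialect labels per retained category, so generated
# tables exercise the consolidation step
.dialect_emission <- list(
  "White" = c("WHITE", "WHITE - RUSSIAN", "WHITE - EASTERN EUROPEAN"),
  "Black/African American" = c("BLACK/AFRICAN AMERICAN",
                               "BLACK/CARIBBEAN ISLAND"),
  "Hispanic/Latino" = c("HISPANIC OR LATINO",
                        "HISPANIC/LATINO - PUERTO RICAN"),
  "Asian" = c("ASIAN", "ASIAN - CHINESE")
)
.icd_emission <- c("F20.0", "F20.9", "F25.9", "295.30", "295.70",
                   "295.90", "295.30,296.20")

# planted response of subgroup g to arm d. Arms are cycled over subgroups in
# descending prevalence order, so every subgroup's primary good match is a
# common treatment (the ones patients actually receive, hence the ones that
# can become relevant in evaluation) and every arm is good for exactly one
# subgroup, keeping marginal per-arm response balanced.
.response_matrix <- function(n_subgroups, effect_size,
                             prevalence = .default_drug_prev()) {
  arms <- treatment_arms()
  by_prev <- names(sort(prevalence[arms], decreasing = TRUE))
  R <- matrix(0.5 - 0.2 * effect_size, n_subgroups, length(arms),
              dimnames = list(NULL, arms))
  for (j in seq_along(by_prev)) {
    g <- ((j - 1L) %% n_subgroups) + 1L
    R[g, by_prev[j]] <- 0.5 + 0.4 * effect_size
  }
  R
}

#' Generate a synthetic cohort
#'
#' Emits raw-field tables only (admissions, discharges, prescription
#' starts): every affinity-relevant signal is expressed through the
#' timeline, never written directly, so the full cleaning and scoring
#' pipeline runs on the output exactly as it would on real extracts.
#'
#' @param spec An [cohort_spec()].
#' @return An `srx_synthetic_cohort`: list with raw tibbles `patients`,
#'   `visits`, `prescriptions` and `truth` (subgroup assignment + response
#'   matrix; for audits only, never read by the pipeline).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "srx_cohort_spec")) spec <- do.call(cohort_spec, spec)
  arms <- treatment_arms()
  drugs <- antipsychotic_arms()
  G <- spec$n_subgroups
  R <- .response_matrix(G, spec$effect_size, spec$drug_prev)

  sigma2 <- log(1 + (spec$los_sd / spec$los_mean)^2)
  sigma <- sqrt(sigma2)
  mu0 <- log(spec$los_mean) - sigma2 / 2

  lambda_g <- 1 + 10 * spec$subgroup_sep * (seq_len(G) - 1) / max(1, G - 1)

  withr::with_seed(spec$seed, {
    n <- spec$n_patients
    pid <- sprintf("P%05d", seq_len(n))

    # demographics are drawn exactly from the specified marginals; the
    # latent subgroup is then a (mostly deterministic) function of the
    # features — ethnicity group crossed with age band — so the planted
    # structure is visible to similarity methods without distorting any
    # marginal. subgroup_sep controls the residual randomness of the
    # assignment (0 = subgroups unlinked to features).
    gender <- ifelse(runif(n) < spec$male_frac, "M", "F")
    eth_levels <- names(spec$ethnicity_probs)
    eth_cat <- sample(eth_levels, n, replace = TRUE,
                      prob = spec$ethnicity_probs)
    age <- round(pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd), 18), 40))

    n_bins <- max(1L, ceiling(G / 2))
    age_breaks <- if (n_bins > 1) {
      stats::qnorm(seq_len(n_bins - 1) / n_bins, spec$age_mean, spec$age_sd)
    } else numeric(0)
    e_bit <- as.integer(eth_cat %in% c("White", "Hispanic/Latino"))
    a_bin <- findInterval(age, age_breaks)
    subgroup <- ((e_bit * n_bins + a_bin) %% G) + 1L
    p_rand <- if (spec$subgroup_sep <= 0) 1 else
      min(1, 0.15 / spec$subgroup_sep)
    flip <- runif(n) < p_rand
    subgroup[flip] <- sample.int(G, sum(flip), replace = TRUE)

    pat_rows <- tibble::tibble(
      patient_id = pid, gender = gender,
      ethnicity = vapply(eth_cat, function(e)
        sample(.dialect_emission[[e]], 1L), character(1)),
      age = age,
      icd_code = sample(.icd_emission, n, replace = TRUE))

    vis_list <- vector("list", n)
    rx_list <- vector("list", n)
    origin <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")

    resp <- function(g, a) {
      pmin(pmax(R[g, a] + rnorm(1, 0, spec$noise_sd), 0.05), 0.95)
    }

    # switch targets follow the prescription prevalence profile (restricted
    # to antipsychotics), so an arm's instance mix is not skewed toward
    # switch episodes merely because the arm is rare at first line
    drug_prev_only <- spec$drug_prev[drugs]
    draw_switch_target <- function(current) {
      cand <- setdiff(drugs, current)
      sample(cand, 1L, prob = drug_prev_only[cand])
    }

    # readmission is response-driven: a well-matched treatment makes a
    # single recorded visit more likely, a poor match a readmission. The
    # per-patient single-visit probability is centred so the cohort-level
    # visit-count mix still matches the specified marginal in expectation.
    mean_r <- sum(spec$drug_prev * colMeans(R))
    draw_n_visits <- function(r) {
      p23 <- spec$visit_probs[2:3]
      if (sum(p23) == 0) return(1L)
      p1 <- pmin(pmax(spec$visit_probs[1] + 0.9 * (r - mean_r), 0), 1)
      sample.int(3L, 1L, prob = c(p1, (1 - p1) * p23 / sum(p23)))
    }

    for (i in seq_len(n)) {
      g <- subgroup[i]
      admit <- origin + runif(1, 0, 3 * 365) * 86400
      cur_arm <- sample(arms, 1L, prob = spec$drug_prev)
      r_cur <- resp(g, cur_arm)
      nv <- draw_n_visits(r_cur)
      vis_rows <- vector("list", nv)
      rx_rows <- list()
      n_switch <- 0L
      switched <- FALSE
      for (v in seq_len(nv)) {
        comorb <- rpois(1, lambda_g[g])
        los <- rlnorm(1, mu0 + 0.8 * (0.5 - r_cur), sigma)
        los <- max(los, 0.25)
        discharge <- admit + los * 86400
        if (cur_arm != "NONE" && (v == 1 || switched)) {
          rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
            patient_id = pid[i], admit_time = admit, drug = cur_arm,
            start_time = admit + los * 86400 * runif(1, 0.02, 0.3))
        }
        # a poorly matched treatment can be swapped mid-stay (for NONE:
        # a drug is started during the admission)
        p_sw <- pmin(pmax(1.3 * (1 - r_cur) - 0.15, 0), 0.9)
        if (v == 1 && nv == 1 && n_switch < 2L && runif(1) < 0.4 * p_sw) {
          new_arm <- draw_switch_target(cur_arm)
          rx_rows[[length(rx_rows) + 1L]] <- tibble::tibble(
            patient_id = pid[i], admit_time = admit, drug = new_arm,
            start_time = admit + los * 86400 * runif(1, 0.4, 0.8))
          cur_arm <- new_arm
          r_cur <- resp(g, cur_arm)
          n_switch <- n_switch + 1L
        }
        vis_rows[[v]] <- tibble::tibble(
          patient_id = pid[i], admit_time = admit,
          discharge_time = discharge, comorbidity_count = comorb,
          visit_number = v)
        if (v < nv) {
          gap <- rgamma(1, shape = 4, scale = (20 + 350 * r_cur) / 4)
          gap <- max(gap, 1)
          admit <- discharge + gap * 86400
          switched <- n_switch < 2L && runif(1) < p_sw
          if (switched) {
            new_arm <- draw_switch_target(cur_arm)
            cur_arm <- new_arm
            r_cur <- resp(g, cur_arm)
            n_switch <- n_switch + 1L
          }
        }
      }
      vis_list[[i]] <- dplyr::bind_rows(vis_rows)
      if (length(rx_rows)) rx_list[[i]] <- dplyr::bind_rows(rx_rows)
    }

    structure(list(
      patients = pat_rows,
      visits = dplyr::bind_rows(vis_list),
      prescriptions = dplyr::bind_rows(rx_list),
      truth = list(subgroup = setNames(subgroup, pid),
                   response = R, spec = spec)),
      class = "srx_synthetic_cohort")
  })
}

#' Write a synthetic cohort to CSV (+ truth sidecar)
#'
#' @param synth An `srx_synthetic_cohort`.
#' @param dir Output directory.
#' @param truth Also write `truth.json`? The pipeline never reads it;
#'   deleting it changes no output.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(synth, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    for (cn in names(d)) {
      if (inherits(d[[cn]], "POSIXct")) {
        d[[cn]] <- format(d[[cn]], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
      }
    }
    d
  }
  readr::write_csv(fmt(synth$patients), file.path(dir, "patients.csv"))
  readr::write_csv(fmt(synth$visits), file.path(dir, "visits.csv"))
  readr::write_csv(fmt(synth$prescriptions),
                   file.path(dir, "prescriptions.csv"))
  if (truth) {
    jsonlite::write_json(
      list(subgroup = as.list(synth$truth$subgroup),
           response = as.data.frame(synth$truth$response)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Assemble an `srx_cohort` directly from a synthetic cohort
#' @param synth An `srx_synthetic_cohort`.
#' @return The cleaned [build_cohort()] result.
#' @export
as_cohort <- function(synth) {
  build_cohort(synth$patients, synth$visits, synth$prescriptions)
}

#' Check generated marginals against the specification
#'
#' Two-sided z-tests of each generated marginal against its specified
#' value: male fraction, ethnicity mix, visit-count mix, age mean, length
#' of stay mean, and the visit-1 arm distribution (the ten rare "other"
#' antipsychotics pooled into one bucket). A marginal fails when |z| > 4.
#'
#' @param synth An `srx_synthetic_cohort`.
#' @param spec The generating [cohort_spec()] (defaults to the one stored
#'   in the truth sidecar).
#' @return Tibble with `marginal`, `observed`, `expected`, `z`, `pass`;
#'   attribute `all_pass`.
#' @export
validate_marginals <- function(synth, spec = synth$truth$spec) {
  pat <- synth$patients
  vis <- synth$visits
  n <- nrow(pat)
  dialect <- default_ethnicity_dialect()
  eth <- consolidate_ethnicity(pat$ethnicity, dialect)

  z_prop <- function(obs_n, n_tot, p) {
    se <- sqrt(p * (1 - p) / n_tot)
    if (se == 0) return(if (obs_n / n_tot == p) 0 else Inf)
    (obs_n / n_tot - p) / se
  }
  rows <- list()
  add <- function(name, observed, expected, z) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      marginal = name, observed = observed, expected = expected, z = z)
  }

  add("male_fraction", mean(pat$gender == "M"), spec$male_frac,
      z_prop(sum(pat$gender == "M"), n, spec$male_frac))
  for (e in names(spec$ethnicity_probs)) {
    add(paste0("ethnicity_", e), mean(eth == e), spec$ethnicity_probs[[e]],
        z_prop(sum(eth == e), n, spec$ethnicity_probs[[e]]))
  }
  nv <- table(factor(table(vis$patient_id), levels = 1:3))
  for (v in 1:3) {
    add(paste0("visit_count_", v), as.integer(nv[v]) / n,
        spec$visit_probs[v], z_prop(as.integer(nv[v]), n,
                                    spec$visit_probs[v]))
  }
  add("age_mean", mean(pat$age), spec$age_mean,
      (mean(pat$age) - spec$age_mean) / (spec$age_sd / sqrt(n)))
  los <- as.numeric(difftime(vis$discharge_time, vis$admit_time,
                             units = "days"))
  add("los_mean", mean(los), spec$los_mean,
      (mean(los) - spec$los_mean) / (spec$los_sd / sqrt(length(los))))

  # visit-1 arm distribution, rare antipsychotics pooled
  first_vis <- vis[vis$visit_number == 1, c("patient_id", "admit_time")]
  rx1 <- dplyr::inner_join(synth$prescriptions, first_vis,
                           by = c("patient_id", "admit_time"))
  rx1 <- rx1[order(rx1$start_time), ]
  arm1 <- setNames(rep("NONE", n), pat$patient_id)
  first_rx <- rx1[!duplicated(rx1$patient_id), ]
  arm1[first_rx$patient_id] <- first_rx$drug
  common <- c("NONE", "risperidone", "olanzapine", "haloperidol",
              "aripiprazole", "clozapine")
  pooled <- function(a) ifelse(a %in% common, a, "other")
  prev <- spec$drug_prev
  exp_pooled <- c(prev[common], other = sum(prev[setdiff(names(prev), common)]))
  obs_arm <- pooled(arm1)
  for (a in names(exp_pooled)) {
    add(paste0("visit1_arm_", a), mean(obs_arm == a), exp_pooled[[a]],
        z_prop(sum(obs_arm == a), n, exp_pooled[[a]]))
  }

  out <- dplyr::bind_rows(rows)
  out$pass <- abs(out$z) <= 4
  attr(out, "all_pass") <- all(out$pass)
  out
}
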