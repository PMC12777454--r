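# The evaluation harness: train-fold context construction (bounds,
# affinities, feature space, similarity model), inner-loop neighbourhood
# size selection, visit-stratified outer evaluation, nested CV driver,
# frozen-model external validation, sensitivity reruns and the planted
# structure recovery check used on synthetic cohorts.

# --- fold context -----------------------------------------------------------

# everything fitted on (and only on) the training patients of one fold
fold_context <- function(cohort, train_ids, scheme = "equal",
                         missing_policy = "best",
                         provenance = "training") {
  inst <- cohort$instances[cohort$instances$patient_id %in% train_ids, ,
                           drop = FALSE]
  assert_nonempty_df(inst, "training instance set")
  bounds <- fit_bounds(inst, provenance = provenance)
  aff <- compute_affinity(inst, bounds, scheme, missing_policy)
  feat <- dplyr::inner_join(
    aff[, c("patient_id", "drug", "init_visit", "affinity")],
    cohort$consultations,
    by = c("patient_id", "init_visit" = "visit_index"))
  list(bounds = bounds, pool = feat, scheme = scheme,
       missing_policy = missing_policy)
}

fit_fold_model <- function(ctx, method, config = list()) {
  labels <- ctx$pool$affinity > 0.5
  if (method %in% c("dr_rba_gower", "dr_nca") &&
      length(unique(labels)) < 2L) {
    srx_abort("srx_single_class_error",
              "training affinities fall on one side of 0.5; cannot fit labelled method")
  }
  fit_similarity_model(method, ctx$pool[, all_feature_cols()],
                       train_labels = labels, config = config)
}

# observed affinities of test-patient instances, scored with TRAIN bounds
observed_for_patients <- function(cohort, ctx, ids) {
  inst <- cohort$instances[cohort$instances$patient_id %in% ids, ,
                           drop = FALSE]
  compute_affinity(inst, ctx$bounds, ctx$scheme, ctx$missing_policy)
}

# --- neighbourhood size selection ------------------------------------------

#' Select the neighbourhood size K on inner folds
#'
#' Evaluates every candidate K by the mean, over inner patient-grouped
#' folds, of the RMSE between predicted and observed affinity of each
#' validation consultation's actually prescribed arm. Observed affinities
#' and all preprocessing use inner-training statistics only. Ties break
#' toward the smallest K.
#'
#' @param cohort An `srx_cohort`.
#' @param train_ids Outer-fold training patient ids.
#' @param inner_folds List of validation-id vectors partitioning
#'   `train_ids` (from the fold plan).
#' @param method Similarity method name.
#' @param k_grid Candidate neighbourhood sizes (default 5 to 60 by 5).
#' @param scheme Affinity scheme.
#' @param weighted Similarity-weighted averaging?
#' @param config Hyperparameter list (see [fit_similarity_model()]).
#' @return The selected K, with attribute `inner_rmse` (named vector).
#' @export
select_k <- function(cohort, train_ids, inner_folds, method,
                     k_grid = seq(5L, 60L, by = 5L), scheme = "equal",
                     weighted = TRUE, config = list()) {
  per_fold <- matrix(NA_real_, length(inner_folds), length(k_grid))
  for (f in seq_along(inner_folds)) {
    val_ids <- inner_folds[[f]]
    fit_ids <- setdiff(train_ids, val_ids)
    ctx <- fold_context(cohort, fit_ids, scheme,
                        provenance = sprintf("inner_%d", f))
    model <- fit_fold_model(ctx, method, config)
    cons <- cohort$consultations[cohort$consultations$patient_id %in% val_ids, ,
                                 drop = FALSE]
    if (nrow(cons) == 0) next
    obs_tab <- observed_for_patients(cohort, ctx, val_ids)
    obs <- obs_tab$affinity[match(paste(cons$patient_id, cons$arm),
                                  paste(obs_tab$patient_id, obs_tab$drug))]
    S <- similarity_to_train(model, cons[, all_feature_cols()])
    pool <- ctx$pool
    gmean <- mean(pool$affinity)
    pat_cols <- split(seq_len(nrow(pool)), pool$patient_id)
    pats <- names(pat_cols)
    P <- vapply(pat_cols, function(cs) {
      if (length(cs) == 1L) S[, cs] else
        do.call(pmax, lapply(cs, function(c) S[, c]))
    }, numeric(nrow(cons)))
    if (nrow(cons) == 1L) P <- matrix(P, 1L, dimnames = list(NULL, pats))
    key <- paste(pool$patient_id, pool$drug)
    err2 <- matrix(NA_real_, nrow(cons), length(k_grid))
    for (i in seq_len(nrow(cons))) {
      a <- cons$arm[i]
      rows_all <- which(pool$drug == a)
      dmean <- if (length(rows_all)) mean(pool$affinity[rows_all]) else gmean
      ord <- order(-P[i, ], pats, method = "radix")
      w <- P[i, ord]
      rows <- match(paste(pats[ord], a), key)
      has <- !is.na(rows)
      aff <- ifelse(has, pool$affinity[ifelse(has, rows, 1L)], 0)
      cw <- cumsum(w * has)
      cwa <- cumsum(w * has * aff)
      cn <- cumsum(has)
      ca <- cumsum(has * aff)
      for (kk in seq_along(k_grid)) {
        k_use <- min(k_grid[kk], length(pats))
        p <- if (cw[k_use] > 0) {
          if (weighted) cwa[k_use] / cw[k_use] else ca[k_use] / cn[k_use]
        } else dmean
        err2[i, kk] <- (p - obs[i])^2
      }
    }
    per_fold[f, ] <- sqrt(colMeans(err2, na.rm = TRUE))
  }
  mean_rmse <- colMeans(per_fold, na.rm = TRUE)
  # ties (to numerical tolerance) break toward the smallest K
  best <- k_grid[min(which(mean_rmse <= min(mean_rmse) + 1e-12))]
  attr(best, "inner_rmse") <- setNames(mean_rmse, k_grid)
  best
}

# --- outer-fold evaluation --------------------------------------------------

#' Evaluate one outer fold
#'
#' Fits bounds, affinities, preprocessing and the similarity model on the
#' outer training patients only, then predicts every test consultation's
#' per-arm affinity with the supplied K, records the ranked list, and
#' returns one row per test consultation (visit-stratifiable downstream).
#'
#' @inheritParams select_k
#' @param test_ids Test patient ids (disjoint from `train_ids`).
#' @param K Neighbourhood size (from [select_k()] or frozen).
#' @return List: `details` (per-consultation tibble), `recommendations`
#'   (long tibble: one row per consultation x rank), `ctx`.
#' @export
evaluate_fold <- function(cohort, train_ids, test_ids, method, K,
                          scheme = "equal", weighted = TRUE,
                          config = list()) {
  if (length(intersect(train_ids, test_ids)) > 0) {
    srx_abort("srx_temporal_leakage_error",
              "train and test patient sets overlap")
  }
  ctx <- fold_context(cohort, train_ids, scheme, provenance = "outer_train")
  model <- fit_fold_model(ctx, method, config)
  cons <- cohort$consultations[cohort$consultations$patient_id %in% test_ids, ,
                               drop = FALSE]
  assert_nonempty_df(cons, "test consultation set")

  obs_tab <- observed_for_patients(cohort, ctx, test_ids)
  key <- paste(obs_tab$patient_id, obs_tab$drug)
  obs <- obs_tab$affinity[match(paste(cons$patient_id, cons$arm), key)]
  relevant <- lapply(cons$patient_id, function(p) {
    obs_tab$drug[obs_tab$patient_id == p & obs_tab$affinity > 0.5]
  })

  S <- similarity_to_train(model, cons[, all_feature_cols()])
  res <- predict_all_arms(S, ctx$pool$patient_id, ctx$pool$drug,
                          ctx$pool$affinity, K = K, weighted = weighted)
  arms <- colnames(res$pred)

  n <- nrow(cons)
  det <- vector("list", n)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    rk <- rank_treatments(ranking_predictions(res$pred[i, ], res$fallback[i, ]),
                          res$support[i, ])
    top3 <- attr(rk, "top3")
    a <- cons$arm[i]
    det[[i]] <- tibble::tibble(
      patient_id = cons$patient_id[i],
      visit_index = cons$visit_index[i],
      actual_arm = a,
      observed = obs[i],
      predicted_actual = res$pred[i, a],
      fallback_actual = res$fallback[i, a],
      top1 = top3[1],
      top2 = if (length(top3) > 1) top3[2] else NA_character_,
      top3_arm = if (length(top3) > 2) top3[3] else NA_character_,
      top1_predicted = rk$predicted[1],
      rank_of_actual = match(a, rk$arm),
      relevant_n = length(relevant[[i]]),
      ap3 = average_precision_at_k(rk$arm, relevant[[i]], 3L),
      overlap_hit = a %in% top3,
      history_max_visit = cons$history_max_visit[i]
    )
    rec[[i]] <- tibble::tibble(
      patient_id = cons$patient_id[i],
      visit_index = cons$visit_index[i],
      rank = rk$rank, arm = rk$arm, predicted = rk$predicted,
      support = rk$support,
      fallback = res$fallback[i, rk$arm]
    )
  }
  list(details = dplyr::bind_rows(det),
       recommendations = dplyr::bind_rows(rec),
       ctx = ctx,
       n_test_instances = nrow(obs_tab))
}

# per-stratum metrics from a details tibble
stratum_metrics <- function(details) {
  strata <- list(overall = details,
                 visit_1 = details[details$visit_index == 1, ],
                 visit_2 = details[details$visit_index == 2, ],
                 visit_3 = details[details$visit_index == 3, ])
  rows <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) == 0) {
      return(tibble::tibble(stratum = nm, n = 0L, rmse = NA_real_,
                            map3 = NA_real_, overlap = NA_real_,
                            coverage = NA_real_, n_map3 = 0L))
    }
    ok <- !is.na(d$observed)
    r <- if (any(ok)) rmse(d$predicted_actual[ok], d$observed[ok]) else NA_real_
    ap <- d$ap3[!is.na(d$ap3)]
    ov <- mean(d$overlap_hit)
    tibble::tibble(stratum = nm, n = nrow(d), rmse = r,
                   map3 = if (length(ap)) mean(ap) else NA_real_,
                   overlap = ov, coverage = 1 - ov,
                   n_map3 = length(ap))
  })
  dplyr::bind_rows(rows)
}

# --- nested CV driver -------------------------------------------------------

#' Run nested patient-grouped cross-validation
#'
#' The full evaluation protocol: an outer 5-fold patient split; inside each
#' outer training set an inner 5-fold patient-grouped selection of the
#' neighbourhood size K (grid 5-60 by 5, minimising inner RMSE); then
#' visit-stratified evaluation of the outer test patients with everything
#' (normalisation bounds, encoders/scalers, similarity model) fitted on the
#' outer training patients only. Metrics are aggregated as mean and sd over
#' outer folds, overall and per visit index.
#'
#' @inheritParams select_k
#' @param n_outer,n_inner Fold counts.
#' @param seed Seed for the fold plan.
#' @param plan Optionally a pre-built [make_fold_plan()] (then
#'   `n_outer`/`n_inner`/`seed` are taken from it).
#' @return An `srx_cv_result`: `metrics` (per-stratum mean/sd tibble),
#'   `fold_metrics`, `details`, `recommendations`, `best_k`, `plan`,
#'   `audit` (leakage audit), `method`, `scheme_name`.
#' @export
run_nested_cv <- function(cohort, method = "cf_cosine",
                          k_grid = seq(5L, 60L, by = 5L),
                          n_outer = 5L, n_inner = 5L, seed = 42L,
                          scheme = "equal", weighted = TRUE,
                          config = list(), plan = NULL) {
  scheme_obj <- resolve_scheme(scheme)
  if (is.null(plan)) {
    plan <- make_fold_plan(unique(cohort$patients$patient_id),
                           n_outer, n_inner, seed)
  }
  all_ids <- unique(cohort$patients$patient_id)
  fold_det <- list(); fold_rec <- list(); fold_met <- list()
  best_k <- integer(length(plan$outer))
  audit_folds <- list()
  n_test_instances <- integer(length(plan$outer))

  for (k in seq_along(plan$outer)) {
    test_ids <- plan$outer[[k]]$test
    train_ids <- setdiff(all_ids, test_ids)
    bk <- if (length(k_grid) > 1) {
      select_k(cohort, train_ids, plan$outer[[k]]$inner, method,
               k_grid, scheme_obj, weighted, config)
    } else k_grid[1]
    best_k[k] <- as.integer(bk)
    ev <- evaluate_fold(cohort, train_ids, test_ids, method, best_k[k],
                        scheme_obj, weighted, config)
    det <- ev$details; det$fold <- k
    rec <- ev$recommendations; rec$fold <- k
    fold_det[[k]] <- det
    fold_rec[[k]] <- rec
    m <- stratum_metrics(ev$details); m$fold <- k
    fold_met[[k]] <- m
    n_test_instances[k] <- ev$n_test_instances
    audit_folds[[k]] <- list(
      fold = k,
      train_patients = sort(train_ids),
      test_patients = sort(test_ids),
      train_test_intersection = length(intersect(train_ids, test_ids)),
      future_visit_reads = sum(det$history_max_visit >= det$visit_index)
    )
  }

  fm <- dplyr::bind_rows(fold_met)
  agg <- dplyr::summarise(
    dplyr::group_by(fm, .data$stratum),
    best_k_mean = mean(best_k), best_k_sd = stats::sd(best_k),
    rmse_mean = mean(.data$rmse, na.rm = TRUE),
    rmse_sd = stats::sd(.data$rmse, na.rm = TRUE),
    map3_mean = mean(.data$map3, na.rm = TRUE),
    map3_sd = stats::sd(.data$map3, na.rm = TRUE),
    overlap_mean = mean(.data$overlap, na.rm = TRUE),
    overlap_sd = stats::sd(.data$overlap, na.rm = TRUE),
    coverage_mean = mean(.data$coverage, na.rm = TRUE),
    avg_consultations = mean(.data$n),
    .groups = "drop")
  agg$avg_test_instances <- mean(n_test_instances)
  agg <- agg[match(c("overall", "visit_1", "visit_2", "visit_3"),
                   agg$stratum), , drop = FALSE]
  agg <- dplyr::bind_cols(tibble::tibble(method = method), agg)

  details <- dplyr::bind_rows(fold_det)
  audit <- list(
    seed = plan$seed,
    folds = audit_folds,
    max_train_test_intersection =
      max(vapply(audit_folds, `[[`, integer(1), "train_test_intersection")),
    total_future_visit_reads =
      sum(vapply(audit_folds, `[[`, integer(1), "future_visit_reads"))
  )
  structure(list(metrics = agg, fold_metrics = fm, details = details,
                 recommendations = dplyr::bind_rows(fold_rec),
                 best_k = best_k, plan = plan, audit = audit,
                 method = method, scheme_name = scheme_obj$name),
            class = "srx_cv_result")
}

#' @export
print.srx_cv_result <- function(x, ...) {
  cat("<srx_cv_result> method=", x$method, " scheme=", x$scheme_name,
      " best K per fold: ", paste(x$best_k, collapse = "/"), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

# --- frozen model & external validation ------------------------------------

#' Freeze a model on a development cohort
#'
#' Trains bounds, preprocessing and the similarity model on the whole
#' development cohort with a fixed K, for later external validation with no
#' re-tuning.
#'
#' @inheritParams run_nested_cv
#' @param K The frozen neighbourhood size.
#' @return An `srx_frozen_model`.
#' @export
freeze_model <- function(cohort, method = "cf_cosine", K = 7L,
                         scheme = "equal", weighted = TRUE, config = list()) {
  ctx <- fold_context(cohort, unique(cohort$patients$patient_id),
                      scheme, provenance = "development")
  model <- fit_fold_model(ctx, method, config)
  structure(list(ctx = ctx, model = model, K = as.integer(K),
                 method = method, weighted = weighted, config = config),
            class = "srx_frozen_model")
}

#' Externally validate a frozen model
#'
#' Applies a frozen model to an external cohort without any re-tuning: K is
#' never re-selected, preprocessing and (by default) normalisation bounds
#' come from the development fit, and unseen categorical levels encode as
#' zeros.
#'
#' @param frozen An `srx_frozen_model`.
#' @param external_cohort An `srx_cohort` from the external site.
#' @param bounds_source `"training"` (default: development bounds) or
#'   `"external"` (refit bounds on the external population).
#' @return List: `metrics` (per-stratum tibble), `details`,
#'   `recommendations`.
#' @export
external_validate <- function(frozen, external_cohort,
                              bounds_source = c("training", "external")) {
  bounds_source <- match.arg(bounds_source)
  if (!inherits(frozen, "srx_frozen_model")) {
    srx_abort("srx_not_fitted_error", "frozen must come from freeze_model()")
  }
  cons <- external_cohort$consultations
  missing_cols <- setdiff(all_feature_cols(), names(cons))
  if (length(missing_cols) > 0) {
    srx_abort("srx_schema_mismatch_error",
              paste("external cohort lacks feature columns:",
                    paste(missing_cols, collapse = ", ")))
  }
  ctx <- frozen$ctx
  if (bounds_source == "external") {
    ctx$bounds <- fit_bounds(external_cohort$instances,
                             provenance = "external")
  }
  new_lev <- setdiff(unique(cons$ethnicity),
                     frozen$model$feature_space$levels$ethnicity)
  if (length(new_lev) > 0) {
    srx_warn("srx_unseen_level_warning",
             paste("external categorical level(s) unseen in training encode as zeros:",
                   paste(new_lev, collapse = ", ")))
  }
  ids <- unique(external_cohort$patients$patient_id)
  obs_tab <- compute_affinity(
    external_cohort$instances[external_cohort$instances$patient_id %in% ids, ],
    ctx$bounds, ctx$scheme, ctx$missing_policy)
  key <- paste(obs_tab$patient_id, obs_tab$drug)
  obs <- obs_tab$affinity[match(paste(cons$patient_id, cons$arm), key)]
  relevant <- lapply(cons$patient_id, function(p) {
    obs_tab$drug[obs_tab$patient_id == p & obs_tab$affinity > 0.5]
  })
  S <- suppressWarnings(
    similarity_to_train(frozen$model, cons[, all_feature_cols()]))
  res <- predict_all_arms(S, frozen$ctx$pool$patient_id,
                          frozen$ctx$pool$drug, frozen$ctx$pool$affinity,
                          K = frozen$K, weighted = frozen$weighted)
  det <- vector("list", nrow(cons)); rec <- vector("list", nrow(cons))
  for (i in seq_len(nrow(cons))) {
    rk <- rank_treatments(ranking_predictions(res$pred[i, ], res$fallback[i, ]),
                          res$support[i, ])
    top3 <- attr(rk, "top3")
    a <- cons$arm[i]
    det[[i]] <- tibble::tibble(
      patient_id = cons$patient_id[i], visit_index = cons$visit_index[i],
      actual_arm = a, observed = obs[i],
      predicted_actual = res$pred[i, a],
      fallback_actual = res$fallback[i, a],
      top1 = top3[1],
      top2 = if (length(top3) > 1) top3[2] else NA_character_,
      top3_arm = if (length(top3) > 2) top3[3] else NA_character_,
      top1_predicted = rk$predicted[1],
      rank_of_actual = match(a, rk$arm),
      relevant_n = length(relevant[[i]]),
      ap3 = average_precision_at_k(rk$arm, relevant[[i]], 3L),
      overlap_hit = a %in% top3,
      history_max_visit = cons$history_max_visit[i])
    rec[[i]] <- tibble::tibble(
      patient_id = cons$patient_id[i], visit_index = cons$visit_index[i],
      rank = rk$rank, arm = rk$arm, predicted = rk$predicted,
      support = rk$support, fallback = res$fallback[i, rk$arm])
  }
  details <- dplyr::bind_rows(det)
  list(metrics = stratum_metrics(details), details = details,
       recommendations = dplyr::bind_rows(rec))
}

# --- sensitivity ------------------------------------------------------------

#' Re-run the nested CV under alternative affinity schemes
#'
#' Repeats the full nested cross-validation for each weighting/penalty
#' scheme with a shared fold plan (same seed), so differences between runs
#' are attributable to the affinity definition alone.
#'
#' @inheritParams run_nested_cv
#' @param schemes Named list of schemes (default [affinity_schemes()]).
#' @return List: `runs` (named list of `srx_cv_result`), `comparison`
#'   (overall metric rows bound across schemes).
#' @export
run_sensitivity <- function(cohort, method = "cf_cosine",
                            schemes = affinity_schemes(),
                            k_grid = seq(5L, 60L, by = 5L),
                            n_outer = 5L, n_inner = 5L, seed = 42L,
                            weighted = TRUE, config = list()) {
  stopifnot(length(schemes) >= 1)
  plan <- make_fold_plan(unique(cohort$patients$patient_id),
                         n_outer, n_inner, seed)
  runs <- lapply(schemes, function(sc) {
    run_nested_cv(cohort, method, k_grid, n_outer, n_inner, seed,
                  scheme = sc, weighted = weighted, config = config,
                  plan = plan)
  })
  comparison <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    m <- runs[[nm]]$metrics
    dplyr::bind_cols(tibble::tibble(scheme = nm), m)
  }))
  list(runs = runs, comparison = comparison)
}

# --- planted-structure recovery check ---------------------------------------

#' Planted-structure recovery on a synthetic cohort
#'
#' Patient-grouped holdout evaluation of CF on visit-1 consultations, with
#' a label-permutation null for MAP@3: training affinities are permuted
#' across training instances `n_perm` times (similarities, rankings
#' machinery and test-side relevance are held fixed) and MAP@3 recomputed
#' each time. Also reports RMSE against the predict-the-global-training-
#' mean baseline.
#'
#' @param cohort An `srx_cohort` (typically synthetic).
#' @param method Similarity method (default `"cf_cosine"`).
#' @param K Neighbourhood size.
#' @param train_frac Fraction of patients used for training.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the split and the permutations.
#' @param scheme Affinity scheme.
#' @return List: `map3`, `null` (numeric vector of permuted MAP@3),
#'   `null_q975`, `rmse`, `rmse_baseline`, `n_test_consultations`.
#' @export
planted_recovery <- function(cohort, method = "cf_cosine", K = 40L,
                             train_frac = 0.8, n_perm = 200L, seed = 42L,
                             scheme = "equal") {
  ids <- unique(cohort$patients$patient_id)
  shuffled <- withr::with_seed(seed, sample(ids))
  n_train <- floor(length(ids) * train_frac)
  train_ids <- shuffled[seq_len(n_train)]
  test_ids <- setdiff(ids, train_ids)

  ctx <- fold_context(cohort, train_ids, scheme)
  model <- fit_fold_model(ctx, method)
  cons <- cohort$consultations[
    cohort$consultations$patient_id %in% test_ids &
      cohort$consultations$visit_index == 1L, , drop = FALSE]
  obs_tab <- observed_for_patients(cohort, ctx, test_ids)
  key <- paste(obs_tab$patient_id, obs_tab$drug)
  obs <- obs_tab$affinity[match(paste(cons$patient_id, cons$arm), key)]
  relevant <- lapply(cons$patient_id, function(p) {
    obs_tab$drug[obs_tab$patient_id == p & obs_tab$affinity > 0.5]
  })
  S <- similarity_to_train(model, cons[, all_feature_cols()])
  pool <- ctx$pool
  arms <- treatment_arms()
  nq <- nrow(cons)

  # fixed neighbourhood structure: per query the top-K training patients,
  # per (query, arm) the pool rows those neighbours contribute. The
  # structure depends only on similarities, so it is invariant under label
  # permutation and is built once.
  pat_cols <- split(seq_len(nrow(pool)), pool$patient_id)
  pats <- names(pat_cols)
  P <- vapply(pat_cols, function(cs) {
    if (length(cs) == 1L) S[, cs] else
      do.call(pmax, lapply(cs, function(c) S[, c]))
  }, numeric(nq))
  if (nq == 1L) P <- matrix(P, 1L, dimnames = list(NULL, pats))
  keymap <- paste(pool$patient_id, pool$drug)
  arm_rows <- lapply(arms, function(a) which(pool$drug == a))
  names(arm_rows) <- arms
  k_use <- min(K, length(pats))

  hood <- vector("list", nq * length(arms))
  dim(hood) <- c(nq, length(arms))
  for (i in seq_len(nq)) {
    ord <- order(-P[i, ], pats, method = "radix")[seq_len(k_use)]
    neigh <- pats[ord]
    w_all <- P[i, ord]
    for (j in seq_along(arms)) {
      a <- arms[j]
      rows <- match(paste(neigh, a), keymap)
      has <- !is.na(rows)
      if (!any(has)) {
        hood[[i, j]] <- if (length(arm_rows[[a]]) == 0)
          list(type = "global") else list(type = "drug", idx = arm_rows[[a]])
      } else if (sum(w_all[has]) == 0) {
        hood[[i, j]] <- list(type = "drug", idx = arm_rows[[a]])
      } else {
        hood[[i, j]] <- list(type = "knn", idx = rows[has], w = w_all[has],
                             support = sum(has))
      }
    }
  }
  score_with <- function(aff) {
    gmean <- mean(aff)
    pred <- matrix(NA_real_, nq, length(arms), dimnames = list(NULL, arms))
    rankable <- matrix(FALSE, nq, length(arms))
    supp <- matrix(0L, nq, length(arms))
    for (j in seq_along(arms)) for (i in seq_len(nq)) {
      h <- hood[[i, j]]
      pred[i, j] <- switch(h$type,
        global = gmean,
        drug = mean(aff[h$idx]),
        knn = sum(h$w * aff[h$idx]) / sum(h$w))
      if (identical(h$type, "knn")) {
        supp[i, j] <- h$support
        rankable[i, j] <- TRUE
      }
    }
    ap <- numeric(nq); keep <- logical(nq)
    for (i in seq_len(nq)) {
      use <- if (any(rankable[i, ])) which(rankable[i, ]) else
        seq_along(arms)
      ord <- use[order(-pred[i, use], -supp[i, use], arms[use],
                       method = "radix")]
      ap_i <- average_precision_at_k(arms[ord], relevant[[i]], 3L)
      keep[i] <- !is.na(ap_i)
      ap[i] <- if (keep[i]) ap_i else 0
    }
    list(map3 = if (any(keep)) mean(ap[keep]) else NA_real_, pred = pred)
  }

  real <- score_with(pool$affinity)
  pred_actual <- vapply(seq_len(nq),
                        function(i) real$pred[i, cons$arm[i]], numeric(1))
  ok <- !is.na(obs)
  null <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(r) {
      score_with(sample(pool$affinity))$map3
    }, numeric(1))
  })
  list(map3 = real$map3,
       null = null,
       null_q975 = stats::quantile(null, 0.975, names = FALSE),
       rmse = rmse(pred_actual[ok], obs[ok]),
       rmse_baseline = rmse(rep(mean(pool$affinity), sum(ok)), obs[ok]),
       n_test_consultations = nq)
}
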