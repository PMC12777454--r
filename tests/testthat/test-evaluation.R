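test_that("fold plans partition patients, group consultations and are reproducible", {
  ids <- sprintf("p%02d", 1:10)
  plan <- make_fold_plan(ids, n_outer = 5, n_inner = 3, seed = 7)
  sizes <- vapply(plan$outer, function(f) length(f$test), integer(1))
  expect_identical(sizes, rep(2L, 5))
  # every patient in exactly one outer test fold
  all_test <- unlist(lapply(plan$outer, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_identical(anyDuplicated(all_test), 0L)
  # inner folds partition the outer training ids
  for (f in plan$outer) {
    expect_setequal(unlist(f$inner), setdiff(ids, f$test))
  }
  plan2 <- make_fold_plan(ids, n_outer = 5, n_inner = 3, seed = 7)
  expect_identical(plan, plan2)
  expect_false(identical(plan, make_fold_plan(ids, 5, 3, seed = 8)))
  expect_error(make_fold_plan(ids[1:3], n_outer = 5),
               class = "srx_too_few_patients_error")
})

test_that("K selection finds the informative neighbourhood and breaks ties low", {
  co <- clustered_cohort(n_clusters = 13, cluster_size = 10, seed = 99)
  ids <- co$patients$patient_id
  plan <- make_fold_plan(ids, 5, 5, seed = 42)
  for (f in plan$outer) {
    train_ids <- setdiff(ids, f$test)
    k <- select_k(co, train_ids, f$inner, "cf_euclidean",
                  k_grid = seq(5L, 60L, by = 5L))
    expect_identical(as.integer(k), 5L)
  }

  # identical outcomes everywhere: every K ties exactly, smallest returned
  co_tie <- clustered_cohort(n_clusters = 4, cluster_size = 10, seed = 98,
                             identical_outcomes = TRUE)
  ids_t <- co_tie$patients$patient_id
  plan_t <- make_fold_plan(ids_t, 5, 5, seed = 1)
  train_t <- setdiff(ids_t, plan_t$outer[[1]]$test)
  k_t <- select_k(co_tie, train_t, plan_t$outer[[1]]$inner, "cf_euclidean")
  rmses <- attr(k_t, "inner_rmse")
  expect_true(max(rmses) - min(rmses) < 1e-12)
  expect_identical(as.integer(k_t), 5L)
})

test_that("outer-fold evaluation enforces train-only statistics and determinism", {
  co <- cached_cohort(60, seed = 5)
  ids <- unique(co$patients$patient_id)
  train_ids <- ids[1:48]; test_ids <- ids[49:60]
  expect_error(evaluate_fold(co, train_ids, c(train_ids[1], test_ids),
                             "cf_cosine", K = 5),
               class = "srx_temporal_leakage_error")

  ev1 <- evaluate_fold(co, train_ids, test_ids, "cf_cosine", K = 5)
  ev2 <- evaluate_fold(co, train_ids, test_ids, "cf_cosine", K = 5)
  expect_identical(ev1$details, ev2$details)

  # bounds identical whether or not test patients exist in the cohort at all
  co_trainonly <- co
  keep <- co$instances$patient_id %in% train_ids
  co_trainonly$instances <- co$instances[keep, ]
  b_full <- schizrec:::fold_context(co, train_ids)$bounds
  b_trim <- schizrec:::fold_context(co_trainonly, train_ids)$bounds
  expect_equal(as.data.frame(b_full), as.data.frame(b_trim))

  # a visit-2 evaluation uses the visit-1 record but never future visits
  expect_true(all(ev1$details$history_max_visit < ev1$details$visit_index))
})

test_that("nested CV produces leakage-clean, visit-stratified, reproducible results", {
  co <- cached_cohort(60, seed = 5)
  res <- run_nested_cv(co, "cf_cosine", k_grid = c(5L, 10L), seed = 42)
  expect_s3_class(res, "srx_cv_result")
  expect_identical(res$audit$max_train_test_intersection, 0L)
  expect_identical(res$audit$total_future_visit_reads, 0L)
  expect_identical(res$metrics$stratum,
                   c("overall", "visit_1", "visit_2", "visit_3"))
  # coverage is the exact complement of overlap in every stratum and fold
  expect_equal(res$fold_metrics$coverage, 1 - res$fold_metrics$overlap)
  # every consultation evaluated exactly once across outer folds
  expect_identical(nrow(res$details), nrow(co$consultations))

  res2 <- run_nested_cv(co, "cf_cosine", k_grid = c(5L, 10L), seed = 42)
  expect_identical(res$details, res2$details)
  expect_identical(res$metrics, res2$metrics)
})

test_that("frozen models validate externally without re-tuning", {
  co <- cached_cohort(60, seed = 5)
  frozen <- freeze_model(co, "cf_cosine", K = 7)
  expect_identical(frozen$K, 7L)

  # schema mismatch is rejected
  broken <- cached_cohort(40, seed = 6)
  broken$consultations$age_years <- NULL
  expect_error(external_validate(frozen, broken),
               class = "srx_schema_mismatch_error")

  ext <- cached_cohort(40, seed = 6)
  out <- external_validate(frozen, ext)
  expect_identical(out$metrics$stratum,
                   c("overall", "visit_1", "visit_2", "visit_3"))
  expect_true(all(out$details$predicted_actual >= 0 &
                    out$details$predicted_actual <= 1))

  # a novel ethnicity label runs with a warning, encoded as zeros
  ext2 <- ext
  ext2$consultations$ethnicity[1] <- "Martian"
  expect_warning(external_validate(frozen, ext2),
                 class = "srx_unseen_level_warning")
})

test_that("sensitivity reruns share the fold plan and equal-weight reproduces the primary run", {
  co <- cached_cohort(60, seed = 5)
  sens <- run_sensitivity(co, "cf_cosine", k_grid = c(5L,  10L), seed = 42)
  expect_named(sens$runs, c("equal", "stability_heavy", "burden_heavy"))
  primary <- run_nested_cv(co, "cf_cosine", k_grid = c(5L, 10L), seed = 42,
                           scheme = "equal")
  expect_identical(sens$runs$equal$details, primary$details)
  expect_identical(sens$runs$equal$metrics$rmse_mean,
                   primary$metrics$rmse_mean)
  for (nm in names(sens$runs)) {
    expect_identical(sens$runs[[nm]]$plan, primary$plan)
  }
})
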