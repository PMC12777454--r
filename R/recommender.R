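# K-nearest-neighbour prediction of per-drug affinity and ranked top-3
# recommendation lists. User-based neighbourhoods: the K most similar
# training patients overall form a query's neighbourhood, and each arm is
# scored from the neighbours' observed outcomes on it — so the ranked list
# is grounded in what similar patients actually received, and an arm with
# no evidence among the neighbours cannot crowd the list on the strength of
# one or two extreme historical outcomes. Predictions are
# similarity-weighted means (unweighted available), with a logged fallback
# chain (drug training mean, then global training mean) used for error
# measurement of arms outside the neighbourhood.

#' Predict affinity of one consultation for one drug
#'
#' Similarity-weighted mean of the K most similar training instances'
#' observed affinities for `drug`: `sum(sim * A) / sum(sim)`. If fewer than
#' K neighbours carry an outcome for the drug, all are used; if every
#' candidate similarity is 0, the drug's training-mean affinity is used; if
#' the drug is unobserved in training, the global training mean.
#'
#' @param sims Numeric vector: similarity of the query to every training
#'   instance (non-negative).
#' @param train_drug Character vector of training instance arms.
#' @param train_affinity Numeric vector of observed training affinities.
#' @param drug Arm to score.
#' @param K Neighbourhood size (>= 1).
#' @param weighted Similarity-weighted (default) or unweighted mean.
#' @param tie_key Optional character vector (one per training instance):
#'   similarity ties at the neighbourhood boundary break on this key so
#'   predictions are invariant to training-pool row order.
#' @return List: `prediction`, `support` (neighbours used), `fallback`
#'   (`"none"`, `"drug_mean"` or `"global_mean"`).
#' @export
predict_affinity <- function(sims, train_drug, train_affinity, drug, K,
                             weighted = TRUE, tie_key = NULL) {
  stopifnot(K >= 1)
  idx <- which(train_drug == drug)
  if (length(idx) == 0) {
    return(list(prediction = mean(train_affinity), support = 0L,
                fallback = "global_mean"))
  }
  s <- sims[idx]
  key <- if (is.null(tie_key)) idx else tie_key[idx]
  ord <- idx[order(-s, key, method = "radix")]
  top <- ord[seq_len(min(K, length(ord)))]
  w <- sims[top]
  if (sum(w) == 0) {
    return(list(prediction = mean(train_affinity[idx]), support = 0L,
                fallback = "drug_mean"))
  }
  pred <- if (weighted) {
    sum(w * train_affinity[top]) / sum(w)
  } else {
    mean(train_affinity[top])
  }
  list(prediction = pred, support = length(top), fallback = "none")
}

# All-arms prediction for a block of query rows; the vectorised core used by
# the evaluation harness. User-based neighbourhoods: for each query the K
# most similar training *patients* (patient similarity = best similarity
# over the patient's instances) form the neighbourhood; an arm's prediction
# is the similarity-weighted mean of the neighbours' observed affinities for
# that arm. Arms no neighbour has an outcome for fall back to the drug's
# training mean (or the global mean for arms unobserved in training); the
# fallback flag lets callers keep such unevidenced arms out of rankings
# while still scoring the actually-prescribed arm for error measurement.
predict_all_arms <- function(S, train_patient, train_drug, train_affinity,
                             arms = treatment_arms(), K, weighted = TRUE) {
  nq <- nrow(S)
  pat_cols <- split(seq_along(train_patient), train_patient)  # sorted ids
  pats <- names(pat_cols)
  P <- vapply(pat_cols, function(cs) {
    if (length(cs) == 1L) S[, cs] else do.call(pmax, lapply(cs, function(c) S[, c]))
  }, numeric(nq))
  if (nq == 1L) P <- matrix(P, nrow = 1L, dimnames = list(NULL, pats))

  key <- paste(train_patient, train_drug)
  gmean <- mean(train_affinity)
  dmean <- tapply(train_affinity, train_drug, mean)

  pred <- matrix(NA_real_, nq, length(arms), dimnames = list(NULL, arms))
  support <- matrix(0L, nq, length(arms), dimnames = list(NULL, arms))
  fallback <- matrix("none", nq, length(arms), dimnames = list(NULL, arms))

  k_use <- min(K, length(pats))
  for (i in seq_len(nq)) {
    ord <- order(-P[i, ], pats, method = "radix")[seq_len(k_use)]
    neigh <- pats[ord]
    w_all <- P[i, ord]
    for (a in arms) {
      rows <- match(paste(neigh, a), key)
      has <- !is.na(rows)
      if (!any(has)) {
        if (is.na(dmean[a])) {
          pred[i, a] <- gmean
          fallback[i, a] <- "global_mean"
        } else {
          pred[i, a] <- dmean[[a]]
          fallback[i, a] <- "drug_mean"
        }
        next
      }
      w <- w_all[has]
      aff <- train_affinity[rows[has]]
      if (sum(w) == 0) {
        pred[i, a] <- dmean[[a]]
        fallback[i, a] <- "drug_mean"
      } else {
        pred[i, a] <- if (weighted) sum(w * aff) / sum(w) else mean(aff)
        support[i, a] <- sum(has)
      }
    }
  }
  list(pred = pred, support = support, fallback = fallback)
}

# ranking input: arms with genuine neighbour evidence compete; fallback-only
# arms are withheld (NA) unless nothing at all is evidenced
ranking_predictions <- function(pred_row, fallback_row) {
  out <- pred_row
  if (any(fallback_row == "none")) out[fallback_row != "none"] <- NA_real_
  out
}

#' Rank treatment arms for one consultation
#'
#' Sorts arms by predicted affinity (descending); exact ties break toward
#' larger neighbour support, then lexicographic arm name, so rankings are
#' total and bit-reproducible. `"NONE"` competes as an ordinary arm.
#'
#' @param predictions Named numeric vector of per-arm predicted affinities.
#' @param support Named integer vector of per-arm neighbour support
#'   (defaults to 0 for all).
#' @return Tibble with `rank`, `arm`, `predicted`, `support`; attribute
#'   `top3` holds the first `min(3, n)` arms.
#' @export
rank_treatments <- function(predictions, support = NULL) {
  keep <- !is.na(predictions)
  if (!any(keep)) {
    srx_abort("srx_no_scorable_arm_error", "no arm could be scored")
  }
  predictions <- predictions[keep]
  if (is.null(support)) support <- setNames(rep(0L, length(predictions)),
                                            names(predictions))
  support <- support[names(predictions)]
  ord <- order(-predictions, -support, names(predictions), method = "radix")
  out <- tibble::tibble(
    rank = seq_along(ord),
    arm = names(predictions)[ord],
    predicted = as.numeric(predictions[ord]),
    support = as.integer(support[ord])
  )
  attr(out, "top3") <- out$arm[seq_len(min(3L, nrow(out)))]
  out
}

#' Recommend treatments for one test consultation
#'
#' End-to-end single-consultation API: guards the temporal discipline
#' (supplied history must predate the consultation's visit), excludes the
#' test patient from the neighbour pool entirely, computes similarities
#' with a fitted model, predicts every arm's affinity and returns the
#' ranked list.
#'
#' @param consultation One-row tibble: consultation ids + feature columns
#'   (built by [build_feature_vector()] from visits before `visit_index`).
#' @param training_pool Tibble of training instances with feature columns
#'   plus `patient_id`, `drug`, `affinity`.
#' @param model Fitted `srx_similarity_model` (on the training pool).
#' @param K Neighbourhood size.
#' @param patient_history Optional tibble of the patient's prior visits
#'   (checked: all `visit_index` strictly below the consultation's).
#' @param weighted Similarity-weighted averaging?
#' @return A [rank_treatments()] tibble.
#' @export
recommend_for_visit <- function(consultation, training_pool, model, K,
                                patient_history = NULL, weighted = TRUE) {
  v <- consultation$visit_index
  if (!is.null(patient_history) && nrow(patient_history) > 0 &&
      any(patient_history$visit_index >= v)) {
    srx_abort("srx_temporal_leakage_error",
              "patient_history contains the current or a future visit")
  }
  pool <- training_pool[training_pool$patient_id != consultation$patient_id, ,
                        drop = FALSE]
  assert_nonempty_df(pool, "training pool (after excluding the test patient)")
  S <- similarity_to_train(model, consultation)
  # model was fitted on the full pool; drop excluded columns if needed
  if (ncol(S) != nrow(pool)) {
    keep <- training_pool$patient_id != consultation$patient_id
    S <- S[, keep, drop = FALSE]
  }
  res <- predict_all_arms(S, pool$patient_id, pool$drug, pool$affinity,
                          K = K, weighted = weighted)
  rank_treatments(ranking_predictions(res$pred[1, ], res$fallback[1, ]),
                  res$support[1, ])
}
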