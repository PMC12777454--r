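# Patient-grouped fold plans for nested cross-validation: an outer 5-fold
# split of patient ids (~20% test each) and, inside each outer training set,
# an inner 5-fold patient-grouped split for neighbourhood-size selection.
# A patient's consultations never span the train and test side of any split.

#' Build a nested patient-grouped fold plan
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param n_outer,n_inner Numbers of outer and inner folds (default 5/5).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return An `srx_fold_plan`: list with `seed`, `n_outer`, `n_inner` and
#'   `outer`, a list of `list(test = ids, inner = list of validation-id
#'   vectors partitioning the outer training ids)`.
#' @export
make_fold_plan <- function(patient_ids, n_outer = 5L, n_inner = 5L,
                           seed = 42L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (n < n_outer) {
    srx_abort("srx_too_few_patients_error",
              sprintf("%d patients cannot fill %d outer folds", n, n_outer))
  }
  split_ids <- function(ids, k, s) {
    shuffled <- withr::with_seed(s, sample(ids))
    unname(split(shuffled, rep_len(seq_len(k), length(shuffled))))
  }
  outer_sets <- split_ids(patient_ids, n_outer, seed)
  outer <- lapply(seq_len(n_outer), function(k) {
    test <- sort(outer_sets[[k]])
    train <- setdiff(patient_ids, test)
    if (length(train) < n_inner) {
      srx_abort("srx_too_few_patients_error",
                "outer training set too small for the inner folds")
    }
    inner <- lapply(split_ids(train, n_inner, seed + k), sort)
    list(test = test, inner = inner)
  })
  structure(list(seed = seed, n_outer = n_outer, n_inner = n_inner,
                 outer = outer),
            class = "srx_fold_plan")
}

#' @export
print.srx_fold_plan <- function(x, ...) {
  sizes <- vapply(x$outer, function(f) length(f$test), integer(1))
  cat("<srx_fold_plan> ", x$n_outer, "x", x$n_inner,
      " patient-grouped folds (seed ", x$seed, "); outer test sizes: ",
      paste(sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}
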