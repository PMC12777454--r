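# The five patient-similarity engines. Two operate on the encoded feature
# space directly (cosine, Euclidean-converted), one on a Gaussian RBF kernel
# of the encoded space, one on the raw mixed-type records (weighted Gower
# with ReliefF attribute weights) and one in an NCA-learned linear map of
# the encoded space. All emit similarities in [0, 1]; cosine values that dip
# below zero after standardisation are clipped to 0 so that downstream
# weighted averaging uses non-negative weights.

.sim_epsilon <- 1e-9

#' Cosine similarity
#'
#' `dot(x, y) / (||x|| * ||y||)`. A zero vector has no direction; such
#' arguments return 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    srx_warn("srx_zero_vector_warning",
             "cosine similarity of a zero vector is undefined; returning 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' Euclidean distance converted to similarity
#'
#' `1 / (1 + ||x - y|| + 1e-9)`; the epsilon guards the division although
#' the denominator is already positive, and identical vectors score just
#' under 1.
#'
#' @inheritParams cosine_similarity
#' @export
euclidean_similarity <- function(x, y) {
  1 / (1 + sqrt(sum((x - y)^2)) + .sim_epsilon)
}

#' Gaussian RBF similarity
#'
#' `exp(-gamma * ||x - y||^2)`; the default bandwidth used by the fitted
#' models is `1 / n_features`.
#'
#' @inheritParams cosine_similarity
#' @param gamma Positive kernel bandwidth.
#' @export
rbf_similarity <- function(x, y, gamma) {
  stopifnot(gamma > 0)
  exp(-gamma * sum((x - y)^2))
}

#' Weighted Gower similarity of two mixed-type records
#'
#' Categorical features contribute 1 iff equal; numeric features contribute
#' `1 - |u - v| / range` with ranges fitted on the training fold (clipped to
#' `[0, 1]` for out-of-range test values). The result is the weighted mean
#' over features where both records are non-missing.
#'
#' @param u,v One-row tibbles (or lists) on the [feature_schema()] columns.
#' @param ranges Named numeric vector of training-fold ranges for the
#'   numeric features (a zero range makes the feature uninformative: it
#'   contributes 1 when both values are present).
#' @param weights Named non-negative per-feature weights; default all 1.
#' @return Scalar similarity in `[0, 1]`.
#' @export
gower_similarity <- function(u, v, ranges, weights = NULL) {
  sch <- feature_schema()
  feats <- c(sch$categorical, sch$numeric)
  if (is.null(weights)) weights <- setNames(rep(1, length(feats)), feats)
  num <- 0; den <- 0
  for (f in feats) {
    a <- u[[f]]; b <- v[[f]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) next
    w <- weights[[f]]
    if (is.null(w) || is.na(w)) w <- 0
    if (f %in% sch$categorical) {
      part <- as.numeric(identical(as.character(a), as.character(b)))
    } else {
      r <- ranges[[f]]
      part <- if (is.null(r) || is.na(r) || r == 0) 1 else
        1 - min(abs(as.numeric(a) - as.numeric(b)) / r, 1)
    }
    num <- num + w * part
    den <- den + w
  }
  if (den == 0) {
    srx_abort("srx_all_missing_error",
              "no comparable (non-missing, positively weighted) feature between records")
  }
  num / den
}

# ---------------------------------------------------------------------------
# fitted similarity models

#' Fit a similarity model on a training fold
#'
#' @param method One of `"cf_cosine"`, `"cf_euclidean"`, `"dr_rba_gower"`,
#'   `"dr_rbf"`, `"dr_nca"`.
#' @param train_features Tibble of training feature rows.
#' @param train_labels Binary labels (observed affinity > 0.5) — required by
#'   the ReliefF weighting of `dr_rba_gower` and the NCA fit of `dr_nca`.
#' @param config Optional list of hyperparameters: `relieff_neighbors` (10),
#'   `rbf_gamma` (default `1/n_features`), `nca_max_iter` (100), `nca_seed`
#'   (1), `nca_max_samples` (200), `gower_top_m` (optional top-m ReliefF
#'   feature selection; default keeps and weights all features).
#' @return An object of class `srx_similarity_model`.
#' @export
fit_similarity_model <- function(method, train_features, train_labels = NULL,
                                 config = list()) {
  method <- match.arg(method, c("cf_cosine", "cf_euclidean", "dr_rba_gower",
                                "dr_rbf", "dr_nca"))
  assert_nonempty_df(train_features, "training feature table")
  fs <- fit_feature_space(train_features)
  X <- transform_features(fs, train_features)
  model <- list(method = method, feature_space = fs, train_matrix = X,
                epsilon = .sim_epsilon)

  if (method == "dr_rbf") {
    model$gamma <- config$rbf_gamma %||% (1 / ncol(X))
  }
  if (method == "dr_rba_gower") {
    if (is.null(train_labels)) {
      srx_abort("srx_not_fitted_error",
                "dr_rba_gower requires binary training labels for ReliefF")
    }
    sch <- feature_schema()
    rng <- vapply(sch$numeric, function(cn) {
      x <- train_features[[cn]]
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else max(x) - min(x)
    }, numeric(1))
    model$gower_ranges <- rng
    w <- relieff_weights(train_features, train_labels,
                         n_neighbors = config$relieff_neighbors %||% 10L)
    top_m <- config$gower_top_m
    if (!is.null(top_m) && top_m < length(w)) {
      w[rank(-w, ties.method = "first") > top_m] <- 0
    }
    model$feature_weights <- w
    model$train_features <- train_features
  }
  if (method == "dr_nca") {
    if (is.null(train_labels)) {
      srx_abort("srx_not_fitted_error",
                "dr_nca requires binary training labels")
    }
    fit <- nca_fit(X, train_labels,
                   max_iter = config$nca_max_iter %||% 100L,
                   seed = config$nca_seed %||% 1L,
                   max_samples = config$nca_max_samples %||% 200L)
    model$nca <- fit
    model$train_mapped <- X %*% fit$transform
  }
  class(model) <- "srx_similarity_model"
  model
}

# dense similarity of query rows against all training rows; the workhorse
# behind prediction. Returns an n_query x n_train matrix in [0, 1].
#' Similarity of query consultations to the training pool
#'
#' @param model An `srx_similarity_model`.
#' @param query_features Tibble of query feature rows (encoded with the
#'   model's train-fitted feature space; never refitted).
#' @return Matrix `n_query x n_train` of similarities in `[0, 1]`.
#' @export
similarity_to_train <- function(model, query_features) {
  if (!inherits(model, "srx_similarity_model")) {
    srx_abort("srx_not_fitted_error",
              "model must come from fit_similarity_model()")
  }
  Q <- transform_features(model$feature_space, query_features)
  Xt <- model$train_matrix
  switch(model$method,
    cf_cosine = {
      qn <- sqrt(rowSums(Q^2)); tn <- sqrt(rowSums(Xt^2))
      qn[qn == 0] <- 1; tn[tn == 0] <- 1
      S <- (Q %*% t(Xt)) / outer(qn, tn)
      pmin(pmax(S, 0), 1)
    },
    cf_euclidean = 1 / (1 + .cross_dist(Q, Xt) + model$epsilon),
    dr_rbf = exp(-model$gamma * .cross_dist(Q, Xt)^2),
    dr_nca = {
      Qm <- Q %*% model$nca$transform
      1 / (1 + .cross_dist(Qm, model$train_mapped) + model$epsilon)
    },
    dr_rba_gower = .gower_matrix(query_features, model$train_features,
                                 model$gower_ranges, model$feature_weights)
  )
}

# vectorised weighted Gower similarity of all query rows vs all train rows;
# agrees with gower_similarity() pair by pair
.gower_matrix <- function(qf, tf, ranges, weights) {
  sch <- feature_schema()
  feats <- c(sch$categorical, sch$numeric)
  nq <- nrow(qf); nt <- nrow(tf)
  num <- matrix(0, nq, nt); den <- matrix(0, nq, nt)
  for (f in feats) {
    w <- weights[[f]]
    if (is.null(w) || is.na(w) || w == 0) next
    a <- qf[[f]]; b <- tf[[f]]
    present <- outer(!is.na(a), !is.na(b), "&")
    if (f %in% sch$categorical) {
      part <- outer(as.character(a), as.character(b), "==")
      part[!present] <- 0
      part <- part * 1
    } else {
      r <- ranges[[f]]
      if (is.null(r) || is.na(r) || r == 0) {
        part <- matrix(1, nq, nt)
      } else {
        part <- 1 - pmin(abs(outer(as.numeric(a), as.numeric(b), "-")) / r, 1)
      }
      part[!present] <- 0
    }
    num <- num + w * part * present
    den <- den + w * present
  }
  if (any(den == 0)) {
    srx_abort("srx_all_missing_error",
              "a query/train pair shares no comparable feature")
  }
  num / den
}

# pairwise Euclidean distances between rows of A and rows of B. Computed as
# an explicit per-row sweep: the ||x||^2 + ||y||^2 - 2xy expansion loses
# ~1e-6 of precision near zero distance, which matters because identical
# records must score sim = 1/(1 + 1e-9) essentially exactly.
.cross_dist <- function(A, B) {
  tB <- t(B)
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    out[i, ] <- sqrt(colSums((tB - A[i, ])^2))
  }
  out
}
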