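# ReliefF attribute weighting for the mixed-type feature schema. Per-feature
# differences use the Gower convention (categorical: 0/1 disagreement;
# numeric: |u - v| / range), so the instance distance used for neighbour
# search is consistent with the weighted Gower similarity the weights feed.

#' ReliefF feature weights on binary labels
#'
#' Standard ReliefF: for every instance, find its `n_neighbors` nearest
#' hits (same class) and misses (other class); a feature's weight
#' accumulates mean miss-difference minus mean hit-difference. Raw scores
#' are floored at 0 and rescaled to mean 1 (a constant feature keeps
#' weight 0). Labels are `1{observed affinity > 0.5}`.
#'
#' @param X Tibble of feature rows on the [feature_schema()] columns (extra
#'   columns are ignored), or a plain numeric matrix/data.frame whose
#'   columns are all treated as numeric features.
#' @param labels Binary vector (0/1 or logical), one per row of `X`.
#' @param n_neighbors Number of hit/miss neighbours (default 10, truncated
#'   to class size - 1 when classes are small).
#' @return Named non-negative weights, mean 1 unless all scores floor to 0.
#' @export
relieff_weights <- function(X, labels, n_neighbors = 10L) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    srx_abort("srx_single_class_error",
              "ReliefF needs at least 2 instances in each class")
  }
  sch <- feature_schema()
  if (is.matrix(X)) X <- tibble::as_tibble(as.data.frame(X))
  known <- c(sch$categorical, sch$numeric)
  if (all(names(X) %in% c(known, "patient_id", "visit_index", "arm",
                          "history_max_visit")) &&
      any(names(X) %in% known)) {
    cat_cols <- intersect(sch$categorical, names(X))
    num_cols <- intersect(sch$numeric, names(X))
  } else {
    cat_cols <- names(X)[!vapply(X, is.numeric, logical(1))]
    num_cols <- names(X)[vapply(X, is.numeric, logical(1))]
  }
  feats <- c(cat_cols, num_cols)
  n <- nrow(X)

  # per-feature pairwise diff arrays (n x n), NA-masked to 0 with presence
  diffs <- list(); pres <- list()
  for (f in feats) {
    x <- X[[f]]
    p <- outer(!is.na(x), !is.na(x), "&")
    if (f %in% cat_cols) {
      d <- 1 - (outer(as.character(x), as.character(x), "==") * 1)
    } else {
      x <- as.numeric(x)
      r <- diff(range(x, na.rm = TRUE))
      d <- if (!is.finite(r) || r == 0) matrix(0, n, n) else
        pmin(abs(outer(x, x, "-")) / r, 1)
    }
    d[!p] <- 0
    diffs[[f]] <- d; pres[[f]] <- p
  }
  den <- Reduce(`+`, pres)
  dist <- Reduce(`+`, diffs) / pmax(den, 1)
  diag(dist) <- Inf

  w <- setNames(numeric(length(feats)), feats)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    other <- which(labels != labels[i])
    k_h <- min(n_neighbors, length(same))
    k_m <- min(n_neighbors, length(other))
    hits <- same[order(dist[i, same])][seq_len(k_h)]
    misses <- other[order(dist[i, other])][seq_len(k_m)]
    for (f in feats) {
      w[f] <- w[f] + mean(diffs[[f]][i, misses]) - mean(diffs[[f]][i, hits])
    }
  }
  w <- w / n
  w <- pmax(w, 0)
  if (mean(w) > 0) w <- w / mean(w)
  w
}
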