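# Neighbourhood components analysis: learns a square linear map A of the
# encoded feature space that maximises the expected leave-one-out
# classification accuracy under soft (softmax) neighbour assignments,
#   p_ij = exp(-||Ax_i - Ax_j||^2) / sum_{k != i} exp(-||Ax_i - Ax_k||^2),
#   f(A) = sum_i sum_{j in class(i)} p_ij.
# The gradient is evaluated in its vectorised Laplacian form, and -f is
# minimised with L-BFGS-B starting from the identity map, which makes the
# fit deterministic for a given dataset.

#' Fit an NCA linear transform
#'
#' @param X Numeric matrix of encoded training features (rows = instances).
#' @param labels Binary labels (observed affinity > 0.5), one per row.
#' @param max_iter Maximum optimiser iterations; `0` returns the identity
#'   map, under which NCA similarities reduce to plain Euclidean ones.
#' @param seed Seed controlling the deterministic subsample (and any future
#'   stochastic initialisation); fits are bit-reproducible given the same
#'   seed and data.
#' @param max_samples Fit on at most this many rows (deterministic,
#'   seed-controlled subsample) to keep the quadratic objective tractable
#'   on large folds; the learned map is then applied to all rows.
#' @return List of class `srx_nca`: `transform` (d x d matrix),
#'   `converged`, `objective`.
#' @export
nca_fit <- function(X, labels, max_iter = 100L, seed = 1L,
                    max_samples = 200L) {
  X <- as.matrix(X)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    srx_abort("srx_single_class_error", "NCA needs two classes")
  }
  d <- ncol(X)
  if (max_iter <= 0L) {
    return(structure(list(transform = diag(d), converged = TRUE,
                          objective = NA_real_), class = "srx_nca"))
  }
  if (nrow(X) > max_samples) {
    idx <- withr::with_seed(seed, sample.int(nrow(X), max_samples))
    idx <- sort(idx)
    X <- X[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  n <- nrow(X)
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE

  obj_grad <- function(a_vec) {
    A <- matrix(a_vec, d, d)
    Z <- X %*% A
    d2 <- outer(rowSums(Z^2), rowSums(Z^2), "+") - 2 * Z %*% t(Z)
    d2 <- pmax(d2, 0)
    lo <- -d2
    diag(lo) <- -Inf
    lo <- lo - apply(lo, 1, max)
    P <- exp(lo)
    P <- P / rowSums(P)            # p_ij, rows sum to 1
    p_i <- rowSums(P * same)       # soft per-instance accuracy
    f <- sum(p_i)
    # dF/dA = 2 X^T L X A with W_ij = p_i p_ij - p_ij 1{j in class(i)}
    W <- P * p_i - P * same
    Dr <- diag(rowSums(W)); Dc <- diag(colSums(W))
    L <- Dr + Dc - W - t(W)
    G <- 2 * t(X) %*% L %*% X %*% A
    list(f = f, g = G)
  }

  fn <- function(a) -obj_grad(a)$f
  gr <- function(a) -as.numeric(obj_grad(a)$g)
  fit <- tryCatch(
    stats::optim(as.numeric(diag(d)), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter)),
    error = function(e) NULL)
  if (is.null(fit)) {
    srx_warn("srx_convergence_warning",
             "NCA optimisation failed; falling back to the identity map")
    return(structure(list(transform = diag(d), converged = FALSE,
                          objective = NA_real_), class = "srx_nca"))
  }
  if (fit$convergence != 0) {
    srx_warn("srx_convergence_warning",
             sprintf("NCA optimiser stopped without convergence (code %d)",
                     fit$convergence))
  }
  structure(list(transform = matrix(fit$par, d, d),
                 converged = fit$convergence == 0,
                 objective = -fit$value),
            class = "srx_nca")
}

#' Apply a fitted NCA transform
#' @param nca An `srx_nca` fit.
#' @param X Encoded feature matrix.
#' @return Mapped matrix `X %*% transform`.
#' @export
nca_transform <- function(nca, X) {
  if (!inherits(nca, "srx_nca")) {
    srx_abort("srx_not_fitted_error", "nca must come from nca_fit()")
  }
  as.matrix(X) %*% nca$transform
}
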