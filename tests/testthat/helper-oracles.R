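# Independent brute-force oracles. Each re-implements a formula or procedure
# directly from its definition, sharing no code with the package paths it
# checks.

# affinity as one expression: min-max components (clipped), equal/custom
# weights, switch penalty, final clip. bounds: list(gap=c(mn,mx), sw=, los=,
# nv=) ; single-visit / no-switch components are 1 under the "best" policy.
oracle_affinity <- function(gap, sw_days, los, nv, sw_count,
                            bounds, w = c(.25, .25, .25, .25),
                            pen = c(-0.05, 0.10, 0.20)) {
  nm <- function(x, b, inv = FALSE) {
    v <- if (b[2] == b[1]) rep(0.5, length(x)) else
      pmin(pmax((x - b[1]) / (b[2] - b[1]), 0), 1)
    if (inv) 1 - v else v
  }
  t_ <- ifelse(is.na(gap), 1, nm(gap, bounds$gap))
  s_ <- ifelse(is.na(sw_days), 1, nm(sw_days, bounds$sw))
  l_ <- nm(los, bounds$los, inv = TRUE)
  v_ <- nm(nv, bounds$nv, inv = TRUE)
  pmin(pmax(w[1] * t_ + w[2] * s_ + w[3] * l_ + w[4] * v_ -
              pen[sw_count + 1], 0), 1)
}

oracle_cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

oracle_euclidean_sim <- function(x, y) 1 / (1 + sqrt(sum((x - y)^2)) + 1e-9)

oracle_rbf <- function(x, y, gamma) exp(-gamma * sum((x - y)^2))

# Gower over explicit feature lists
oracle_gower <- function(u, v, cat_cols, num_cols, ranges, weights) {
  num <- 0; den <- 0
  for (f in c(cat_cols, num_cols)) {
    a <- u[[f]]; b <- v[[f]]
    if (is.na(a) || is.na(b)) next
    part <- if (f %in% cat_cols) as.numeric(a == b) else {
      r <- ranges[[f]]
      if (r == 0) 1 else 1 - min(abs(a - b) / r, 1)
    }
    num <- num + weights[[f]] * part
    den <- den + weights[[f]]
  }
  num / den
}

# exhaustive sort-and-average KNN prediction
oracle_knn <- function(sims, drugs, affs, drug, K, weighted = TRUE) {
  idx <- which(drugs == drug)
  if (length(idx) == 0) return(mean(affs))
  ord <- idx[order(sims[idx], decreasing = TRUE)]
  top <- ord[seq_len(min(K, length(ord)))]
  w <- sims[top]
  if (sum(w) == 0) return(mean(affs[idx]))
  if (weighted) sum(w * affs[top]) / sum(w) else mean(affs[top])
}

# average precision by direct enumeration of ranks
oracle_ap3 <- function(ranked, relevant) {
  if (length(relevant) == 0) return(NA_real_)
  hits <- 0; total <- 0
  for (r in 1:min(3, length(ranked))) {
    if (ranked[r] %in% relevant) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / min(3, length(relevant))
}
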