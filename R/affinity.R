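# The composite treatment-outcome ("affinity") score. For every patient-drug
# instance, four utilisation quantities are min-max normalised against
# training-fold bounds and oriented so larger = better:
#   t : time between admissions        (longer gaps  -> fewer relapses)
#   s : time between medication switches (longer     -> greater stability)
#   l : 1 - norm(length of stay)
#   v : 1 - norm(number of visits)
# The base score is a weighted average (equal weights by default), a fixed
# switch penalty is subtracted (-0.05 bonus for no switch, 0.10 for a first
# switch, 0.20 for a second) and the result is clipped to [0, 1].

.affinity_quantities <- c("gap_days", "switch_days", "los_days", "n_visits")

#' Fit normalisation bounds on a training fold
#'
#' Records the per-quantity min and max of the raw utilisation quantities
#' (inter-admission days, inter-switch days, total length of stay, visit
#' count) over training instances only. The returned object is tagged with a
#' provenance label so downstream code can assert that test-set scoring
#' never reads test-set extrema.
#'
#' @param instances Tibble of training patient-drug instances (as in
#'   `srx_cohort$instances`).
#' @param provenance Free-text tag identifying the training fold.
#' @return An object of class `srx_bounds`: tibble with `quantity`, `min`,
#'   `max`, `degenerate`.
#' @export
fit_bounds <- function(instances, provenance = "training") {
  assert_nonempty_df(instances, "training instance set")
  rows <- lapply(.affinity_quantities, function(q) {
    x <- instances[[q]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      tibble::tibble(quantity = q, min = NA_real_, max = NA_real_,
                     degenerate = TRUE)
    } else {
      tibble::tibble(quantity = q, min = min(x), max = max(x),
                     degenerate = min(x) == max(x))
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- provenance
  class(out) <- c("srx_bounds", class(out))
  out
}

#' Min-max normalise against fitted bounds
#'
#' `(x - min) / (max - min)`, clipped to `[0, 1]` so that out-of-training
#' range values (which occur in external validation) stay bounded. A
#' degenerate quantity (`max == min`) maps to the uninformative midpoint
#' 0.5. With `invert = TRUE` returns one minus the normalised value.
#'
#' @param x Numeric vector of raw values.
#' @param min,max Training-fold bounds.
#' @param invert Return `1 - norm(x)`?
#' @return Numeric vector in `[0, 1]`; `NA` inputs stay `NA`.
#' @export
normalize_minmax <- function(x, min, max, invert = FALSE) {
  if (is.na(min) || is.na(max) || max == min) {
    out <- ifelse(is.na(x), NA_real_, 0.5)
  } else {
    out <- pmin(pmax((x - min) / (max - min), 0), 1)
  }
  if (invert) 1 - out else out
}

#' Affinity weighting schemes
#'
#' Three named schemes: the primary equal-weight formulation
#' (`b = (t + s + l + v) / 4`, penalties -0.05/0.10/0.20); a
#' stability-heavy variant up-weighting inter-admission gaps and switch
#' stability; and a patient-burden-heavy variant up-weighting length of
#' stay and visit count with halved penalties. The variant weights are
#' configuration defaults (any weights satisfying the variant ordering are
#' admissible) and can be overridden via [affinity_scheme()].
#'
#' @return Named list of three `srx_scheme` objects.
#' @export
affinity_schemes <- function() {
  list(
    equal = affinity_scheme("equal", c(t = .25, s = .25, l = .25, v = .25),
                            c(`0` = -0.05, `1` = 0.10, `2` = 0.20)),
    stability_heavy = affinity_scheme(
      "stability_heavy", c(t = .35, s = .35, l = .15, v = .15),
      c(`0` = -0.05, `1` = 0.10, `2` = 0.20)),
    burden_heavy = affinity_scheme(
      "burden_heavy", c(t = .15, s = .15, l = .35, v = .35),
      c(`0` = -0.025, `1` = 0.05, `2` = 0.10))
  )
}

#' @rdname affinity_schemes
#' @param name Scheme label.
#' @param weights Named non-negative weights `c(t=, s=, l=, v=)` summing to 1.
#' @param penalties Named penalties for switch counts `"0"`, `"1"`, `"2"`.
#' @export
affinity_scheme <- function(name, weights, penalties) {
  weights <- weights[c("t", "s", "l", "v")]
  if (anyNA(weights) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    srx_abort("srx_invalid_scheme_error",
              "weights must be non-negative, named t/s/l/v and sum to 1")
  }
  penalties <- penalties[c("0", "1", "2")]
  if (anyNA(penalties)) {
    srx_abort("srx_invalid_scheme_error",
              "penalties must be named '0', '1', '2'")
  }
  structure(list(name = name, weights = weights, penalties = penalties),
            class = "srx_scheme")
}

resolve_scheme <- function(scheme) {
  if (inherits(scheme, "srx_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1) {
    all <- affinity_schemes()
    if (scheme %in% names(all)) return(all[[scheme]])
  }
  srx_abort("srx_invalid_scheme_error",
            "scheme must be an srx_scheme or one of 'equal', 'stability_heavy', 'burden_heavy'")
}

#' Base score from normalised components
#'
#' Weighted average of the four components under the active scheme; the
#' equal-weight default reproduces `(t + s + l + v) / 4`. When a component
#' is `NA` (no observed gap or switch) and `na_policy = "renormalize"`, its
#' weight is dropped and the rest renormalised; with the default `"best"`
#' policy callers are expected to have imputed 1 already.
#'
#' @param components Tibble/data.frame with columns `t`, `s`, `l`, `v`.
#' @param scheme An `srx_scheme` or scheme name.
#' @param na_policy One of `"best"` (components assumed complete) or
#'   `"renormalize"`.
#' @return Numeric vector of base scores `b`.
#' @export
base_score <- function(components, scheme = "equal", na_policy = "best") {
  scheme <- resolve_scheme(scheme)
  m <- as.matrix(components[, c("t", "s", "l", "v")])
  w <- scheme$weights
  if (na_policy == "renormalize" && anyNA(m)) {
    wm <- matrix(w, nrow(m), 4, byrow = TRUE)
    wm[is.na(m)] <- 0
    m[is.na(m)] <- 0
    rowSums(m * wm) / rowSums(wm)
  } else {
    as.numeric(m %*% w)
  }
}

#' Apply the switch penalty and clip
#'
#' `A = clip(b - P, 0, 1)` with `P` = -0.05 for no switch (a bonus), 0.10
#' for a first switch and 0.20 for a second under the equal-weight scheme.
#'
#' @param b Numeric base scores.
#' @param switch_count Integer vector in `{0, 1, 2}`.
#' @inheritParams base_score
#' @return Numeric vector of final affinities in `[0, 1]`.
#' @export
apply_penalty <- function(b, switch_count, scheme = "equal") {
  scheme <- resolve_scheme(scheme)
  if (any(is.na(switch_count)) || any(!switch_count %in% 0:2)) {
    srx_abort("srx_invalid_switch_count_error",
              "switch_count must be 0, 1 or 2")
  }
  p <- scheme$penalties[as.character(switch_count)]
  pmin(pmax(b - as.numeric(p), 0), 1)
}

#' Compute affinity scores for patient-drug instances
#'
#' Composes normalisation, base score and penalty for a table of instances,
#' using (and never updating) the supplied training-fold bounds.
#' Single-visit patients have no observed inter-admission gap and
#' no-switch instances no inter-switch time; under the default
#' `missing_policy = "best"` those components are set to 1 (no readmission /
#' no switch is the best observed proxy), under `"renormalize"` the
#' component is dropped and the remaining weights renormalised.
#'
#' @param instances Tibble with `gap_days`, `switch_days`, `los_days`,
#'   `n_visits`, `switch_count`.
#' @param bounds An `srx_bounds` from [fit_bounds()].
#' @inheritParams base_score
#' @param missing_policy `"best"` or `"renormalize"`.
#' @return The input tibble plus columns `t`, `s`, `l`, `v`, `base_b`,
#'   `penalty_P`, `affinity`.
#' @export
compute_affinity <- function(instances, bounds, scheme = "equal",
                             missing_policy = c("best", "renormalize")) {
  missing_policy <- match.arg(missing_policy)
  scheme <- resolve_scheme(scheme)
  if (!inherits(bounds, "srx_bounds")) {
    srx_abort("srx_not_fitted_error", "bounds must come from fit_bounds()")
  }
  b_of <- function(q) bounds[bounds$quantity == q, , drop = FALSE]
  bg <- b_of("gap_days"); bs <- b_of("switch_days")
  bl <- b_of("los_days"); bv <- b_of("n_visits")

  sc <- pmin(instances$switch_count, 2L)
  comp <- tibble::tibble(
    t = normalize_minmax(instances$gap_days, bg$min, bg$max),
    s = normalize_minmax(instances$switch_days, bs$min, bs$max),
    l = normalize_minmax(instances$los_days, bl$min, bl$max, invert = TRUE),
    v = normalize_minmax(instances$n_visits, bv$min, bv$max, invert = TRUE)
  )
  if (missing_policy == "best") {
    comp$t[is.na(comp$t)] <- 1
    comp$s[is.na(comp$s)] <- 1
    b <- base_score(comp, scheme)
  } else {
    b <- base_score(comp, scheme, na_policy = "renormalize")
  }
  p <- as.numeric(scheme$penalties[as.character(sc)])
  out <- instances
  out$t <- comp$t; out$s <- comp$s; out$l <- comp$l; out$v <- comp$v
  out$switch_count <- sc
  out$base_b <- b
  out$penalty_P <- p
  out$affinity <- apply_penalty(b, sc, scheme)
  out
}
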