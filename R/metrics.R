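# Evaluation metrics: RMSE between predicted and observed affinities,
# mean average precision of the top-3 list (relevance = an arm the patient
# actually received with observed affinity > 0.5), and overlap/coverage of
# the clinician's actual therapy with the top 3.

#' Root-mean-square error
#'
#' @param predicted,observed Paired numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0 || length(predicted) != length(observed)) {
    srx_abort("srx_empty_pairs_error",
              "predicted/observed must be non-empty and paired")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Average precision of a top-k list
#'
#' `AP@k = sum_{r <= k} precision@r * rel(r) / min(k, |relevant|)`. Arms
#' without an observed outcome for the patient count as non-relevant.
#'
#' @param ranked Character vector of arms in rank order.
#' @param relevant Character vector of relevant arms.
#' @param k List depth (default 3).
#' @return AP in `[0, 1]`, or `NA` when `relevant` is empty (AP undefined).
#' @export
average_precision_at_k <- function(ranked, relevant, k = 3L) {
  if (length(relevant) == 0) return(NA_real_)
  top <- head(ranked, k)
  rel <- as.numeric(top %in% relevant)
  if (sum(rel) == 0) return(0)
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec * rel) / min(k, length(relevant))
}

#' Mean average precision at 3 over consultations
#'
#' Consultations whose relevant set is empty (no received arm with observed
#' affinity > 0.5) are skipped and counted in the `n_skipped` attribute —
#' average precision is undefined there.
#'
#' @param rankings List of character vectors (arms in rank order).
#' @param relevant_sets List of character vectors of relevant arms, aligned
#'   with `rankings`.
#' @return MAP@3 in `[0, 1]` with attributes `n_evaluated`, `n_skipped`.
#' @export
map_at_3 <- function(rankings, relevant_sets) {
  stopifnot(length(rankings) == length(relevant_sets))
  ap <- mapply(average_precision_at_k, rankings, relevant_sets,
               MoreArgs = list(k = 3L))
  keep <- !is.na(ap)
  if (!any(keep)) {
    srx_abort("srx_no_evaluable_consultation_error",
              "every consultation has an empty relevant set")
  }
  structure(mean(ap[keep]),
            n_evaluated = sum(keep), n_skipped = sum(!keep))
}

#' Overlap and coverage of the actual therapy
#'
#' Overlap is the fraction of consultations whose actually prescribed
#' therapy appears in the top 3; coverage is its exact complement.
#'
#' @param top3_lists List of character vectors (the top-3 arms).
#' @param actual Character vector of actually prescribed arms.
#' @return Named numeric vector `c(overlap =, coverage =)`.
#' @export
overlap_and_coverage <- function(top3_lists, actual) {
  stopifnot(length(top3_lists) == length(actual))
  hit <- mapply(function(t3, a) a %in% t3, top3_lists, actual)
  ov <- mean(hit)
  c(overlap = ov, coverage = 1 - ov)
}

#' Model-clinician disagreement analysis
#'
#' Restricted to consultations whose actual therapy is absent from the
#' top-3 list, compares the system's predicted affinity for its top
#' recommendation with the affinity the clinician's choice actually
#' achieved: paired differences `d_i = predicted(top arm) -
#' observed(actual arm)`, paired t statistic `mean(d)/(sd(d)/sqrt(n))`
#' (two-sided p, n - 1 df) and Cohen's d for paired data
#' (`mean(d)/sd(d)`). A negative mean difference means clinicians
#' outperformed the system.
#'
#' @param evaluations Tibble with columns `top3` (list-column of arm
#'   vectors), `top1_predicted`, `actual_arm`, `actual_observed`.
#' @return List of class `srx_disagreement`: `n`, `mean_difference`,
#'   `sd_difference`, `t`, `p_value`, `cohens_d`, and the mean
#'   predicted/observed levels.
#' @export
disagreement_analysis <- function(evaluations) {
  disagree <- !mapply(function(t3, a) a %in% t3,
                      evaluations$top3, evaluations$actual_arm)
  ev <- evaluations[disagree, , drop = FALSE]
  n <- nrow(ev)
  if (n < 2) {
    srx_abort("srx_too_few_cases_error",
              sprintf("disagreement analysis needs >= 2 cases, got %d", n))
  }
  d <- ev$top1_predicted - ev$actual_observed
  m <- mean(d); s <- stats::sd(d)
  t_stat <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf   # degenerate: all differences equal
  } else m / (s / sqrt(n))
  structure(list(
    n = n,
    mean_difference = m,
    sd_difference = s,
    t = t_stat,
    p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
    cohens_d = if (s == 0) { if (m == 0) 0 else sign(m) * Inf } else m / s,
    mean_predicted = mean(ev$top1_predicted),
    mean_observed = mean(ev$actual_observed)
  ), class = "srx_disagreement")
}

#' @export
print.srx_disagreement <- function(x, ...) {
  cat(sprintf(
    "<disagreement> n=%d  mean diff=%.4f (sd %.4f)  t=%.4f  p=%.3g  d=%.4f\n",
    x$n, x$mean_difference, x$sd_difference, x$t, x$p_value, x$cohens_d))
  invisible(x)
}
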