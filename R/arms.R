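#' Treatment arms
#'
#' The fixed, closed set of treatment arms: the 15 unique antipsychotics
#' observed in the development cohort plus the explicit `"NONE"` arm
#' (no antipsychotic medication). `"NONE"` competes with the drugs as an
#' ordinary arm throughout scoring, ranking and evaluation.
#'
#' @return Character vector of 16 arm names; antipsychotics in lexicographic
#'   order followed by `"NONE"`.
#' @export
#' @examples
#' treatment_arms()
treatment_arms <- function() {
  c(
    "aripiprazole", "asenapine", "chlorpromazine", "clozapine",
    "fluphenazine", "haloperidol", "iloperidone", "lurasidone",
    "olanzapine", "paliperidone", "perphenazine", "prochlorperazine",
    "risperidone", "thiothixene", "ziprasidone",
    "NONE"
  )
}

#' @rdname treatment_arms
#' @export
antipsychotic_arms <- function() setdiff(treatment_arms(), "NONE")
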