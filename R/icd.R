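# ICD handling for the schizophrenia-spectrum cohort (ICD-9 295.x and
# ICD-10 F2x). Source systems sometimes store several codes in one
# comma-separated field; only the first is analysed.

# 295.x subtype digit -> ICD-10 target. Disorganised-type handling groups
# 295.1x and 295.2x together under F20.1.
.icd9_295_map <- c(
  "0" = "F20.89", # simple type
  "1" = "F20.1",  # disorganised
  "2" = "F20.1",  # grouped with disorganised
  "3" = "F20.0",  # paranoid
  "4" = "F20.81", # schizophreniform
  "5" = "F21",    # latent / schizotypal
  "6" = "F20.5",  # residual
  "7" = "F25.9",  # schizoaffective
  "8" = "F20.89", # other specified
  "9" = "F20.9"   # unspecified
)

#' Keep the first code of a comma-separated ICD field
#'
#' @param raw Character vector of raw ICD fields, possibly comma-separated.
#' @return Character vector: the substring before the first comma,
#'   whitespace-trimmed.
#' @export
#' @examples
#' first_code("295.30,296.20")
#' first_code(" F25.9 , F32.9")
first_code <- function(raw) {
  if (length(raw) == 0L) {
    srx_abort("srx_empty_field_error", "ICD field is empty")
  }
  out <- trimws(vapply(strsplit(as.character(raw), ",", fixed = TRUE),
                       function(p) if (length(p)) p[[1L]] else "",
                       character(1)))
  if (any(is.na(raw)) || any(!nzchar(out))) {
    srx_abort("srx_empty_field_error", "blank ICD field")
  }
  out
}

#' Map ICD-9 schizophrenia-spectrum codes to ICD-10
#'
#' ICD-10 `F2x` codes pass through unchanged, so the mapping is idempotent.
#' ICD-9 `295.x` codes are mapped by subtype digit (e.g. paranoid
#' schizophrenia `295.3x` to `F20.0`, schizoaffective `295.7x` to `F25.9`).
#' A bare `"295"` maps to `F20.9` (unspecified).
#'
#' @param code Character vector of single ICD-9 or ICD-10 codes (apply
#'   [first_code()] beforehand if the field may hold several).
#' @return Character vector of ICD-10 `F2x` codes.
#' @export
#' @examples
#' map_icd9_to_icd10(c("295.70", "295.3", "F20.0"))
map_icd9_to_icd10 <- function(code) {
  code <- trimws(as.character(code))
  out <- character(length(code))
  is_icd10 <- grepl("^F2", code)
  out[is_icd10] <- code[is_icd10]
  todo <- which(!is_icd10)
  for (i in todo) {
    x <- code[i]
    if (identical(x, "295")) {
      out[i] <- "F20.9"
    } else if (grepl("^295\\.[0-9]", x)) {
      digit <- substr(sub("^295\\.", "", x), 1L, 1L)
      out[i] <- .icd9_295_map[[digit]]
    } else {
      srx_abort(
        "srx_unknown_code_error",
        sprintf("ICD code '%s' is outside the schizophrenia-spectrum mapping table", x),
        code = x
      )
    }
  }
  out
}
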