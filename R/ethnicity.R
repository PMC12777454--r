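# Ethnicity labels arrive in source-specific dialects (fine-grained,
# upper-case strings). They are consolidated into four retained analysis
# categories; small groups are excluded. The dialect table ships as an
# editable CSV resource so other source systems can be supported by
# swapping the file.

.retained_ethnicities <- c("White", "Black/African American",
                           "Hispanic/Latino", "Asian")

#' Ethnicity categories retained after consolidation
#' @return Character vector of the four retained categories.
#' @export
retained_ethnicities <- function() .retained_ethnicities

#' Default ethnicity dialect table
#'
#' Maps upper-case source labels to a retained category or the sentinel
#' `"EXCLUDE"` (Unknown/Declined/Other, American Indian/Alaska Native,
#' Native Hawaiian/Pacific Islander, Multiracial).
#'
#' @param path Optional path to a replacement dialect CSV with columns
#'   `source` and `category`.
#' @return Tibble with columns `source`, `category`.
#' @export
default_ethnicity_dialect <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ethnicity_dialect.csv",
                                package = "schizrec", mustWork = TRUE)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  ok <- tab$category %in% c(.retained_ethnicities, "EXCLUDE")
  if (!all(ok)) {
    srx_abort("srx_unknown_label_error",
              paste("dialect table maps to unknown categories:",
                    paste(unique(tab$category[!ok]), collapse = ", ")))
  }
  tab
}

#' Consolidate source ethnicity labels
#'
#' @param raw Character vector of source-dialect labels (matched
#'   case-insensitively after trimming).
#' @param dialect Dialect table as from [default_ethnicity_dialect()].
#' @return Character vector: one of the four retained categories or
#'   `"EXCLUDE"`.
#' @export
#' @examples
#' consolidate_ethnicity(c("WHITE - RUSSIAN", "MULTIRACIAL"))
consolidate_ethnicity <- function(raw, dialect = default_ethnicity_dialect()) {
  key <- toupper(trimws(as.character(raw)))
  idx <- match(key, toupper(trimws(dialect$source)))
  if (anyNA(idx)) {
    bad <- unique(raw[is.na(idx)])
    srx_abort("srx_unknown_label_error",
              sprintf("ethnicity label(s) not in dialect table: %s",
                      paste(bad, collapse = ", ")),
              labels = bad)
  }
  dialect$category[idx]
}
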