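# Train-fitted feature preprocessing shared by the encoded similarity
# methods: one-hot encoding of categorical columns (levels recorded on the
# training fold; unseen or missing levels encode as an all-zero block) and
# standardisation of numeric columns (training mean/sd; missing values map
# to 0 after scaling, i.e. the training mean).

#' Fit the encoded feature space on a training fold
#'
#' @param features Tibble of training consultation/instance feature rows
#'   with the columns of [feature_schema()].
#' @param fitted_on Provenance tag for the training fold.
#' @return An object of class `srx_feature_space`.
#' @export
fit_feature_space <- function(features, fitted_on = "training") {
  assert_nonempty_df(features, "feature table")
  sch <- feature_schema()
  levels <- lapply(sch$categorical, function(cn) {
    sort(unique(as.character(features[[cn]][!is.na(features[[cn]])])))
  })
  names(levels) <- sch$categorical
  center <- vapply(sch$numeric, function(cn) {
    m <- mean(features[[cn]], na.rm = TRUE)
    if (is.nan(m)) 0 else m
  }, numeric(1))
  scale <- vapply(sch$numeric, function(cn) {
    s <- stats::sd(features[[cn]], na.rm = TRUE)
    if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  structure(list(levels = levels, center = center, scale = scale,
                 fitted_on = fitted_on),
            class = "srx_feature_space")
}

#' Encode feature rows with a fitted feature space
#'
#' A pure function of the fitted state: transforming the same rows twice
#' yields identical matrices, and no statistic is updated from the rows
#' being transformed.
#'
#' @param fs An `srx_feature_space`.
#' @param features Tibble of feature rows (training or test).
#' @return Numeric matrix, rows aligned with `features`.
#' @export
transform_features <- function(fs, features) {
  if (!inherits(fs, "srx_feature_space")) {
    srx_abort("srx_not_fitted_error", "fs must come from fit_feature_space()")
  }
  n <- nrow(features)
  blocks <- list()
  for (cn in names(fs$levels)) {
    lev <- fs$levels[[cn]]
    if (length(lev) == 0) next
    x <- as.character(features[[cn]])
    m <- matrix(0, n, length(lev),
                dimnames = list(NULL, paste0(cn, "=", lev)))
    hit <- match(x, lev)
    ok <- which(!is.na(hit))
    m[cbind(ok, hit[ok])] <- 1
    blocks[[cn]] <- m
  }
  num <- matrix(0, n, length(fs$center),
                dimnames = list(NULL, names(fs$center)))
  for (j in seq_along(fs$center)) {
    cn <- names(fs$center)[j]
    z <- (features[[cn]] - fs$center[j]) / fs$scale[j]
    z[is.na(z)] <- 0
    num[, j] <- z
  }
  do.call(cbind, c(blocks, list(num)))
}
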