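# Classed conditions so callers can distinguish failure modes programmatically.
# Every error carries class c(<specific>, "schizrec_error", "error", "condition").

srx_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "schizrec_error")))
}

srx_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "schizrec_warning")))
}

# shared argument checks ------------------------------------------------------

assert_nonempty_df <- function(x, what = "training set") {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    srx_abort("srx_empty_training_error", paste0(what, " is empty"))
  }
  invisible(x)
}
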