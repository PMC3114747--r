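# Internal validation helpers. Validation failures signal a condition of class
# "subcloneCNA_validation" so the command-line wrapper can map them to a
# distinct exit code.

fail_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("subcloneCNA_validation", "error")))
}

check_that <- function(ok, msg) {
  if (!isTRUE(ok)) fail_validation(msg)
  invisible(TRUE)
}

# Seed handling: every stochastic entry point takes `seed`; NULL draws from the
# session RNG stream so callers can run many operations under one set.seed().
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
               "`seed` must be a single finite number or NULL")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}
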