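# Internal condition helpers: every user-facing failure is a classed condition
# so callers (and tests) can branch on the failure kind, not on message text.

ne_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "nescore_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_format     <- function(msg) ne_stop(msg, "nescore_format_error")
stop_validation <- function(msg) ne_stop(msg, "nescore_validation_error")
stop_overlap    <- function(msg) ne_stop(msg, "nescore_overlap_error")
stop_degenerate <- function(msg) ne_stop(msg, "nescore_degenerate_error")

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("'%s' must be a single finite number", name))
  }
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x != as.integer(x) || x < min) {
    stop_validation(sprintf("'%s' must be an integer >= %d", name, min))
  }
}

# Pearson correlation p-value via the exact t transform (n - 2 df), two-sided.
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n >= 3
  tstat <- r[ok] * sqrt((n[ok] - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n[ok] - 2)
  pmin(p, 1)
}
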