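# Internal helpers shared across modules.

# Case-fold identifiers: gene symbols in GMT files and expression matrices
# routinely disagree in case, so all matching is done on upper-cased,
# whitespace-trimmed ids.
fold_id <- function(x) toupper(trimws(x))

# Stop with a plain (non-call) message; all user-facing errors go through this.
estop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    estop("%s contains NA/NaN/Inf values", what)
  }
  invisible(TRUE)
}

# z-score a vector; errors on zero variance when required.
zscore <- function(x, what = "values", allow_constant = FALSE) {
  s <- stats::sd(x)
  if (s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    estop("%s have zero variance; cannot z-score", what)
  }
  (x - mean(x)) / s
}

# Deterministic descending order with ties broken by case-folded id.
order_desc_by_value <- function(values, ids) {
  order(-values, fold_id(ids), method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
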