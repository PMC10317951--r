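abort_domain <- function(msg) abort(msg, class = "neffbiome_domain_error")
abort_config <- function(msg) abort(msg, class = "neffbiome_config_error")

# scalar finite-number check used by the arithmetic layer (all ops vectorise)
check_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_domain(sprintf("`%s` must be finite and numeric", name))
  }
  invisible(x)
}

# run `expr` under `seed` when supplied, leaving the caller's RNG untouched
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# tiny order-insensitive hash of a configuration, stamped into file headers
config_hash <- function(x) {
  txt <- paste(deparse(x[order(names(x))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 251 + 1)) %% .Machine$integer.max)
}

sem <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}
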