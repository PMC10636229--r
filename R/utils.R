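#' @keywords internal
"_PACKAGE"

# Structured one-line stage logging. Suppressed with options(gxewas.quiet = TRUE).
gxewas_log <- function(stage, ...) {
  if (isTRUE(getOption("gxewas.quiet", FALSE))) return(invisible(NULL))
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  invisible(NULL)
}

# FNV-1a 32-bit hash of a config-like object, for run provenance in result files.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Deterministic per-study seed substreams from one global seed.
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
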