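#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit string hash (FNV-style), used to key per-stage and
# per-set random substreams off a single user-facing seed.
string_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 2166136261 %% 2147480009
  for (c in codes) h <- (h * 31 + c) %% 2147480009
  as.integer(h)
}

# Expand a global seed into a reproducible substream seed for a named stage.
# Keeps every derived seed a valid 32-bit R integer.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + string_hash(stage)) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
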