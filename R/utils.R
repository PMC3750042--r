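# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

.abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "concordis_error")))
}

abort_config <- function(...) .abort(paste0(...), "concordis_config_error")
abort_domain <- function(...) .abort(paste0(...), "concordis_domain_error")
abort_format <- function(...) .abort(paste0(...), "concordis_format_error")
abort_compute <- function(...) .abort(paste0(...), "concordis_compute_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Sub-seeds for the component generators: fixed offsets from the config
# seed keep each component's stream independent of call order, and the
# modulus keeps derived seeds well inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e8) + offset)
}

# Small stable offset from a character id, for per-dataset streams.
.id_offset <- function(id) {
  as.integer(sum(utf8ToInt(id)) %% 1000L)
}

# Deterministic checksum of a character vector (polynomial rolling hash,
# modulus 2^31 - 1); used to stamp pipeline manifests.
.text_hash <- function(lines) {
  b <- utf8ToInt(paste(lines, collapse = "\n"))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%d", h)
}

# sample() treats a length-1 numeric pool as 1:x; this does not.
.resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    abort_config(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

.check_prob <- function(x, name, open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) abort_config(sprintf("'%s' must be a probability in %s", name,
                                if (open) "(0, 1)" else "[0, 1]"))
  as.numeric(x)
}

.check_pos <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    abort_config(sprintf("'%s' must be a single positive number", name))
  }
  as.numeric(x)
}
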