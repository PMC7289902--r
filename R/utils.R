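# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is_count(seed)) stopf("`seed` must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-module substream from one user-facing seed, so that adding a
# generator to one module never perturbs the draws of another. Kept below
# 2^31 because R seeds are 32-bit integers.
module_seed <- function(seed, module) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + sum(utf8ToInt(module))) %% 2147483647
}

assert_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stopf("`%s` must be a data.frame", what)
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stopf("`%s` lacks required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}
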