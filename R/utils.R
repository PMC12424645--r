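# Internal helpers.

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state. A NULL seed leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Abeta coordinates of a peptide of length `len` starting at `start`,
# skipping the nonexistent position 0.
abetaCoords <- function(start, len) {
  if (is.na(start)) return(seq_len(len))
  pos <- start + seq_len(len) - 1L
  if (start < 0L) pos[pos >= 0L] <- pos[pos >= 0L] + 1L
  as.integer(pos)
}

# Write a list to JSON with stable formatting (used by the pipeline so
# identical inputs give byte-identical outputs).
writeStableJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
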