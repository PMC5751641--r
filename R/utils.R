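#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fan a run-level seed out to per-stage seeds; keeps every stage's stream
# independent while the whole run is reproducible from one integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + offs) %% 2147483647L)
}

numeric_id <- function(ids) as.integer(sub("^[A-Za-z*]+", "", ids))

# "T3"-style id sequences; safe for n = 0 (paste0 recycles zero-length
# arguments to "" since R 4.0.1, which would fabricate a bare prefix).
id_seq <- function(prefix, n, offset = 0L) {
  if (n < 1L) return(character(0))
  paste0(prefix, offset + seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
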