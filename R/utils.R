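# Internal helpers: named RNG sub-streams and a small config hash.

# Deterministic 32-bit sub-seed for a named stream, derived from the master
# seed.  Keeps each stochastic sub-process (onset, growth, symptomatic,
# attendance, sensitivity) on its own reproducible stream so that screening
# overlays reuse identical natural histories (common random numbers).
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 17
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483629 + 1)
}

# Evaluate expr with the RNG seeded from a named stream, restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# FNV-1a hash of a configuration (over its deparsed form), printed as hex;
# used to stamp output artifacts so a run is reconstructable.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Write a data.frame as CSV with provenance header comments.
write_csv_with_header <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", format(seed)), con)
  if (!is.null(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
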