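# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Package-level logging: quiet by default so simulation loops stay readable;
# set options(conjfdr.verbose = TRUE) to see filter/harmonization counts.
cj_log <- function(...) {
  if (isTRUE(getOption("conjfdr.verbose", FALSE))) message("conjfdr: ", ...)
  invisible(NULL)
}

# Reverse (upper-tail) 2D cumulative sum: S[i, j] = sum(M[i:G, j:G]).
rev_cumsum2 <- function(M) {
  M <- apply(M, 2L, function(x) rev(cumsum(rev(x))))
  t(apply(M, 1L, function(x) rev(cumsum(rev(x)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
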