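#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' package randomness never disturbs user-level reproducibility.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Deterministic per-unit substream seed derived from a master seed
#' @keywords internal
sub_seed <- function(seed, index, salt = 0L) {
  ((as.double(seed) %% 2147483647) + 104729 * as.double(index) +
     7919 * as.double(salt)) %% 2147483647
}
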