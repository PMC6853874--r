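#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# `seed = NULL` means: use (and advance) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (FNV-1a variant), used to derive independent
# per-population seed streams from one top-level seed.  Adding a population
# to a scenario never perturbs the draws of the others.
hash31 <- function(label) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(enc2utf8(as.character(label)))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Derive a reproducible sub-seed from a top-level seed and a label
#'
#' Population-specific random streams are derived by stable hashing of the
#' population label combined with the top-level seed, so that the draws for
#' one population do not depend on which other populations are present.
#'
#' @param seed integer top-level seed.
#' @param label character scalar (e.g. a population label).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((hash31(label) + (as.numeric(seed) %% 2147483647) * 48271) %%
               2147483647)
}

stop_scalar_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", what),
         call. = FALSE)
  }
  invisible(x)
}
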