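#' Derive a child seed from a top-level seed and a stream label
#'
#' All generators in the package draw from streams derived from a single
#' top-level seed. Each generator owns a stable text label, so adding or
#' reordering generators never perturbs the streams of the others.
#'
#' @param seed integer top-level seed.
#' @param label character stream label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "trajectories")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
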