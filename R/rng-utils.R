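# Deterministic seed derivation for independent substreams.
#
# R has no native splittable RNG, so per-entity substreams are derived by
# folding integer ids into a root seed with repeated multiplicative-
# congruential steps (Park-Miller constants).  Two properties matter here:
# (a) the derived seed depends only on (root, ids...), so adding neurons to a
# population never perturbs the spike trains of existing (neuron, trial)
# pairs; (b) results stay below 2^31 so they are valid R integer seeds.

.MIX_M <- 2147483647  # 2^31 - 1
.MIX_A <- 48271

#' Derive a substream seed from a root seed and integer ids
#'
#' @param root root seed (integer).
#' @param ... integer ids identifying the substream (e.g. neuron index,
#'   trial index). Order matters.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @keywords internal
#' @noRd
mix_seed <- function(root, ...) {
  ids <- c(root, ...)
  h <- 1
  for (x in ids) {
    x <- as.numeric(x) %% (.MIX_M - 1)
    h <- ((h + x + 1) * .MIX_A) %% .MIX_M
    # one extra LCG step improves diffusion of small consecutive ids
    h <- (h * .MIX_A) %% .MIX_M
  }
  as.integer(h %% (.MIX_M - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not disturb the
#' caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
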