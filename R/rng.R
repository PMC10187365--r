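#' Derive a deterministic sub-stream seed from a master seed
#'
#' Scenario runs draw frailty, protection and epidemic randomness from
#' separate streams so that changing one distribution does not perturb the
#' draws of the others (useful for variance reduction when comparing
#' scenarios).  Each stream seed is a deterministic hash of the master seed
#' and a purpose label, kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param purpose character label, e.g. `"frailty"`, `"epidemic:3"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "frailty")
#' substream_seed(1L, "protection")
substream_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- (abs(seed) %% m)
  for (code in utf8ToInt(purpose)) {
    # doubles hold integers exactly up to 2^53, so (h * 69069 + code) is exact
    h <- ((h %% 65011) * 69069 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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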