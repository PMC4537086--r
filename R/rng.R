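# Counter-based substream seeding.
#
# A single master seed plus a (counter, stream) pair is mixed into a fresh
# seed for R's generator by two rounds of a modular LCG, done in double
# precision where all intermediates stay below 2^53 and are therefore
# exact. Replicate i then has the same substream no matter how many
# replicates are requested, and the mutation stream (stream 1) is
# independent of the genealogy stream (stream 0).

.mix_modulus <- 2147483629  # largest prime below 2^31

#' Derive a substream seed from a master seed
#'
#' Deterministically mixes a master seed with a replicate counter and a
#' stream identifier, so that replicate `counter` is reproducible
#' independently of how many replicates are drawn, and different streams
#' (genealogy vs mutation) are decoupled.
#'
#' @param seed Integer master seed.
#' @param counter Non-negative integer replicate counter.
#' @param stream Small integer stream identifier (0 = genealogy,
#'   1 = mutations, 2 = sweep grid points).
#' @return A single integer seed suitable for [set.seed()].
#' @export
#' @examples
#' mix_seed(42, 0)
#' mix_seed(42, 0, stream = 1)
mix_seed <- function(seed, counter, stream = 0L) {
  x <- abs(as.numeric(seed)) %% .mix_modulus
  x <- (x * 1000003 + as.numeric(counter) * 2654435 + as.numeric(stream) + 12345) %% .mix_modulus
  x <- (x * 69069 + 1) %% .mix_modulus
  as.integer(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so library code does not
# perturb user-level randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Fold an ms-style "-seeds a b c" triple into one master seed (documented
# hash: sequential LCG absorption of the three values).
fold_ms_seeds <- function(seeds) {
  x <- 0
  for (s in as.numeric(seeds)) {
    x <- (x * 1000003 + abs(s) %% .mix_modulus) %% .mix_modulus
  }
  as.integer(x)
}
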