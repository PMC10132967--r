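#' Deterministic random streams
#'
#' The simulator and the empirical null draw randomness through small
#' self-contained RNG streams so that results are bit-reproducible given a
#' seed and independent of the caller's global RNG state. Sub-seeds for
#' labelled units (patients, samples, amplicons) are derived by stable
#' string hashing so generation is order-independent.
#'
#' @name rng
#' @keywords internal
NULL

make_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed %% .Machine$integer.max))
    get(".Random.seed", envir = globalenv())
  })
  e
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

rng_eval <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng_state(old))
  assign(".Random.seed", rng$state, envir = globalenv())
  out <- expr()
  rng$state <- get(".Random.seed", envir = globalenv())
  out
}

sample_int <- function(rng, n, k, replace = FALSE) {
  rng_eval(rng, function() sample.int(n, k, replace = replace))
}

runif_rng <- function(rng, n, min = 0, max = 1) {
  rng_eval(rng, function() stats::runif(n, min, max))
}

rlnorm_rng <- function(rng, n, meanlog, sdlog) {
  rng_eval(rng, function() stats::rlnorm(n, meanlog, sdlog))
}

# order-independent 31-bit hash of a label, for sub-seed derivation
stable_hash <- function(label) {
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 1000003
  as.integer(h)
}

sub_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + stable_hash(label)) %% 2147483647)
}
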