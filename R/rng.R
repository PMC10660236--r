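#' Deterministic per-stream random number generation
#'
#' Every random decision in the selection engine is drawn from an isolated
#' stream created by [coach_rng()], so that a (global seed, participant,
#' week) triple always yields the same message regardless of the order in
#' which participants or weeks are processed, and regardless of the caller's
#' own RNG state.
#'
#' @name rng
#' @keywords internal
NULL

# 32-bit FNV-1a over the UTF-8 bytes of a string, using doubles as 32-bit
# accumulators (products are split so intermediates stay below 2^53).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive the RNG seed for one participant-week
#'
#' Hashes \code{"<global_seed>:<participant_id>:<week_index>"} with 32-bit
#' FNV-1a and folds the result into \code{[1, 2^31 - 1]}. Reproducibility is
#' therefore independent of cohort iteration order.
#'
#' @param global_seed Integer seed for the whole run.
#' @param participant_id Participant identifier string.
#' @param week_index Program week (1-based).
#' @return An integer seed suitable for [coach_rng()].
#' @export
derive_seed <- function(global_seed, participant_id, week_index) {
  key <- paste(global_seed, participant_id, week_index, sep = ":")
  as.integer(fnv1a32(key) %% 2147483646) + 1L
}

#' Create an isolated uniform RNG stream
#'
#' Returns a stream object whose \code{$unif(n)} method draws \code{n}
#' Uniform(0,1) deviates from a private Mersenne-Twister state seeded with
#' \code{seed}. The caller's \code{.Random.seed} is saved and restored around
#' every draw, so engine randomness never perturbs user code.
#'
#' @param seed Integer seed.
#' @return A list with elements \code{seed} and function \code{unif(n)}.
#' @export
coach_rng <- function(seed) {
  seed <- as.integer(seed)
  state <- NULL
  unif <- function(n = 1L) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
    if (is.null(state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", state, envir = genv)
    }
    u <- stats::runif(n)
    state <<- get(".Random.seed", envir = genv, inherits = FALSE)
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else {
      rm(".Random.seed", envir = genv)
    }
    u
  }
  list(seed = seed, unif = unif)
}

# Run expr with a temporary seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Pick index from non-negative weights using one uniform draw.
sample_weighted <- function(weights, u) {
  total <- sum(weights)
  stopifnot(total > 0)
  cum <- cumsum(weights) / total
  which(u <= cum + 1e-15)[1L]
}
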