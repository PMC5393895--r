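# Counter-based random streams.
#
# Synaptic release draws must not depend on how cells are split across
# workers, nor on how many draws other synapses have consumed.  A stateful
# generator cannot provide that, so every draw is a pure function of
# (seed, stream id, counter): a murmur3-style avalanche hash evaluated on
# demand.  All 32-bit arithmetic is emulated on doubles (exact below 2^53),
# vectorised over ids/counters.

TWO32 <- 4294967296

u32_xor <- function(a, b) {
  al <- a %% 65536L; ah <- (a - al) / 65536
  bl <- b %% 65536L; bh <- (b - bl) / 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

u32_mul <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  (((ah * b) %% 65536) * 65536 + al * b) %% TWO32
}

u32_rotl <- function(a, r) {
  ((a * 2^r) %% TWO32) + (a %/% 2^(32 - r))
}

# murmur3 32-bit finalizer: full avalanche on one word
u32_fmix <- function(h) {
  h <- u32_xor(h, h %/% 65536)
  h <- u32_mul(h, 2246822507)      # 0x85ebca6b
  h <- u32_xor(h, h %/% 8192)
  h <- u32_mul(h, 3266489909)      # 0xc2b2ae35
  u32_xor(h, h %/% 65536)
}

mix_word <- function(h, w) {
  w <- u32_mul(w %% TWO32, 3432918353)   # 0xcc9e2d51
  w <- u32_rotl(w, 15)
  w <- u32_mul(w, 461845907)             # 0x1b873593
  h <- u32_xor(h, w)
  h <- u32_rotl(h, 13)
  (u32_mul(h, 5) + 3864292196) %% TWO32  # 0xe6546b64
}

#' Counter-based uniform deviates
#'
#' Returns deviates in (0, 1) that are a pure function of `(seed, id, ctr)`.
#' The same triple always yields the same value, and distinct triples yield
#' independent-quality values, so consumers (one stream per synapse, counter =
#' presynaptic event index) get reproducible draws regardless of evaluation
#' order or process partitioning.
#'
#' @param seed integer scalar master seed.
#' @param id integer vector, stream identifier (e.g. synapse id).
#' @param ctr integer vector, event counter within the stream.
#' @return numeric vector of uniforms in (0, 1), recycled to the common length
#'   of `id` and `ctr`.
#' @examples
#' counter_runif(1L, 1:5, 0L)
#' @export
counter_runif <- function(seed, id, ctr) {
  n <- max(length(id), length(ctr))
  id <- rep_len(as.numeric(id), n) %% TWO32
  ctr <- rep_len(as.numeric(ctr), n) %% TWO32
  h <- rep_len(as.numeric(seed) %% TWO32, n)
  h <- mix_word(h, id)
  h <- mix_word(h, ctr)
  h <- u32_xor(h, 8)   # length pad, as in murmur3
  (u32_fmix(h) + 0.5) / TWO32
}

#' Counter-based Bernoulli draws
#'
#' One Bernoulli trial per element, success probability `p`, using
#' [counter_runif()] streams.
#'
#' @inheritParams counter_runif
#' @param p numeric vector of success probabilities in `[0, 1]`.
#' @return logical vector.
#' @export
counter_bernoulli <- function(seed, id, ctr, p) {
  counter_runif(seed, id, ctr) < p
}

# FNV-1a 32-bit over a character string; change-detection hash for configs.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- u32_xor(h, b)
    h <- u32_mul(h, 16777619)
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
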