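#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Leaky rectified linear unit
#'
#' @param x numeric vector.
#' @param slope negative-side slope (default 0.2).
#' @return `x` where positive, `slope * x` elsewhere.
#' @export
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

#' Numerically stable softmax
#'
#' @param x numeric vector of scores.
#' @return nonnegative weights summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eatree <- function(msg, class) {
  stop(structure(
    class = c(class, "eatree_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## 32-bit LCG over doubles (exact: products stay below 2^53); used for
## deterministic, RNG-state-free hashing of vocabulary keys.
lcg_next <- function(state) (69069 * state + 1) %% 4294967296

string_hash <- function(key, seed = 0L) {
  codes <- utf8ToInt(key)
  state <- (as.numeric(seed) %% 4294967296)
  for (cd in codes) state <- lcg_next((state + cd) %% 4294967296)
  state
}

#' Deterministic pseudo-random vector for a string key
#'
#' Pure function of `(key, seed)`: does not touch R's RNG stream. Components
#' are approximately uniform on (-1, 1).
#'
#' @param key character scalar.
#' @param d output dimension.
#' @param seed integer seed mixed into the hash.
#' @return numeric vector of length `d`.
#' @export
hash_vector <- function(key, d, seed = 0L) {
  state <- string_hash(key, seed)
  out <- numeric(d)
  for (i in seq_len(d)) {
    state <- lcg_next(state)
    out[i] <- 2 * state / 4294967296 - 1
  }
  out
}
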