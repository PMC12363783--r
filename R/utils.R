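#' @noRd
stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that e.g. atlas generation and permutation draws are
#' decoupled: changing the number of permutations never changes the atlas.
#'
#' @param seed integer root seed.
#' @param ... character/numeric stream labels, combined in order.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
seed_stream <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  cp <- utf8ToInt(key)
  h <- sum(cp * seq_along(cp)) %% 1048573
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h * 97 + 17) %% 2147483647)
}

#' @noRd
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

#' @noRd
upper_tri_pairs <- function(n) {
  # row-major upper triangle: (1,2),(1,3),...,(1,n),(2,3),...
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}
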