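#' Deterministic seed expansion
#'
#' Expands a master seed plus one or more integer stage indices into a
#' derived seed in \code{[1, 2^31 - 2]}. All randomness in the package flows
#' through \code{set.seed(expandSeed(master, ...))} so that a single master
#' seed reproduces every stage of a pipeline run.
#'
#' @param seed integer master seed.
#' @param ... integer stage / realization indices.
#' @return A single integer seed.
#' @examples
#' expandSeed(1, 2, 3)
#' @export
expandSeed <- function(seed, ...) {
  ks <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  m <- 2147483647  # 2^31 - 1 (Mersenne prime)
  s <- 987654321
  for (k in ks) {
    s <- (s * 69069 + abs(k) + 12345) %% m
    s <- (s * 69069 + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}
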