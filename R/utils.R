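#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# km per degree of latitude under the equirectangular approximation
.KM_PER_DEG <- 111.32

#' Derive a reproducible integer sub-seed
#'
#' Deterministic substreams for bootstrap replicates and simulation stages:
#' replicate `r` of a run seeded with `seed` always sees the same RNG state,
#' independent of how many earlier replicates were retained or discarded.
#'
#' @param seed Master seed (non-negative integer).
#' @param stream Stream index (non-negative integer), e.g. replicate number.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  # affine hash mod the Mersenne prime 2^31 - 1; cheap, collision-free for
  # the stream counts used here, and always a valid 32-bit seed
  as.integer((abs(seed) %% 2147483647 * 69621 + stream * 181243 + 7) %% 2147483647)
}

# run code with a temporary RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# stop() with a class so tests can assert on error types
hzc_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "hzclines_error"))
}
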