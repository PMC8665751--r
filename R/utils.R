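#' Round half away from zero
#'
#' Commercial ("half-up") rounding as used in printed precision tables, as
#' opposed to [base::round()]'s round-half-even.  A relative guard of 1e-9
#' absorbs binary representation error just below a .5 boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25, 1.55165), c(1, 1, 1))
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + abs(x) * s * 1e-9) / s
}

# Deterministic 31-base polynomial string hash modulo 2^31 - 1.  Used to
# derive independent substream seeds from a master seed so that the values
# generated for one cell do not move when another cell is added.
stable_hash <- function(...) {
  s <- paste(..., sep = "\r")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Substream seed: combine master seed and component hash, keep < 2^31.
substream_seed <- function(seed, ...) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(...)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == floor(x)
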