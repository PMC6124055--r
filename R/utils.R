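# internal helpers shared across modules

# round half away from zero (presentation rounding for integer percentages)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# percentage display of a proportion, rounded half away from zero
as_pct <- function(p) round_half_up(100 * p)

#' Derive a reproducible sub-stream seed from a root seed
#'
#' A single root seed feeds several named random sub-streams (dates,
#' outcomes, cascade fields, error injections) so that adding a stream to a
#' generator never perturbs draws in the others. The mapping is a fixed
#' integer hash of the stream name mixed with the root seed; the result is
#' always a valid positive 32-bit integer seed.
#'
#' @param seed integer root seed.
#' @param stream character scalar naming the sub-stream.
#' @return a positive integer seed.
#' @export
sub_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + h * 8191 + 1
  as.integer(s %% 2147483646 + 1)
}

stop_domain <- function(...) stop(..., call. = FALSE)
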