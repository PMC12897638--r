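#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds: each generator stage draws from its own
# stream so stages can be regenerated independently under one master seed.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 1024L
  as.integer((as.numeric(seed) %% 2147483647 + 1000003 * (h + 1)) %% 2147483646) + 1L
}

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

# round-half-up (printed summary tables carry 2 decimals; base round()
# applies round-half-even which disagrees on .x5 boundaries)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Beta-binomial sampler with intra-class correlation phi in (0, 1):
# Var(X) = m p (1 - p) (1 + (m - 1) phi).
rbetabinom <- function(n, size, prob, phi) {
  stopifnot(phi > 0, phi < 1)
  a <- prob * (1 - phi) / phi
  b <- (1 - prob) * (1 - phi) / phi
  q <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
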