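# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hrsc <- function(...) stop(..., call. = FALSE)

# Evaluate `code` under a local RNG seed without touching the caller's stream;
# seed = NULL means "use the current stream" so composite pipelines can seed once.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Ordinary least-squares line y = a + b x with the n-2 residual standard error.
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop_hrsc("cannot fit a line: no spread in x")
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  r <- y - (a + b * x)
  list(a = a, b = b, resid = r,
       sigma = sqrt(sum(r^2) / max(n - 2L, 1L)))
}

# Truncated-normal draws by vectorised rejection; open interval (lo, hi).
# mean, sd, lo and hi may be scalars or length-k vectors.
draw_trunc <- function(k, mean, sd, lo = -Inf, hi = Inf) {
  mean <- rep_len(mean, k); sd <- rep_len(sd, k)
  lo <- rep_len(lo, k); hi <- rep_len(hi, k)
  x <- stats::rnorm(k, mean, sd)
  bad <- which(x <= lo | x >= hi)
  it <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= lo[bad] | x[bad] >= hi[bad]]
    it <- it + 1L
    if (it > 10000L) stop_hrsc("truncated draw failed to converge; check bounds")
  }
  x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
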