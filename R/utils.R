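# internal helpers

# run expr under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# FFT-based analytic signal; zero-pads to a 2-3-5-smooth length for speed
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("signal too short for analytic-signal computation")
  nf <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nf - n)))
  h <- numeric(nf)
  h[1L] <- 1
  if (nf %% 2L == 0L) {
    h[nf / 2 + 1] <- 1
    h[2:(nf / 2)] <- 2
  } else {
    h[2:((nf + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / nf
  a[seq_len(n)]
}

# unwrap phase angles (accumulate past 2*pi instead of resetting)
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

stop_if_not_scalar_prob <- function(x, name = "plv") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a single value in [0, 1]")
}
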