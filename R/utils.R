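## Internal numeric helpers shared by the signal-processing and simulation code.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Deterministic 31-bit sub-seed from a base seed and a stream of integer keys.
## Keeps every per-participant / per-session RNG stream reproducible from one
## pipeline seed without correlated streams.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in keys) {
    h <- (h * 69069 + as.double(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Truncated normal via rejection; bounds inclusive. Falls back to clamping
## when the acceptance region is tiny (sd = 0 or extreme means).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(clamp(rep(mean, n), lo, hi))
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:50) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (!length(need)) break
  }
  if (length(need)) out[need] <- clamp(stats::rnorm(length(need), mean, sd), lo, hi)
  out
}

## Centred moving average with window w samples (odd enforced); edges use the
## available partial window so output length matches input.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Zero-phase band-pass via FFT bin masking. Adequate for feature extraction
## on short, roughly stationary test recordings; not a general-purpose filter.
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  if (n < 4L) return(x - mean(x))
  xc <- x - mean(x)
  X <- stats::fft(xc)
  freq <- (seq_len(n) - 1L) / n * fs
  freq <- pmin(freq, fs - freq)  # two-sided spectrum, mirrored frequencies
  keep <- freq >= f_lo & freq <= f_hi
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

## Local maxima above `min_height`, greedily enforcing a minimum separation
## (larger peaks win). Returns sample indices in increasing order.
find_peaks <- function(x, min_sep = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand])]
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= min_sep)) taken <- c(taken, i)
  }
  sort(taken)
}

## Linear interpolation of a (possibly irregular) stream onto a uniform grid.
resample_uniform <- function(t, y, fs) {
  grid <- seq(min(t), max(t), by = 1 / fs)
  if (is.matrix(y)) {
    apply(y, 2L, function(col) stats::approx(t, col, xout = grid)$y)
  } else {
    stats::approx(t, y, xout = grid)$y
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
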