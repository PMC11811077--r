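# Internal helpers: classed conditions, RNG scoping, FFT primitives.

stop_classed <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "neofba_error")))
}

stop_value   <- function(msg, ...) stop_classed("neofba_value_error", msg, ...)
stop_montage <- function(msg, ...) stop_classed("neofba_montage_error", msg, ...)
stop_parse   <- function(msg, ...) stop_classed("neofba_parse_error", msg, ...)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards so package randomness never perturbs
# user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic derived seeds, kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483587)
}

# Discrete analytic-signal envelope |y + jH{y}| via the FFT.
hilbert_envelope <- function(x) {
  if (length(x) < 2L) return(abs(x))
  envelope_from_fft(fft(x))
}

# Truncate (or pad) an n-point spectrum to m points, keeping frequencies
# below the new Nyquist: the spectral core of Fourier-method resampling.
spectrum_resize <- function(X, m) {
  n <- length(X)
  if (m == n) return(X)
  Y <- complex(length.out = m)
  k <- floor(min(n, m) / 2)
  Y[1:(k + 1L)] <- X[1:(k + 1L)]
  if (k > 0L) Y[(m - k + 1L):m] <- X[(n - k + 1L):n]
  if (min(n, m) %% 2L == 0L && m > n) {
    # split the original Nyquist bin symmetrically when upsampling
    Y[k + 1L] <- X[k + 1L] / 2
    Y[m - k + 1L] <- X[k + 1L] / 2
  }
  Y
}

# Fourier-method resampling of a real signal to `m` samples. Band-limited
# interpolation with an ideal (brick-wall) anti-alias response; exact output
# length by construction.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  Re(fft(spectrum_resize(fft(x), m), inverse = TRUE)) / n
}

# Squared magnitude response |H(e^{jw})|^2 of an IIR filter (b, a) on the
# n-point FFT grid. Memoised: the same response is reused across channels
# and subjects.
.resp_cache <- new.env(parent = emptyenv())

filter_response_sq <- function(b, a, n) {
  key <- paste(n, paste(signif(c(b, NA, a), 12), collapse = ","), sep = "|")
  hit <- .resp_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- 2 * pi * (seq_len(n) - 1L) / n
  z <- exp(complex(imaginary = -w))
  num <- 0; den <- 0; zp <- 1
  for (k in seq_len(max(length(b), length(a)))) {
    if (k <= length(b)) num <- num + b[k] * zp
    if (k <= length(a)) den <- den + a[k] * zp
    zp <- zp * z
  }
  out <- Mod(num / den)^2
  if (length(.resp_cache) > 32L) rm(list = ls(.resp_cache), envir = .resp_cache)
  .resp_cache[[key]] <- out
  out
}

# Zero-phase filtering: applies |H|^2 (the forward-backward magnitude
# response of the filter) in the frequency domain. Exactly zero phase;
# boundary behaviour is circular rather than transient-padded, which for
# the long signals used here is negligible.
zero_phase_filter <- function(x, b, a = 1) {
  n <- length(x)
  Re(fft(fft(x) * filter_response_sq(b, a, n), inverse = TRUE)) / n
}

# Analytic-signal envelope from a precomputed spectrum.
envelope_from_fft <- function(X) {
  n <- length(X)
  h <- numeric(n)
  if (n %% 2L == 0L) { h[c(1L, n / 2L + 1L)] <- 1; h[2:(n / 2L)] <- 2 } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Type-7 quantiles of a pre-sorted vector (avoids quantile() overhead in
# tight per-epoch loops).
quantile7_sorted <- function(xs, probs) {
  n <- length(xs)
  idx <- (n - 1) * probs + 1
  lo <- floor(idx); hi <- ceiling(idx)
  xs[lo] + (idx - lo) * (xs[hi] - xs[lo])
}

# Centred moving average with edge shrinkage (window truncated at borders).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# max/min over every `width`-sample window with hop `hop`, where width is an
# integer multiple of hop: computed from hop-block extrema so the cost is
# linear in the signal length.
block_ranges <- function(x, width, hop) {
  stopifnot(width %% hop == 0L)
  nblk <- length(x) %/% hop
  if (nblk < width %/% hop) return(numeric(0))
  xm <- matrix(x[seq_len(nblk * hop)], nrow = hop)
  rows <- asplit(xm, 1L)
  bmax <- do.call(pmax, rows)
  bmin <- do.call(pmin, rows)
  per <- width %/% hop
  nseg <- nblk - per + 1L
  mx <- bmax[seq_len(nseg)]
  mn <- bmin[seq_len(nseg)]
  if (per > 1L) for (o in 1L:(per - 1L)) {
    mx <- pmax(mx, bmax[seq_len(nseg) + o])
    mn <- pmin(mn, bmin[seq_len(nseg) + o])
  }
  mx - mn
}
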