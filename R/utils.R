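# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL runs as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FFT of `x` zero-padded to length `n_pad` (>= length(x)).
padded_fft <- function(x, n_pad) {
  n <- length(x)
  if (n_pad < n) stop("padded length shorter than the signal")
  stats::fft(c(x, numeric(n_pad - n)))
}

# Padded length realizing a frequency-grid spacing of `resolution` Hz.
# The grid must land exactly on integer frequencies (1 and 4 Hz are
# frequencies of interest), i.e. 1/resolution must be a whole number of
# bins, and sample_rate/resolution a whole number of samples.
resolution_nfft <- function(sample_rate, resolution) {
  n_pad <- sample_rate / resolution
  if (abs(n_pad - round(n_pad)) > 1e-9 ||
      abs(1 / resolution - round(1 / resolution)) > 1e-9)
    stop("resolution must divide the sample rate and 1 Hz exactly ",
         "(the frequency grid must contain the integer frequencies of interest)")
  as.integer(round(n_pad))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
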