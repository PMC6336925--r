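# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# brute-force O(n*m) linear convolution, truncated to length(x)
conv_bruteforce <- function(x, k) {
  n <- length(x)
  m <- length(k)
  out <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, m)
    out[i] <- sum(k[seq_len(jmax)] * x[i - seq_len(jmax) + 1L])
  }
  out
}

# explicit normal-equations OLS
ols_normal_equations <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Butterworth low-pass via analog prototype + bilinear transform, done from
# the textbook formulas (no signal package)
butter_lp_bilinear <- function(order, fc, fs) {
  # prewarped analog cut-off
  wc <- 2 * fs * tan(pi * fc / fs)
  k <- seq_len(order)
  p_analog <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain_analog <- wc^order
  # bilinear transform s = 2 fs (z-1)/(z+1)
  p_d <- (1 + p_analog / (2 * fs)) / (1 - p_analog / (2 * fs))
  z_d <- rep(-1 + 0i, order)
  gain_d <- Re(gain_analog * prod(1 / (2 * fs - p_analog)) * (2 * fs)^0)
  # expand polynomials
  polyfromroots <- function(r) {
    c <- 1 + 0i
    for (ri in r) c <- c(c, 0) - ri * c(0, c)
    c
  }
  b <- Re(gain_d * polyfromroots(z_d))
  a <- Re(polyfromroots(p_d))
  list(b = b, a = a)
}

# direct-DFT modified periodogram of one segment (Hamming window), one-sided
periodogram_direct <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xs <- x * w
  nf <- n %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / n
  pxx <- numeric(nf)
  t_idx <- 0:(n - 1)
  for (k in seq_len(nf)) {
    Xk <- sum(xs * exp(-2i * pi * (k - 1) * t_idx / n))
    pxx[k] <- Mod(Xk)^2 / (fs * sum(w^2))
  }
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(freq = freqs, psd = pxx * dbl)
}

# scipy's Shapiro-Wilk as an independent implementation (pre-installed
# python on PATH)
shapiro_scipy <- function(values) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(format(values, digits = 17), f)
  code <- paste0(
    "import sys, numpy as np\n",
    "from scipy import stats\n",
    "x = np.loadtxt(sys.argv[1])\n",
    "w, p = stats.shapiro(x)\n",
    "print(repr(float(w))); print(repr(float(p)))")
  out <- system2("python", c("-c", shQuote(code), f), stdout = TRUE)
  list(W = as.numeric(out[1]), p = as.numeric(out[2]))
}

# tiny fast study configuration for pipeline tests
small_protocol <- function() protocol_spec(n_blocks = 4, task_dur = 20,
                                           rest_dur = 20, lead_in = 20)
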