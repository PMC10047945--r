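# Synthetic signal families used to characterise the estimators: white
# Gaussian noise, 1/f (pink) noise, correlated channel pairs, MIX and
# coupled-MIX processes, and SNR-controlled noise injection.  Every
# generator is a pure function of its arguments including the seed.

with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

#' White Gaussian noise channels
#'
#' Independent standard-normal channels (zero mean, unit SD).
#'
#' @param n_channels number of channels, `>= 1`.
#' @param length samples per channel, `>= 2`.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return `n_channels x length` matrix.
#' @export
gen_wgn <- function(n_channels, length, seed = NULL) {
  n_channels <- as.integer(n_channels); length <- as.integer(length)
  if (n_channels < 1L || length < 2L)
    stop("need n_channels >= 1 and length >= 2")
  with_seed_or_not(seed,
    matrix(rnorm(n_channels * length), n_channels, length, byrow = TRUE))
}

pink_channel <- function(L) {
  # white noise through the classic pole-zero pink approximation
  # (Kasdin-style third-order filter), with a 2000-sample warm-up to clear
  # the filter transient, then z-scored.  The filter tracks 1/f closely
  # over the resolvable band while levelling off at the very lowest
  # frequencies, as physical 1/f sources do.
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(-2.494956002, 2.017265875, -0.522189400)
  warm <- 2000L
  w <- rnorm(L + warm)
  ma <- stats::filter(w, b, method = "convolution", sides = 1)
  ma[is.na(ma)] <- 0
  y <- as.numeric(stats::filter(ma, -a, method = "recursive"))
  y <- y[-seq_len(warm)]
  (y - mean(y)) / sd(y)
}

#' 1/f (pink) noise channels
#'
#' Independent channels whose power spectral density falls as 1/frequency
#' over the resolvable band, generated by passing white noise through the
#' classic third-order pole-zero pink filter and z-scoring to zero mean,
#' unit SD. The filter levels off at the very lowest frequencies, so the
#' channels are long-range correlated without the unbounded low-frequency
#' drift of exact spectral synthesis.
#'
#' @inheritParams gen_wgn
#' @return `n_channels x length` matrix.
#' @export
gen_pink_noise <- function(n_channels, length, seed = NULL) {
  n_channels <- as.integer(n_channels); length <- as.integer(length)
  if (n_channels < 1L) stop("need n_channels >= 1")
  if (length < 64L) stop("length must be >= 64 for spectral synthesis")
  with_seed_or_not(seed, {
    out <- matrix(0, n_channels, length)
    for (k in seq_len(n_channels)) out[k, ] <- pink_channel(length)
    out
  })
}

#' Two channels with a prescribed inter-channel correlation
#'
#' Builds the second channel by linear mixing,
#' `z2 = rho * z1 + sqrt(1 - rho^2) * z1'`, of two independent realisations
#' of the requested noise kind; the mixing preserves the marginal spectrum
#' for both white and 1/f noise and targets the population (not sample)
#' correlation. `rho = 0` returns two independent channels.
#'
#' @param kind `"wgn"` or `"pink"`.
#' @param rho population inter-channel correlation, `-1 < rho < 1`.
#' @param length samples per channel.
#' @param seed integer RNG seed.
#' @return `2 x length` matrix.
#' @export
gen_correlated_pair <- function(kind = c("wgn", "pink"), rho, length,
                                seed = NULL) {
  kind <- match.arg(kind)
  if (abs(rho) >= 1) stop("need -1 < rho < 1")
  length <- as.integer(length)
  with_seed_or_not(seed, {
    draw <- function()
      if (kind == "wgn") rnorm(length) else pink_channel(length)
    z1 <- draw(); z1p <- draw()
    rbind(z1, rho * z1 + sqrt(1 - rho^2) * z1p, deparse.level = 0)
  })
}

mix_channel <- function(p, N, fs) {
  # sinusoid 2*sin(2*pi*t/fs) on t = 0..N-1 with round(N*p) positions,
  # chosen uniformly without replacement, replaced by Uniform(-3, 3) draws
  x <- 2 * sin(2 * pi * (0:(N - 1L)) / fs)
  k <- round(N * p)
  if (k > 0) {
    pos <- sample.int(N, k)
    x[pos] <- runif(k, -3, 3)
  }
  x
}

#' MIX process
#'
#' A MIX(p) realisation: the sinusoid `2*sin(2*pi*t/fs)`, `t = 0..N-1`,
#' with a fraction `p` of sample positions (count `round(N*p)`, chosen
#' uniformly at random without replacement) replaced by Uniform(-3, 3)
#' noise. Complexity increases with `p`.
#'
#' @param p replacement probability in `[0, 1]`.
#' @param length number of samples `N`.
#' @param fs sinusoid period divisor (samples per cycle), default 12.
#' @param seed integer RNG seed.
#' @return `1 x length` matrix.
#' @export
gen_mix <- function(p, length, fs = 12, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  length <- as.integer(length)
  with_seed_or_not(seed, matrix(mix_channel(p, length, fs), 1L))
}

#' Parameters of the two-channel coupled-MIX model
#'
#' @param p0,p1,p2 replacement probabilities of the shared and the two
#'   private MIX components, each in `[0, 1]`.
#' @param C coupling coefficient in `[0, 1]`: weight of the shared
#'   component. `C = 0` gives independent channels, `C = 1` identical ones.
#' @param N data length, `>= fs`.
#' @param fs sinusoid period divisor, default 12.
#' @return a list of class `coupled_mix_params`.
#' @export
coupled_mix_params <- function(p0, p1, p2, C, N, fs = 12) {
  probs <- c(p0 = p0, p1 = p1, p2 = p2, C = C)
  if (any(probs < 0 | probs > 1))
    stop("p0, p1, p2 and C must lie in [0, 1]")
  N <- as.integer(N)
  if (N < fs) stop("N must be at least fs")
  structure(list(p0 = p0, p1 = p1, p2 = p2, C = C, N = N, fs = fs),
            class = "coupled_mix_params")
}

#' Coupled two-channel MIX model
#'
#' Three independent MIX realisations on a common time grid combine into
#' two channels sharing a component:
#' `A = C*MIX(p0) + (1-C)*MIX(p1)`, `B = C*MIX(p0) + (1-C)*MIX(p2)`.
#' The coupling coefficient `C` controls the inter-channel correlation
#' while `p0, p1, p2` control the per-channel complexity.
#'
#' @param params a [coupled_mix_params()] object.
#' @param seed integer RNG seed.
#' @return `2 x N` matrix with rows A and B.
#' @export
gen_coupled_mix <- function(params, seed = NULL) {
  stopifnot(inherits(params, "coupled_mix_params"))
  with_seed_or_not(seed, {
    m0 <- mix_channel(params$p0, params$N, params$fs)
    m1 <- mix_channel(params$p1, params$N, params$fs)
    m2 <- mix_channel(params$p2, params$N, params$fs)
    rbind(params$C * m0 + (1 - params$C) * m1,
          params$C * m0 + (1 - params$C) * m2)
  })
}

#' Superimpose white noise at a prescribed signal-to-noise ratio
#'
#' Adds, per channel, zero-mean Gaussian noise scaled so that
#' `10*log10(P_signal / P_noise) = snr_db`, with power taken as the mean
#' squared deviation from the channel mean.
#'
#' @param series channels-by-samples matrix or vector; no channel may be
#'   constant.
#' @param snr_db target signal-to-noise ratio in decibels (may be negative).
#' @param seed integer RNG seed.
#' @return matrix of the same shape.
#' @export
add_noise_at_snr <- function(series, snr_db, seed = NULL) {
  x <- as_channel_matrix(series)
  P <- rowMeans((x - rowMeans(x))^2)
  if (any(P == 0)) stop("constant channel has zero signal power")
  noise_sd <- sqrt(P / 10^(snr_db / 10))
  with_seed_or_not(seed,
    x + matrix(rnorm(nrow(x) * ncol(x)), nrow(x)) * noise_sd)
}
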