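# Shared machinery: channel normalisation, standard and refined-composite
# coarse-graining, multivariate and per-channel embedding, Chebyshev distance.
#
# The universal signal container is a plain numeric matrix with channels as
# rows and samples as columns; a single channel may be given as a numeric
# vector.  All operations are deterministic.

#' Coerce a signal to the channels-by-samples matrix convention
#'
#' Accepts a numeric matrix (channels as rows) or a numeric vector (a single
#' channel) and returns a validated `p x L` matrix. All values must be
#' finite and the series at least two samples long.
#'
#' @param series numeric matrix (channels x samples) or numeric vector.
#' @return a numeric matrix with `p >= 1` rows and `L >= 2` columns.
#' @export
as_channel_matrix <- function(series) {
  if (is.numeric(series) && is.null(dim(series)))
    series <- matrix(series, nrow = 1L)
  if (!is.matrix(series) || !is.numeric(series))
    stop("`series` must be a numeric matrix (channels x samples) or vector")
  if (nrow(series) < 1L || ncol(series) < 2L)
    stop("`series` needs at least 1 channel and 2 samples")
  if (!all(is.finite(series)))
    stop("`series` contains non-finite values")
  series
}

#' Parameter set for the multivariate multi-scale entropy estimators
#'
#' Collects the tuning parameters shared by the six estimators. Defaults
#' follow common practice for the sample/fuzzy entropy family; the
#' symbolic estimators (permutation, dispersion, increment) conventionally
#' use `m = 3` instead, see [default_entropy_params()].
#'
#' @param m per-channel embedding dimension (identical across channels).
#' @param d time delay (identical across channels).
#' @param r similarity tolerance, in units of the normalised signal SD.
#' @param lambda adjustment factor of the refined-composite fuzzy
#'   membership, in `[0.5, 1.5]`.
#' @param c number of classes of the dispersion mapping, `>= 2`.
#' @param R quantisation resolution of the increment words, `>= 1`.
#' @param max_scale largest coarse-graining scale factor.
#' @param mde_frozen_map if `TRUE` (default), the dispersion NCDF mapping
#'   uses the per-channel mean/SD of the original scale-1 series at every
#'   scale — the dispersion analogue of holding the tolerance `r` fixed
#'   across scales — so coarse-graining-induced variance loss is visible
#'   to the estimator. `FALSE` recomputes the parameters from the series
#'   being mapped.
#' @param mde_selection_cap upper bound on `choose(m*p, m)` dispersion
#'   selections per window; exceeding it is an error.
#' @return a list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, d = 1L, r = 0.15, lambda = 0.8,
                           c = 3L, R = 4L, max_scale = 20L,
                           mde_frozen_map = TRUE,
                           mde_selection_cap = 5000L) {
  m <- as.integer(m); d <- as.integer(d); c <- as.integer(c)
  R <- as.integer(R); max_scale <- as.integer(max_scale)
  stopifnot(m >= 1L, d >= 1L, r > 0, lambda >= 0.5, lambda <= 1.5,
            c >= 2L, R >= 1L, max_scale >= 1L)
  structure(list(m = m, d = d, r = r, lambda = lambda, c = c, R = R,
                 max_scale = max_scale, mde_frozen_map = mde_frozen_map,
                 mde_selection_cap = as.integer(mde_selection_cap)),
            class = "entropy_params")
}

#' Per-algorithm default parameters
#'
#' The sample/fuzzy family (`mvmse`, `mvmfe`, `rcmvmfe`) defaults to
#' `m = 2`, `d = 1`, `r = 0.15`, `lambda = 0.8`; the symbolic family
#' (`mvmpe`, `mvmde`, `mvmie`) to `m = 3`, `d = 1`, with `c = 3` classes
#' and quantisation resolution `R = 4`.
#'
#' @param algorithm one of `"mvmse"`, `"mvmfe"`, `"rcmvmfe"`, `"mvmpe"`,
#'   `"mvmde"`, `"mvmie"`.
#' @param max_scale largest scale factor.
#' @return an [entropy_params()] object.
#' @export
default_entropy_params <- function(algorithm, max_scale = 20L) {
  algorithm <- match_algorithm(algorithm)
  if (algorithm %in% c("mvmse", "mvmfe", "rcmvmfe"))
    entropy_params(m = 2L, d = 1L, max_scale = max_scale)
  else
    entropy_params(m = 3L, d = 1L, max_scale = max_scale)
}

algorithm_names <- c("mvmse", "mvmfe", "rcmvmfe", "mvmpe", "mvmde", "mvmie")

match_algorithm <- function(algorithm) {
  match.arg(tolower(algorithm), algorithm_names)
}

#' Z-score each channel
#'
#' Centres and scales every channel to sample mean 0 and sample SD 1
#' (divisor `L - 1`). Applied once to the original scale-1 series so that
#' the similarity tolerance `r` is fixed in SD units across all scales.
#'
#' @param series channels-by-samples matrix or vector.
#' @return matrix of the same shape.
#' @export
zscore_channels <- function(series) {
  x <- as_channel_matrix(series)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  if (any(sdv == 0))
    stop("constant channel: cannot z-score a zero-variance channel")
  (x - mu) / sdv
}

#' Coarse-grain a multichannel series
#'
#' Replaces each channel by the means of consecutive non-overlapping windows
#' of width `s` (the scale factor); the trailing remainder of fewer than `s`
#' samples is dropped. `s = 1` is the identity.
#'
#' @param series channels-by-samples matrix or vector.
#' @param s scale factor, a positive integer.
#' @return a `p x floor(L/s)` matrix.
#' @export
coarse_grain <- function(series, s) {
  x <- as_channel_matrix(series)
  s <- as.integer(s)
  stopifnot(s >= 1L)
  L <- ncol(x)
  N <- L %/% s
  if (N < 2L) stop("series too short to coarse-grain at scale ", s)
  if (s == 1L) return(x)
  out <- matrix(0, nrow(x), N)
  for (k in seq_len(nrow(x)))
    out[k, ] <- .colMeans(x[k, seq_len(N * s)], s, N)
  out
}

#' Refined (offset) coarse-graining
#'
#' The composite variant of coarse-graining: window `b` at offset `t`
#' averages samples `(b-1)s + t` through `bs + t - 1`, so the `s` offsets
#' `t = 1..s` yield `s` phase-shifted coarse-grained series. `t = 1`
#' reproduces [coarse_grain()] exactly. The output length is
#' `floor((L - t + 1)/s)`, so no window reads past the end of the series.
#'
#' @param series channels-by-samples matrix or vector.
#' @param s scale factor.
#' @param t offset, `1 <= t <= s`.
#' @return a `p x floor((L - t + 1)/s)` matrix.
#' @export
refined_coarse_grain <- function(series, s, t) {
  x <- as_channel_matrix(series)
  s <- as.integer(s); t <- as.integer(t)
  if (t < 1L || t > s) stop("offset t must satisfy 1 <= t <= s")
  L <- ncol(x)
  N <- (L - t + 1L) %/% s
  if (N < 1L) stop("series too short to coarse-grain at scale ", s,
                   " offset ", t)
  out <- matrix(0, nrow(x), N)
  for (k in seq_len(nrow(x)))
    out[k, ] <- .colMeans(x[k, t:(t + N * s - 1L)], s, N)
  out
}

#' Multivariate composite delay embedding
#'
#' Builds the composite embedding vectors of dimension `m * p`: vector `i`
#' concatenates, channel block by channel block, the `m` delayed samples
#' `x[k, i], x[k, i+d], ..., x[k, i+(m-1)d]` of each channel. Also returns
#' the `p` one-channel extensions to dimension `m + 1`, which append
#' `x[k, i + m*d]` for the extended channel `k`.
#'
#' @param coarse channels-by-samples matrix (typically coarse-grained).
#' @param m per-channel embedding dimension.
#' @param d time delay.
#' @return list with `base` (an `(N - m*d) x (m*p)` matrix) and
#'   `extensions` (a list of `p` matrices, each `(N - m*d) x (m*p + 1)`).
#' @export
embed_composite <- function(coarse, m, d) {
  x <- as_channel_matrix(coarse)
  m <- as.integer(m); d <- as.integer(d)
  p <- nrow(x); N <- ncol(x); n <- m * d
  M <- N - n
  if (M < 2L) stop("too few samples to embed: need N - m*d >= 2")
  base <- matrix(0, M, m * p)
  for (k in seq_len(p))
    for (l in seq_len(m))
      base[, (k - 1L) * m + l] <- x[k, (0:(M - 1L)) + (l - 1L) * d + 1L]
  extensions <- lapply(seq_len(p), function(k)
    cbind(base, x[k, (0:(M - 1L)) + n + 1L]))
  list(base = base, extensions = extensions)
}

#' Per-channel delay embedding
#'
#' For each channel, the windows `(x[k, i], x[k, i+d], ..., x[k, i+(m-1)d])`
#' for `i = 1..N-(m-1)d`, as one matrix per channel.
#'
#' @param coarse channels-by-samples matrix.
#' @param m embedding dimension.
#' @param d time delay.
#' @return list of `p` matrices, each `(N - (m-1)d) x m`.
#' @export
embed_per_channel <- function(coarse, m, d) {
  x <- as_channel_matrix(coarse)
  m <- as.integer(m); d <- as.integer(d)
  N <- ncol(x)
  M <- N - (m - 1L) * d
  if (M < 1L) stop("too few samples to embed: need N - (m-1)*d >= 1")
  lapply(seq_len(nrow(x)), function(k) {
    out <- matrix(0, M, m)
    for (l in seq_len(m)) out[, l] <- x[k, (0:(M - 1L)) + (l - 1L) * d + 1L]
    out
  })
}

#' Chebyshev (maximum) distance
#'
#' @param u,v numeric vectors of equal length.
#' @return `max(abs(u - v))`.
#' @export
chebyshev <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  max(abs(u - v))
}
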