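# The six multivariate multi-scale entropy estimators.  The sample/fuzzy
# family shares the compiled pairwise kernel (src/mv_kernels.cpp); the
# symbolic family (permutation, dispersion, increment) counts pattern
# frequencies in R.  Estimators operate on an (already coarse-grained)
# channels-by-samples matrix; use multiscale_curve() for the full
# normalise-then-sweep-scales workflow.

#' Multivariate sample entropy of a coarse-grained series
#'
#' The negative log ratio of the mean match probabilities at composite
#' embedding dimensions `m+1` and `m`: two composite delay vectors match
#' when their Chebyshev distance is at most `r`. The `p` single-channel
#' extensions to dimension `m+1` are pooled into one family of
#' `p * (N - m*d)` vectors. When either match probability is zero the
#' value is undefined and `NA` is returned (not an error).
#'
#' @param coarse channels-by-samples matrix, coarse-grained and normalised
#'   by the caller.
#' @param params an [entropy_params()] object (`m`, `d`, `r` are used).
#' @return entropy value, or `NA` when no matches occur.
#' @export
mv_sample_entropy <- function(coarse, params = entropy_params()) {
  x <- as_channel_matrix(coarse)
  check_embeddable(x, params, extra = 3L)
  st <- mv_match_stats(x, params$m, params$d, params$r, 1.0, FALSE)
  if (st[1] == 0 || st[2] == 0) return(NA_real_)
  -log(st[2] / st[1])
}

#' Fuzzy membership similarity
#'
#' Smooth similarity weight replacing the hard match threshold: 1 for
#' `dist <= r`, `exp(-ln2 * ((dist - r)/r)^2)` beyond, continuous at
#' `dist = r` (value 0.5 exactly at `dist = 2r`).
#'
#' @param dist non-negative distance(s).
#' @param r positive tolerance.
#' @return similarity in `(0, 1]`, vectorised over `dist`.
#' @export
fuzzy_similarity <- function(dist, r) {
  rc_fuzzy_similarity(dist, r, 1)
}

#' Refined-composite fuzzy membership similarity
#'
#' The adjusted membership used by RCmvMFE: 1 for `dist <= lambda*r`,
#' `exp(-ln2 * ((dist - lambda*r)/r)^2)` beyond. `lambda = 1` recovers
#' [fuzzy_similarity()].
#'
#' @param dist non-negative distance(s).
#' @param r positive tolerance.
#' @param lambda adjustment factor, typically in `[0.5, 1.5]`.
#' @return similarity in `(0, 1]`, vectorised over `dist`.
#' @export
rc_fuzzy_similarity <- function(dist, r, lambda) {
  if (any(dist < 0)) stop("distances must be non-negative")
  if (r <= 0) stop("r must be positive")
  ifelse(dist <= lambda * r, 1,
         exp(-log(2) * ((dist - lambda * r) / r)^2))
}

#' Multivariate fuzzy entropy of a coarse-grained series
#'
#' As [mv_sample_entropy()] but with the hard match indicator replaced by
#' the fuzzy membership [fuzzy_similarity()]; the match statistics are
#' therefore always positive and the result always finite.
#'
#' @inheritParams mv_sample_entropy
#' @return entropy value (finite).
#' @export
mv_fuzzy_entropy <- function(coarse, params = entropy_params()) {
  x <- as_channel_matrix(coarse)
  check_embeddable(x, params, extra = 3L)
  st <- mv_match_stats(x, params$m, params$d, params$r, 1.0, TRUE)
  -log(st[2] / st[1])
}

#' Refined composite multivariate fuzzy entropy at one scale
#'
#' For each offset `t = 1..s` the series is refined-coarse-grained
#' ([refined_coarse_grain()]), embedded, and the fuzzy match statistics are
#' computed with the adjusted membership [rc_fuzzy_similarity()]; the `s`
#' statistics are averaged at each dimension before taking the negative
#' log ratio. All offsets are truncated to the common length
#' `floor((L - s + 1)/s)` so each contributes equally. At `s = 1`,
#' `lambda = 1` this equals [mv_fuzzy_entropy()] at scale 1 exactly.
#'
#' @param series channels-by-samples matrix, normalised by the caller
#'   (the full-resolution series, not coarse-grained).
#' @param s scale factor.
#' @param params an [entropy_params()] object (`m`, `d`, `r`, `lambda`).
#' @return entropy value.
#' @export
mv_rc_fuzzy_entropy <- function(series, s, params = entropy_params()) {
  x <- as_channel_matrix(series)
  s <- as.integer(s)
  L <- ncol(x)
  Nmin <- (L - s + 1L) %/% s
  if (Nmin < params$m * params$d + 3L)
    stop("series too short for RCmvMFE at scale ", s)
  phi <- c(0, 0)
  for (t in seq_len(s)) {
    xc <- refined_coarse_grain(x, s, t)[, seq_len(Nmin), drop = FALSE]
    phi <- phi + mv_match_stats(xc, params$m, params$d, params$r,
                                params$lambda, TRUE)
  }
  phi <- phi / s
  -log(phi[2] / phi[1])
}

check_embeddable <- function(x, params, extra = 2L) {
  if (ncol(x) - params$m * params$d < extra)
    stop("coarse-grained series too short: need N - m*d >= ", extra)
  invisible(TRUE)
}

#' Multivariate permutation entropy of a coarse-grained series
#'
#' Each per-channel delay window is mapped to its ordinal pattern (stable
#' argsort: earlier index wins ties); pattern counts are pooled across the
#' `p` channels with normaliser `(N - (m-1)d) * p` and the Shannon entropy
#' `-sum(P log P)` (natural log) of the observed patterns is returned. The
#' value is bounded by `log(factorial(m))`.
#'
#' @inheritParams mv_sample_entropy
#' @return entropy value.
#' @export
mv_permutation_entropy <- function(coarse, params = entropy_params(m = 3)) {
  x <- as_channel_matrix(coarse)
  wins <- embed_per_channel(x, params$m, params$d)
  keys <- unlist(lapply(wins, function(W)
    apply(W, 1L, function(w)
      paste(order(w, method = "radix"), collapse = "."))))
  shannon(table(keys) / length(keys))
}

shannon <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Map a series through the normal cumulative distribution function
#'
#' Per channel, `y = pnorm((x - mu_k)/sigma_k)` with `mu_k`, `sigma_k` the
#' mean and sample SD of channel `k` of the series being mapped, yielding
#' values strictly inside (0, 1).
#'
#' @param coarse channels-by-samples matrix.
#' @param mu,sigma optional per-channel mean and SD vectors overriding the
#'   ones computed from `coarse` (used to freeze the mapping at scale 1).
#' @return matrix of the same shape with values in (0, 1).
#' @export
ncdf_map <- function(coarse, mu = NULL, sigma = NULL) {
  x <- as_channel_matrix(coarse)
  if (is.null(mu)) mu <- rowMeans(x)
  if (is.null(sigma)) sigma <- apply(x, 1L, sd)
  if (any(sigma == 0)) stop("constant channel: zero SD in NCDF mapping")
  pnorm((x - mu) / sigma)
}

#' Assign a dispersion class
#'
#' `z = round(c*y + 0.5)` with round-half-away-from-zero, clamped to
#' `[1, c]`.
#'
#' @param y values strictly in (0, 1), e.g. from [ncdf_map()].
#' @param c number of classes, `>= 2`.
#' @return integer classes in `1..c`, same shape as `y`.
#' @export
dispersion_digitize <- function(y, c) {
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly in (0, 1)")
  c <- as.integer(c)
  stopifnot(c >= 2L)
  z <- floor(c * y + 1)  # round-half-away-from-zero of c*y + 0.5
  pmin(pmax(as.integer(z), 1L), c)
}

#' Multivariate dispersion entropy of a coarse-grained series
#'
#' Channels are NCDF-mapped ([ncdf_map()]) and digitised into `c` classes
#' ([dispersion_digitize()]); composite class vectors of length `m*p` are
#' built per window, and every non-redundant selection of `m` of the `m*p`
#' positions (index combinations in lexicographic order, preserving order
#' within a selection) contributes its dispersion pattern. Relative
#' frequencies use the normaliser `(N - (m-1)d) * choose(m*p, m)` and the
#' natural-log Shannon entropy is returned; the value is bounded by
#' `log(c^m)`.
#'
#' @inheritParams mv_sample_entropy
#' @param scale1 optional original-resolution series from which to freeze
#'   the NCDF mapping parameters (only used when
#'   `params$mde_frozen_map = TRUE`).
#' @return entropy value.
#' @export
mv_dispersion_entropy <- function(coarse, params = entropy_params(m = 3),
                                  scale1 = NULL) {
  x <- as_channel_matrix(coarse)
  m <- params$m; d <- params$d; cc <- params$c
  p <- nrow(x)
  n_sel <- choose(m * p, m)
  if (n_sel > params$mde_selection_cap)
    stop("choose(m*p, m) = ", n_sel, " exceeds the selection cap of ",
         params$mde_selection_cap)
  if (isTRUE(params$mde_frozen_map) && !is.null(scale1)) {
    s1 <- as_channel_matrix(scale1)
    y <- ncdf_map(x, mu = rowMeans(s1), sigma = apply(s1, 1L, sd))
  } else {
    y <- ncdf_map(x)
  }
  z <- dispersion_digitize(y, cc)
  dim(z) <- dim(x)
  # composite class windows: (N - (m-1)d) x (m*p), channel-block layout
  W <- do.call(cbind, embed_per_channel(z, m, d))
  sel <- combn(m * p, m)
  pw <- cc^(seq_len(m) - 1L)
  counts <- integer(cc^m)
  for (q in seq_len(ncol(sel))) {
    code <- as.integer((W[, sel[, q], drop = FALSE] - 1L) %*% pw) + 1L
    tab <- tabulate(code, nbins = cc^m)
    counts <- counts + tab
  }
  shannon(counts / (nrow(W) * ncol(sel)))
}

#' Increment (first-difference) series
#'
#' @param coarse channels-by-samples matrix with at least 2 samples.
#' @return `p x (N-1)` matrix of consecutive differences.
#' @export
increment_series <- function(coarse) {
  x <- as_channel_matrix(coarse)
  x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE]
}

#' Word of a window of increments
#'
#' Each increment maps to a (sign, magnitude) pair: the sign is
#' `sign(z) %in% {-1, 0, +1}`; the magnitude is 0 when the window's sample
#' SD is zero, else `min(R, floor(|z| * R / sd(window)))`. The word is the
#' ordered sequence of pairs.
#'
#' @param window numeric vector of increments (non-empty).
#' @param R quantisation resolution, `>= 1`.
#' @return integer matrix with rows `sign` and `magnitude`.
#' @export
increment_word <- function(window, R) {
  if (length(window) == 0) stop("empty window")
  R <- as.integer(R)
  stopifnot(R >= 1L)
  sdw <- if (length(window) > 1L) sd(window) else 0
  # guard against floating-point jitter in nominally constant windows
  if (sdw <= 1e-12 * max(abs(window), 1)) sdw <- 0
  q <- if (sdw == 0) rep(0L, length(window))
       else pmin(R, floor(abs(window) * R / sdw))
  rbind(sign = as.integer(sign(window)), magnitude = as.integer(q))
}

#' Multivariate increment entropy of a coarse-grained series
#'
#' The increment series of each channel is embedded into windows of `m`
#' increments at stride `d`; each window maps to its word of
#' (sign, magnitude) pairs ([increment_word()]). Words are pooled across
#' channels with normaliser `(N - (m-1)d - 1) * p` and the natural-log
#' Shannon entropy over distinct words is returned; with resolution `R`
#' there are at most `(2*(R+1) + 1)^m` possible words.
#'
#' @inheritParams mv_sample_entropy
#' @return entropy value.
#' @export
mv_increment_entropy <- function(coarse, params = entropy_params(m = 3)) {
  x <- as_channel_matrix(coarse)
  m <- params$m; d <- params$d; R <- params$R
  z <- increment_series(x)
  wins <- embed_per_channel(z, m, d)
  keys <- unlist(lapply(wins, function(W) {
    if (m > 1L) {
      mu <- rowMeans(W)
      sdw <- sqrt(pmax(0, rowSums((W - mu)^2) / (m - 1L)))
      # nominally constant windows: floating-point jitter is not structure
      sdw[sdw <= 1e-12 * pmax(apply(abs(W), 1L, max), 1)] <- 0
    } else {
      sdw <- rep(0, nrow(W))
    }
    sg <- sign(W)
    q <- matrix(0L, nrow(W), m)
    pos <- sdw > 0
    if (any(pos))
      q[pos, ] <- pmin(R, floor(abs(W[pos, , drop = FALSE]) * R / sdw[pos]))
    apply(matrix(paste(sg, q, sep = ":"), nrow(W), m), 1L,
          paste, collapse = ",")
  }))
  shannon(table(keys) / length(keys))
}

#' Entropy versus scale factor
#'
#' The full multi-scale workflow: the series is z-scored once (so the
#' tolerance `r` is fixed in SD units across scales), then for each scale
#' `s = 1..max_scale` the requested estimator is applied to the standard
#' coarse-grained series (refined-composite coarse-graining for
#' `"rcmvmfe"`). Scales at which the estimator is undefined or degenerate
#' are recorded as `NA` with `defined = FALSE`, never dropped.
#'
#' @param series channels-by-samples matrix or vector (raw, un-normalised).
#' @param algorithm one of `"mvmse"`, `"mvmfe"`, `"rcmvmfe"`, `"mvmpe"`,
#'   `"mvmde"`, `"mvmie"`.
#' @param params an [entropy_params()] object; defaults to the
#'   per-algorithm conventions of [default_entropy_params()].
#' @return data.frame with columns `scale`, `value`, `defined`.
#' @export
multiscale_curve <- function(series, algorithm,
                             params = default_entropy_params(algorithm)) {
  algorithm <- match_algorithm(algorithm)
  x <- zscore_channels(series)
  vals <- vapply(seq_len(params$max_scale), function(s) {
    tryCatch({
      if (algorithm == "rcmvmfe") {
        mv_rc_fuzzy_entropy(x, s, params)
      } else {
        xc <- coarse_grain(x, s)
        switch(algorithm,
               mvmse = mv_sample_entropy(xc, params),
               mvmfe = mv_fuzzy_entropy(xc, params),
               mvmpe = mv_permutation_entropy(xc, params),
               mvmde = mv_dispersion_entropy(xc, params, scale1 = x),
               mvmie = mv_increment_entropy(xc, params))
      }
    }, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(scale = seq_len(params$max_scale), value = vals,
             defined = !is.na(vals))
}
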