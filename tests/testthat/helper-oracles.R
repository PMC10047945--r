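# Independent naive reference implementations used as oracles.  All are
# deliberately brute-force (explicit double loops over embedding vectors /
# patterns) and written directly from the defining formulas, sharing no
# code with the package internals.

oracle_embed_uni <- function(x, m, d) {
  M <- length(x) - (m - 1L) * d
  t(vapply(seq_len(M), function(i) x[i + (0:(m - 1L)) * d], numeric(m)))
}

# univariate sample entropy: vectors of length m and m+1, both over
# N - m*d start indices, hard threshold r
oracle_sampen_uni <- function(x, m, d, r) {
  M <- length(x) - m * d
  Em <- t(vapply(seq_len(M), function(i) x[i + (0:(m - 1L)) * d],
                 numeric(m)))
  E1 <- t(vapply(seq_len(M), function(i) x[i + (0:m) * d], numeric(m + 1L)))
  phi <- function(E) {
    Mv <- nrow(E); tot <- 0
    for (i in seq_len(Mv)) for (j in seq_len(Mv)) if (i != j)
      tot <- tot + (max(abs(E[i, ] - E[j, ])) <= r)
    tot / (Mv * (Mv - 1))
  }
  pm <- phi(Em); p1 <- phi(E1)
  if (pm == 0 || p1 == 0) NA_real_ else -log(p1 / pm)
}

oracle_fuzzy_sim <- function(dd, r, lambda = 1) {
  if (dd <= lambda * r) 1 else exp(-log(2) * ((dd - lambda * r) / r)^2)
}

oracle_fuzzen_uni <- function(x, m, d, r, lambda = 1) {
  M <- length(x) - m * d
  Em <- t(vapply(seq_len(M), function(i) x[i + (0:(m - 1L)) * d],
                 numeric(m)))
  E1 <- t(vapply(seq_len(M), function(i) x[i + (0:m) * d], numeric(m + 1L)))
  phi <- function(E) {
    Mv <- nrow(E); tot <- 0
    for (i in seq_len(Mv)) for (j in seq_len(Mv)) if (i != j)
      tot <- tot + oracle_fuzzy_sim(max(abs(E[i, ] - E[j, ])), r, lambda)
    tot / (Mv * (Mv - 1))
  }
  -log(phi(E1) / phi(Em))
}

# brute-force multivariate sample/fuzzy statistics for small inputs:
# composite vectors channel-block by channel-block; the p extension
# families to dimension m+1 are each treated exactly like the dimension-m
# set (within-family pairwise similarity) and the p * M per-vector
# probabilities are averaged
oracle_mv_phi <- function(x, m, d, r, lambda = 1, fuzzy = TRUE) {
  p <- nrow(x); N <- ncol(x); n <- m * d
  M <- N - n
  base <- t(vapply(seq_len(M), function(i)
    as.numeric(t(vapply(seq_len(p), function(k)
      x[k, i + (0:(m - 1L)) * d], numeric(m)))), numeric(m * p)))
  sim <- function(dd) {
    if (fuzzy) oracle_fuzzy_sim(dd, r, lambda)
    else as.numeric(dd <= r)
  }
  phi_of <- function(E) {
    Mv <- nrow(E); tot <- 0
    for (i in seq_len(Mv)) for (j in seq_len(Mv)) if (i != j)
      tot <- tot + sim(max(abs(E[i, ] - E[j, ])))
    tot / (Mv * (Mv - 1))
  }
  fam <- vapply(seq_len(p), function(k)
    phi_of(cbind(base, x[k, seq_len(M) + n])), numeric(1))
  c(phi_of(base), mean(fam))
}

# univariate permutation entropy (stable argsort patterns, pooled norm)
oracle_pe_uni <- function(x, m, d) {
  E <- oracle_embed_uni(x, m, d)
  pats <- apply(E, 1L, function(w) paste(order(w), collapse = ""))
  pr <- table(pats) / length(pats)
  -sum(pr * log(pr))
}

# univariate dispersion entropy: NCDF map with the series mean/SD,
# classes round(c*y + 0.5) half-away-from-zero, patterns of m classes
oracle_de_uni <- function(x, m, d, c) {
  y <- pnorm((x - mean(x)) / sd(x))
  z <- pmin(pmax(floor(c * y + 1), 1), c)
  E <- oracle_embed_uni(z, m, d)
  pats <- apply(E, 1L, paste, collapse = "")
  pr <- table(pats) / length(pats)
  -sum(pr * log(pr))
}

# univariate increment entropy: words of (sign, magnitude) pairs over
# windows of m increments, magnitude min(R, floor(|z|R/sd(window)))
oracle_ie_uni <- function(x, m, d, R) {
  z <- diff(x)
  E <- oracle_embed_uni(z, m, d)
  words <- apply(E, 1L, function(w) {
    s <- sign(w)
    sdw <- sd(w)
    q <- if (is.na(sdw) || sdw == 0) rep(0, length(w))
         else pmin(R, floor(abs(w) * R / sdw))
    paste(s, q, sep = ":", collapse = ",")
  })
  pr <- table(words) / length(words)
  -sum(pr * log(pr))
}

# log-log PSD slope via smoothed periodogram regression (excluding DC)
oracle_psd_slope <- function(x) {
  sp <- stats::spec.pgram(stats::ts(x), spans = c(11, 11), plot = FALSE,
                          taper = 0, detrend = TRUE)
  fit <- stats::lm(log(sp$spec) ~ log(sp$freq))
  unname(coef(fit)[2L])
}
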