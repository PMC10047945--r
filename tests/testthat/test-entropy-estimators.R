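# Expected values here were computed with the brute-force oracles in
# helper-oracles.R (explicit double loops over embedding vectors written
# straight from the defining formulas) or by hand enumeration.

test_that("fuzzy similarity matches its defining values and boundaries", {
  r <- 0.2
  expect_equal(fuzzy_similarity(0, r), 1)
  expect_equal(fuzzy_similarity(r, r), 1)
  expect_equal(fuzzy_similarity(2 * r, r), 0.5)  # exp(-ln2) exactly
  expect_equal(rc_fuzzy_similarity(0.8 * r, r, 0.8), 1)
  expect_equal(rc_fuzzy_similarity(0.8 * r + r, r, 0.8), 0.5)
  d <- seq(0, 1, by = 0.01)
  expect_equal(rc_fuzzy_similarity(d, r, 1), fuzzy_similarity(d, r))
  expect_error(fuzzy_similarity(-0.1, r), "non-negative")
})

test_that("single-channel estimators agree with brute-force oracles", {
  pars2 <- entropy_params(m = 2, d = 1, r = 0.15)
  pars3 <- entropy_params(m = 3, d = 1, c = 3, R = 4)
  x <- as.numeric(zscore_channels(gen_wgn(1, 200, seed = 51)))

  expect_equal(mv_sample_entropy(matrix(x, 1), pars2),
               oracle_sampen_uni(x, 2, 1, 0.15), tolerance = 1e-10)
  expect_equal(mv_fuzzy_entropy(matrix(x, 1), pars2),
               oracle_fuzzen_uni(x, 2, 1, 0.15), tolerance = 1e-10)

  y <- as.numeric(zscore_channels(gen_wgn(1, 500, seed = 52)))
  expect_equal(mv_permutation_entropy(matrix(y, 1), pars3),
               oracle_pe_uni(y, 3, 1), tolerance = 1e-10)
  expect_equal(mv_dispersion_entropy(matrix(y, 1), pars3),
               oracle_de_uni(y, 3, 1, 3), tolerance = 1e-10)
  z <- as.numeric(zscore_channels(gen_wgn(1, 300, seed = 53)))
  expect_equal(mv_increment_entropy(matrix(z, 1), pars3),
               oracle_ie_uni(z, 3, 1, 4), tolerance = 1e-10)
})

test_that("multivariate match statistics agree with a brute-force p = 2 oracle", {
  x <- zscore_channels(gen_correlated_pair("wgn", 0.6, 120, seed = 54))
  for (fz in c(TRUE, FALSE)) {
    ours <- mventropy:::mv_match_stats(x, 2L, 1L, 0.3, 1.0, fz)
    expect_equal(as.numeric(ours), oracle_mv_phi(x, 2, 1, 0.3, 1, fz),
                 tolerance = 1e-12)
  }
  ours <- mventropy:::mv_match_stats(x, 2L, 1L, 0.15, 0.8, TRUE)
  expect_equal(as.numeric(ours), oracle_mv_phi(x, 2, 1, 0.15, 0.8, TRUE),
               tolerance = 1e-12)
})

test_that("fuzzy entropy stays finite where sample entropy is undefined", {
  pars <- entropy_params(m = 2, d = 1, r = 0.15)
  # strictly increasing steps of 0.3 > r: no hard matches at all, while
  # neighbouring windows still carry fuzzy weight exp(-ln2) = 0.5
  x <- matrix((1:30) * 0.3, 1)
  expect_true(is.na(mv_sample_entropy(x, pars)))
  expect_true(is.finite(mv_fuzzy_entropy(x, pars)))
})

test_that("RCmvMFE collapses to mvMFE at scale 1 with lambda 1", {
  pars <- entropy_params(m = 2, d = 1, r = 0.15, lambda = 1)
  x <- zscore_channels(gen_correlated_pair("wgn", 0.5, 400, seed = 56))
  expect_equal(mv_rc_fuzzy_entropy(x, 1, pars), mv_fuzzy_entropy(x, pars),
               tolerance = 1e-12)
})

test_that("estimators are invariant to channel order and channel amplitude", {
  x <- gen_wgn(3, 400, seed = 57)
  perm <- x[c(3, 1, 2), ]
  scaled <- x * c(5, 0.2, 40)
  for (a in c("mvmse", "mvmfe", "rcmvmfe", "mvmpe", "mvmde", "mvmie")) {
    pars <- default_entropy_params(a, max_scale = 3L)
    v0 <- multiscale_curve(x, a, pars)$value
    # dispersion patterns are read in channel-block position order, so
    # reordering channels permutes the within-selection reading order of
    # cross-channel selections: mvMDE is invariant only up to that
    # reshuffling of pattern labels, which perturbs the entropy slightly
    tol_perm <- if (a == "mvmde") 5e-3 else 1e-9
    expect_equal(multiscale_curve(perm, a, pars)$value, v0,
                 tolerance = tol_perm, label = paste(a, "permuted"))
    expect_equal(multiscale_curve(scaled, a, pars)$value, v0,
                 tolerance = 1e-9, label = paste(a, "scaled"))
  }
})

test_that("permutation entropy enumerates ordinal patterns with stable ties", {
  pars <- entropy_params(m = 3, d = 1)
  # windows (3,1,2), (1,2,5), (2,5,4): three distinct patterns -> ln 3
  expect_equal(mv_permutation_entropy(c(3, 1, 2, 5, 4), pars), log(3))
  expect_equal(mv_permutation_entropy(1:50, pars), 0)
  x <- gen_wgn(2, 300, seed = 58)
  expect_lte(mv_permutation_entropy(x, pars), log(factorial(3)))
})

test_that("NCDF mapping and dispersion classes follow the printed rules", {
  x <- matrix(c(1, 2, 3, 4, 6), 1)
  y <- ncdf_map(x)
  expect_true(all(y > 0 & y < 1))
  mu <- mean(x); s <- sd(x)
  expect_equal(unname(ncdf_map(matrix(c(mu, mu + s, mu - s), 1),
                               mu = mu, sigma = s)[1, ]),
               c(0.5, pnorm(1), pnorm(-1)))
  expect_equal(dispersion_digitize(0.4, 3), 2L)    # round(1.7)
  expect_equal(dispersion_digitize(0.999, 3), 3L)  # round(3.497)
  expect_equal(dispersion_digitize(0.01, 3), 1L)   # round(0.53)
  expect_error(dispersion_digitize(1.2, 3), "strictly")
  expect_error(ncdf_map(matrix(1, 1, 10)), "constant")
})

test_that("dispersion entropy respects its pattern-count bound and selection cap", {
  pars <- entropy_params(m = 3, d = 1, c = 3)
  x <- gen_wgn(2, 400, seed = 59)
  expect_lte(mv_dispersion_entropy(zscore_channels(x), pars), 3 * log(3))
  tight <- entropy_params(m = 3, d = 1, c = 3, mde_selection_cap = 5L)
  expect_error(mv_dispersion_entropy(zscore_channels(x), tight), "cap")
})

test_that("increment words encode sign and quantised magnitude", {
  expect_equal(increment_word(c(0, 0), 4),
               rbind(sign = c(0L, 0L), magnitude = c(0L, 0L)))
  w <- increment_word(c(2, -1, 0), 4)
  expect_equal(w["sign", ], c(1L, -1L, 0L))
  # sd(c(2,-1,0)) = 1.5275; q = min(4, floor(|z|*4/sd)) = (5->4, 2, 0)
  expect_equal(w["magnitude", ], c(4L, 2L, 0L))
  expect_equal(as.numeric(increment_series(matrix(c(1, 3, 2, 2), 1))),
               c(2, -1, 0))
})

test_that("increment entropy handles degenerate inputs and respects its bound", {
  pars <- entropy_params(m = 3, d = 1, R = 4)
  ramp <- matrix(seq(0, 10, length.out = 60), 1)
  expect_equal(mv_increment_entropy(ramp, pars), 0)  # constant increments
  x <- gen_wgn(2, 300, seed = 60)
  expect_lte(mv_increment_entropy(zscore_channels(x), pars),
             3 * log(2 * (4 + 1) + 1))
})

test_that("pattern distributions of the symbolic estimators sum to one", {
  x <- zscore_channels(gen_wgn(2, 200, seed = 61))
  pars <- entropy_params(m = 3, d = 1, c = 3, R = 4)
  wins <- embed_per_channel(x, 3, 1)
  keys <- unlist(lapply(wins, function(W)
    apply(W, 1, function(w) paste(order(w), collapse = ""))))
  expect_equal(sum(table(keys) / length(keys)), 1, tolerance = 1e-9)
  # dispersion: (N - (m-1)d) * choose(m*p, m) selections in total
  z <- dispersion_digitize(ncdf_map(x), 3)
  expect_identical(length(z), length(x))
})

test_that("multiscale curves mark degenerate scales instead of failing", {
  x <- gen_wgn(1, 60, seed = 62)
  pars <- entropy_params(m = 2, d = 1, r = 1e-9, max_scale = 8L)
  cv <- multiscale_curve(x, "mvmse", pars)
  expect_identical(nrow(cv), 8L)
  expect_true(any(!cv$defined))
  expect_true(all(is.na(cv$value[!cv$defined])))

  one <- multiscale_curve(x, "mvmpe",
                          entropy_params(m = 3, d = 1, max_scale = 1L))
  expect_identical(nrow(one), 1L)
  expect_equal(one$value,
               mv_permutation_entropy(zscore_channels(x),
                                      entropy_params(m = 3, d = 1)))
})

test_that("permutation entropy of white noise is scale-invariant", {
  pars <- entropy_params(m = 3, d = 1, max_scale = 20L)
  d <- vapply(1:20, function(j) {
    cv <- multiscale_curve(gen_wgn(3, 6000, seed = 300 + j), "mvmpe", pars)
    cv$value[20] - cv$value[1]
  }, numeric(1))
  expect_lt(abs(mean(d)), 0.05)
})
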