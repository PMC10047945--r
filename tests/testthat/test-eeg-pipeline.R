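tiny_map <- function() list(F = c("f1", "f2"), P = c("p1", "p2"))

labelled_wgn <- function(labels, L, seed) {
  x <- gen_wgn(length(labels), L, seed = seed)
  rownames(x) <- labels
  x
}

test_that("epoch segmentation splits recordings and drops the remainder", {
  x <- labelled_wgn(c("a", "b"), 180 * 10, seed = 1)   # 180 s at 10 Hz
  ep <- segment_epochs(x, rate = 10, duration_s = 5)
  expect_length(ep$epochs, 36L)
  expect_identical(dim(ep$epochs[[1]]), c(2L, 50L))

  ep2 <- segment_epochs(labelled_wgn("a", 70, seed = 2), 10, 5)
  expect_length(ep2$epochs, 1L)
  expect_error(segment_epochs(labelled_wgn("a", 40, seed = 3), 10, 5),
               "shorter")
})

test_that("region entropy averages epochs robustly and flags outliers", {
  pars <- entropy_params(max_scale = 4L)
  # identical epochs: region curve equals the single-epoch curve
  base <- labelled_wgn(unlist(tiny_map()), 200, seed = 4)
  ep <- segment_epochs(cbind(base, base, base, base, base), 1, 200)
  re <- region_entropy(ep, tiny_map(), pars)
  single <- multiscale_curve(base[c("f1", "f2"), ], "rcmvmfe", pars)
  expect_equal(re$value[re$region == "F"], single$value, tolerance = 1e-12)
  expect_true(all(re$n_used == 5L))

  # one wildly different epoch among many nearly identical ones is excluded
  eps <- c(replicate(8, base + matrix(rnorm(length(base), 0, 1e-4),
                                      nrow(base)), simplify = FALSE),
           list(matrix(rep(gen_mix(1, 200, seed = 9), 4), 4, byrow = TRUE,
                       dimnames = list(unlist(tiny_map())))))
  ep2 <- structure(list(epochs = eps, rate = 1, duration_s = 200),
                   class = "epoch_set")
  re2 <- region_entropy(ep2, tiny_map(), pars)
  nF <- re2$n_used[re2$region == "F"]
  expect_true(all(nF <= 8L))   # the outlier epoch never survives
  expect_true(all(nF >= 6L))
  curves <- vapply(eps[1:8], function(e)
    multiscale_curve(e[c("f1", "f2"), ], "rcmvmfe", pars)$value,
    numeric(4))
  # dropping a jittered inlier moves the mean by at most ~1e-4
  expect_equal(re2$value[re2$region == "F"], rowMeans(curves),
               tolerance = 1e-2)

  expect_error(region_entropy(ep, list(F = c("f1", "zz")), pars), "absent")
})

test_that("band averages summarise the requested scales", {
  cv <- data.frame(scale = 1:15, value = c(2, 2, 2, 2, rep(9, 5),
                                           1:6))
  expect_equal(band_average(cv, scale_band("short")), 2)
  expect_equal(band_average(cv, scale_band("long")), 3.5)
  cv$value[10:15] <- NA
  expect_true(is.na(band_average(cv, scale_band("long"))))
  expect_error(band_average(cv[1:3, ], scale_band("long")), "absent")
})

test_that("group comparison computes t-tests with BH adjustment within bands", {
  subjects <- sprintf("s%02d", 1:12)
  cohort <- expand.grid(subject = subjects, region = c("F", "C", "P"),
                        band = "short", stringsAsFactors = FALSE)
  cohort$group <- ifelse(cohort$subject %in% subjects[1:6], "g1", "g2")
  set.seed(5)
  cohort$entropy <- rnorm(nrow(cohort))
  # identical groups give t = 0, p = 1
  same <- cohort
  for (rg in unique(same$region)) {
    v <- same$entropy[same$region == rg & same$group == "g1"]
    same$entropy[same$region == rg & same$group == "g2"] <- v
  }
  gs <- group_compare(same)
  expect_equal(gs$t, rep(0, 3), tolerance = 1e-12)
  expect_equal(gs$p, rep(1, 3), tolerance = 1e-12)
  expect_false(any(gs$significant))

  # BH step-up: p_adj = cummin over decreasing rank of p * n / rank
  gs2 <- group_compare(cohort)
  ord <- order(gs2$p)
  n <- nrow(gs2)
  manual <- rev(cummin(rev(gs2$p[ord] * n / seq_len(n))))
  expect_equal(gs2$p_adj[ord], pmin(manual, 1), tolerance = 1e-12)
  expect_true(all(gs2$p_adj >= gs2$p))

  expect_error(group_compare(cohort[cohort$subject != "s01", ][1:5, ]),
               "two levels|fewer")
})

test_that("a planted 1.5-pooled-SD short-scale difference is recovered with high power", {
  regions <- c("F", "C", "P", "O", "LT", "RT")
  flags <- vapply(1:100, function(rep) {
    set.seed(rep)
    rows <- do.call(rbind, lapply(regions, function(rg) {
      data.frame(subject = sprintf("s%02d", 1:20),
                 group = c(rep("mci", 12), rep("control", 8)),
                 region = rg, band = "short",
                 entropy = c(rnorm(12, 0), rnorm(8, 1.5)))
    }))
    gs <- group_compare(rows)
    gs$significant[gs$region == "F"]
  }, logical(1))
  expect_gte(mean(flags), 0.8)
})

test_that("null cohorts are flagged at roughly the FDR rate", {
  regions <- c("F", "C", "P", "O", "LT", "RT")
  any_flag <- vapply(1:200, function(rep) {
    set.seed(10000 + rep)
    rows <- do.call(rbind, lapply(regions, function(rg) {
      data.frame(subject = sprintf("s%02d", 1:20),
                 group = c(rep("mci", 12), rep("control", 8)),
                 region = rg, band = "short", entropy = rnorm(20))
    }))
    any(group_compare(rows)$significant)
  }, logical(1))
  expect_lte(mean(any_flag), 0.12)
})

test_that("score correlations report exact r on deterministic inputs and are calibrated", {
  cohort <- data.frame(subject = c("a", "b", "c"), group = "g1",
                       region = "F", band = "short",
                       entropy = c(1, 2, 3), sc = c(2, 4, 6),
                       anti = c(3, 2, 1))
  cs <- correlate_scores(cohort, c("sc", "anti"))
  expect_equal(cs$r[cs$score == "sc"], 1)
  expect_equal(cs$r[cs$score == "anti"], -1)

  # shuffled scores: raw p <= 0.05 in about 5% of seeds
  hits <- vapply(1:200, function(j) {
    set.seed(j)
    co <- data.frame(subject = sprintf("s%d", 1:20), group = "g",
                     region = "F", band = "short",
                     entropy = rnorm(20), sc = sample(rnorm(20)))
    correlate_scores(co, "sc")$p <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.11)

  # constant score recorded as NA, not an error
  cohort$flat <- 1
  expect_true(is.na(correlate_scores(cohort, "flat")$r))
})

test_that("the synthetic cohort plants a recoverable short-scale group difference", {
  map <- tiny_map()
  dirs <- vapply(1:10, function(j) {
    ch <- gen_synthetic_cohort(n_mci = 6, n_control = 6, effect = 0.45,
                               coupling_gap = 0.2, seed = j,
                               duration_s = 30, rate = 100,
                               region_map = map)
    res <- run_eeg_pipeline(ch$series, ch$groups, scores = NULL,
                            region_map = map,
                            params = entropy_params(max_scale = 6L),
                            bands = list(scale_band("short")),
                            rate = 100, epoch_s = 2)
    d <- res$cohort[res$cohort$region == "F", ]
    mean(d$entropy[d$group == "mci"]) < mean(d$entropy[d$group == "control"])
  }, logical(1))
  expect_gte(mean(dirs), 0.9)
})

test_that("cohort generation is reproducible and carries scores", {
  c1 <- gen_synthetic_cohort(2, 2, seed = 3, duration_s = 2, rate = 50,
                             region_map = tiny_map())
  c2 <- gen_synthetic_cohort(2, 2, seed = 3, duration_s = 2, rate = 50,
                             region_map = tiny_map())
  expect_identical(c1, c2)
  expect_setequal(names(c1$scores), c("subject", "MoCA", "AVLT_delayed"))
  expect_identical(length(c1$series), 4L)
  expect_identical(rownames(c1$series[[1]]), unlist(tiny_map(),
                                                    use.names = FALSE))
})

test_that("region maps validate disjointness and channel coverage", {
  expect_silent(validate_region_map <- mventropy:::validate_region_map(
    default_region_map()))
  expect_error(mventropy:::validate_region_map(
    list(A = c("x", "y"), B = c("y", "z"))), "disjoint")
  expect_identical(length(unlist(default_region_map())), 32L)
  tf <- tempfile(fileext = ".yaml")
  writeLines("F: [f1, f2]\nP: [p1]", tf)
  expect_identical(read_region_map(tf), list(F = c("f1", "f2"), P = "p1"))
})

test_that("matrix round-trip through delimited text preserves labels and values", {
  x <- labelled_wgn(c("Cz", "Pz"), 50, seed = 8)
  tf <- tempfile(fileext = ".csv")
  write_mc_matrix(x, tf)
  y <- read_mc_matrix(tf)
  expect_identical(rownames(y), c("Cz", "Pz"))
  expect_equal(unname(y), unname(x), tolerance = 1e-12)
})
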