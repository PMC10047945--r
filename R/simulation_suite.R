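# The five benchmark simulation experiments (complexity, correlation,
# coupling, noise resistance, data length) as seeded, parameterised
# pipelines emitting tidy long-format tables, plus the detector operations
# that summarise them (ordering threshold, peak coupling, stabilisation
# length).
#
# Replicate j of condition ci uses seed `seed + (ci - 1)*10000 + j`, so
# replicates are reproducible and conditions statistically independent.
# Within a replicate all requested algorithms see the same signal.

#' Specification of a simulation experiment
#'
#' Collects the replicate count, signal length, base seed, algorithm list
#' and the experiment-specific grids. Defaults are the study conditions:
#' 20 replicates of length-6000 signals, scales 1 to 20 (1 to 10 for the
#' data-length experiment so that every grid length supports every scale),
#' inter-channel correlation 0.95, coupling grid 0 to 1 in steps of 0.1,
#' SNR levels 20/10/0/-10/-20 dB, length grid 100 to 2000 in steps of 100,
#' and coupled-MIX parameters C = 0.4, p0 = 0.2, p1 = 0.5, p2 = 0.8 for
#' the noise and length experiments.
#'
#' @param experiment one of `"complexity"`, `"correlation"`, `"coupling"`,
#'   `"noise"`, `"length"`.
#' @param reps replicates per condition.
#' @param length samples per channel.
#' @param seed base seed.
#' @param algorithms character vector of estimator names.
#' @param max_scale largest scale factor (default 20; 10 for `"length"`).
#' @param rho inter-channel correlation of the correlated conditions.
#' @param C_grid coupling-coefficient grid.
#' @param p_grid equal-probability settings `p0 = p1 = p2` for the coupling
#'   experiment (equal parameters pin the single-channel complexity,
#'   isolating the coupling effect).
#' @param p_triples optional list of `c(p0, p1, p2)` triples overriding
#'   `p_grid`.
#' @param snr_grid SNR levels in dB for the noise experiment.
#' @param N_grid data-length grid for the length experiment.
#' @param mix coupled-MIX parameters for the noise/length experiments, a
#'   list with `C`, `p0`, `p1`, `p2`.
#' @param fs MIX sinusoid period divisor.
#' @param coupling_scale `"scale1"` (default) or `"scale_mean"`: which
#'   summary the coupling experiment reports alongside the per-scale values.
#' @return a list of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("complexity", "correlation",
                                           "coupling", "noise", "length"),
                            reps = 20L, length = 6000L, seed = 1L,
                            algorithms = c("mvmse", "mvmfe", "rcmvmfe",
                                           "mvmpe", "mvmde", "mvmie"),
                            max_scale = NULL,
                            rho = 0.95,
                            C_grid = seq(0, 1, by = 0.1),
                            p_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            p_triples = NULL,
                            snr_grid = c(20, 10, 0, -10, -20),
                            N_grid = seq(100L, 2000L, by = 100L),
                            mix = list(C = 0.4, p0 = 0.2, p1 = 0.5,
                                       p2 = 0.8),
                            fs = 12,
                            coupling_scale = c("scale1", "scale_mean")) {
  experiment <- match.arg(experiment)
  if (is.null(max_scale))
    max_scale <- if (experiment == "length") 10L else 20L
  algorithms <- vapply(algorithms, match_algorithm, character(1),
                       USE.NAMES = FALSE)
  stopifnot(reps >= 1L, length >= 2L, length(C_grid) >= 1L,
            length(N_grid) >= 1L)
  structure(list(experiment = experiment, reps = as.integer(reps),
                 length = as.integer(length), seed = as.integer(seed),
                 algorithms = algorithms, max_scale = as.integer(max_scale),
                 rho = rho, C_grid = C_grid, p_grid = p_grid,
                 p_triples = p_triples, snr_grid = snr_grid,
                 N_grid = as.integer(N_grid), mix = mix, fs = fs,
                 coupling_scale = match.arg(coupling_scale)),
            class = "experiment_spec")
}

cond_seed <- function(base, cond_idx, rep) {
  base + (cond_idx - 1L) * 10000L + rep
}

curve_table <- function(spec, cond_idx, condition, gen) {
  out <- vector("list", spec$reps)
  for (j in seq_len(spec$reps)) {
    sd_j <- cond_seed(spec$seed, cond_idx, j)
    x <- gen(sd_j)
    rows <- lapply(spec$algorithms, function(a) {
      pars <- default_entropy_params(a, max_scale = spec$max_scale)
      cv <- multiscale_curve(x, a, pars)
      data.frame(algorithm = a, condition = condition, replicate = j,
                 seed = sd_j, scale = cv$scale, value = cv$value,
                 defined = cv$defined)
    })
    out[[j]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Per-scale ensemble mean and SD of a tidy result table
#'
#' @param tab tidy table with columns `algorithm`, `condition`, `scale`,
#'   `value`, `defined` (as produced by the `run_*_experiment` functions).
#' @return data.frame with per-(algorithm, condition, scale) `mean`, `sd`
#'   and `n_defined`, computed over replicates with defined values.
#' @export
summarize_ensemble <- function(tab) {
  key <- interaction(tab$algorithm, tab$condition, tab$scale, drop = TRUE)
  parts <- split(tab, key)
  out <- lapply(parts, function(d) {
    v <- d$value[d$defined]
    data.frame(algorithm = d$algorithm[1], condition = d$condition[1],
               scale = d$scale[1],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n_defined = length(v))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$algorithm, out$condition, out$scale), ]
}

#' Complexity experiment: 1/f versus white-noise channel composition
#'
#' Three-channel signals with 3, 2, 1 or 0 channels of 1/f noise (the
#' remainder white Gaussian noise), all channels mutually independent.
#' Structurally, multivariate 1/f noise is more complex than multivariate
#' white noise, so estimators sensitive to long-range correlation order
#' the four conditions by 1/f channel count at scales above 1.
#'
#' @param spec an [experiment_spec()] (`"complexity"`).
#' @return tidy table: `algorithm`, `condition` (`"pink3"` .. `"pink0"`),
#'   `replicate`, `seed`, `scale`, `value`, `defined`.
#' @export
run_complexity_experiment <- function(spec = experiment_spec("complexity")) {
  stopifnot(inherits(spec, "experiment_spec"))
  tabs <- lapply(0:3, function(np) {
    gen <- function(sd_j) withr::with_seed(sd_j, {
      chans <- c(replicate(np, pink_channel(spec$length), simplify = FALSE),
                 replicate(3L - np, rnorm(spec$length), simplify = FALSE))
      do.call(rbind, chans)
    })
    curve_table(spec, np + 1L, paste0("pink", np), gen)
  })
  do.call(rbind, tabs)
}

#' Correlation experiment: correlated versus uncorrelated channel pairs
#'
#' Two-channel 1/f and white-noise signals, each with inter-channel
#' correlation `rho` (default 0.95) or 0.
#'
#' @param spec an [experiment_spec()] (`"correlation"`).
#' @return tidy table with conditions `"pink_corr"`, `"pink_uncorr"`,
#'   `"wgn_corr"`, `"wgn_uncorr"`.
#' @export
run_correlation_experiment <- function(spec = experiment_spec("correlation")) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- expand.grid(kind = c("pink", "wgn"), corr = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(grid)), function(ci) {
    kind <- grid$kind[ci]
    rho <- if (grid$corr[ci]) spec$rho else 0
    cond <- paste0(kind, if (grid$corr[ci]) "_corr" else "_uncorr")
    gen <- function(sd_j)
      gen_correlated_pair(kind, rho, spec$length, seed = sd_j)
    curve_table(spec, ci, cond, gen)
  })
  do.call(rbind, tabs)
}

#' Joint coupling/complexity experiment on the coupled-MIX model
#'
#' For each probability setting and each coupling coefficient `C` on the
#' grid, generates two-channel coupled-MIX signals and reports, per
#' algorithm and replicate, the multi-channel entropy and the
#' single-channel (channel A alone) entropy, both at scale 1 (or the mean
#' over scales `1..max_scale` when `spec$coupling_scale = "scale_mean"`).
#'
#' @param spec an [experiment_spec()] (`"coupling"`).
#' @return tidy table: `algorithm`, `p0`, `p1`, `p2`, `C`, `replicate`,
#'   `seed`, `multi_value`, `single_value`.
#' @export
run_joint_coupling_experiment <- function(spec = experiment_spec("coupling")) {
  stopifnot(inherits(spec, "experiment_spec"))
  triples <- spec$p_triples
  if (is.null(triples))
    triples <- lapply(spec$p_grid, function(p) c(p, p, p))
  grid <- expand.grid(ti = seq_along(triples), C = spec$C_grid)
  use_mean <- identical(spec$coupling_scale, "scale_mean")
  max_s <- if (use_mean) spec$max_scale else 1L
  out <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    tr <- triples[[grid$ti[ci]]]
    pars_cm <- coupled_mix_params(tr[1], tr[2], tr[3], grid$C[ci],
                                  spec$length, spec$fs)
    rows <- vector("list", spec$reps)
    for (j in seq_len(spec$reps)) {
      sd_j <- cond_seed(spec$seed, ci, j)
      x <- gen_coupled_mix(pars_cm, seed = sd_j)
      vals <- lapply(spec$algorithms, function(a) {
        pp <- default_entropy_params(a, max_scale = max_s)
        mc <- multiscale_curve(x, a, pp)
        sc <- multiscale_curve(x[1L, , drop = FALSE], a, pp)
        data.frame(algorithm = a, p0 = tr[1], p1 = tr[2], p2 = tr[3],
                   C = grid$C[ci], replicate = j, seed = sd_j,
                   multi_value = mean(mc$value[mc$defined]),
                   single_value = mean(sc$value[sc$defined]))
      })
      rows[[j]] <- do.call(rbind, vals)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Noise-resistance experiment
#'
#' Coupled-MIX base signals (defaults C = 0.4, p0 = 0.2, p1 = 0.5,
#' p2 = 0.8) plus white Gaussian noise at each SNR level; the `"clean"`
#' condition is the noise-free model.
#'
#' @param spec an [experiment_spec()] (`"noise"`).
#' @return tidy table with conditions `"clean"`, `"snr+20"`, ...,
#'   `"snr-20"`.
#' @export
run_noise_experiment <- function(spec = experiment_spec("noise")) {
  stopifnot(inherits(spec, "experiment_spec"))
  pars_cm <- coupled_mix_params(spec$mix$p0, spec$mix$p1, spec$mix$p2,
                                spec$mix$C, spec$length, spec$fs)
  conds <- c(NA, spec$snr_grid)
  tabs <- lapply(seq_along(conds), function(ci) {
    snr <- conds[ci]
    cond <- if (is.na(snr)) "clean" else sprintf("snr%+d", as.integer(snr))
    gen <- function(sd_j) {
      x <- gen_coupled_mix(pars_cm, seed = sd_j)
      if (is.na(snr)) x else add_noise_at_snr(x, snr, seed = sd_j + 5000L)
    }
    curve_table(spec, ci, cond, gen)
  })
  do.call(rbind, tabs)
}

#' Data-length experiment
#'
#' Coupled-MIX signals (defaults C = 0.4, p0 = 0.2, p1 = 0.5, p2 = 0.8) at
#' each length of the grid. Scales default to 1..10 so the shortest grid
#' length supports every scale; lengths too short for a given scale are
#' recorded as undefined, never raised.
#'
#' @param spec an [experiment_spec()] (`"length"`).
#' @return tidy table with an extra column `N`; `condition` is `"N<len>"`.
#' @export
run_length_experiment <- function(spec = experiment_spec("length")) {
  stopifnot(inherits(spec, "experiment_spec"))
  tabs <- lapply(seq_along(spec$N_grid), function(ci) {
    N <- spec$N_grid[ci]
    pars_cm <- coupled_mix_params(spec$mix$p0, spec$mix$p1, spec$mix$p2,
                                  spec$mix$C, N, spec$fs)
    sp <- spec
    sp$length <- N
    tab <- curve_table(sp, ci, sprintf("N%d", N),
                       function(sd_j) gen_coupled_mix(pars_cm, seed = sd_j))
    tab$N <- N
    tab
  })
  do.call(rbind, tabs)
}

#' Smallest scale above which a strict ordering of mean curves holds
#'
#' Given per-condition ensemble-mean curves on a common scale grid and the
#' required ordering (largest first), returns the smallest `s*` such that
#' the strict ordering holds at every scale greater than `s*` (0 when it
#' holds everywhere), or `NA` when the ordering fails at the largest scale.
#'
#' @param mean_curves named list of numeric vectors (one mean value per
#'   scale, common grid).
#' @param ordering character vector of condition names, largest expected
#'   value first.
#' @return integer scale threshold, or `NA` if never satisfied.
#' @export
detect_ordering_threshold <- function(mean_curves, ordering) {
  if (!all(ordering %in% names(mean_curves)))
    stop("ordering names missing from mean_curves")
  lens <- vapply(mean_curves[ordering], length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("mean curves must share a common scale grid")
  mat <- do.call(cbind, mean_curves[ordering])
  ok <- apply(mat, 1L, function(v) all(diff(v) < 0))
  if (!ok[length(ok)]) return(NA_integer_)
  bad <- which(!ok)
  if (length(bad) == 0L) 0L else max(bad)
}

#' Coupling coefficient maximising the mean multi-channel entropy
#'
#' Grid argmax of the ensemble-mean multi-channel entropy over the
#' coupling grid of a [run_joint_coupling_experiment()] table; ties go to
#' the smaller coupling value.
#'
#' @param coupling_tab table from [run_joint_coupling_experiment()].
#' @param algorithm estimator whose values to maximise.
#' @return the coupling coefficient at the maximum.
#' @export
find_peak_coupling <- function(coupling_tab, algorithm) {
  algorithm <- match_algorithm(algorithm)
  d <- coupling_tab[coupling_tab$algorithm == algorithm, ]
  if (nrow(d) == 0L) stop("no rows for algorithm ", algorithm)
  means <- tapply(d$multi_value, d$C, mean, na.rm = TRUE)
  Cs <- as.numeric(names(means))
  ord <- order(Cs)
  Cs <- Cs[ord]; means <- means[ord]
  Cs[which.max(means)]  # which.max takes the first (smallest C) on ties
}

#' Smallest grid length at which the mean entropy stabilises
#'
#' Returns the smallest grid length `N*` such that the ensemble mean at
#' every `N >= N*` lies within `tol_fraction` of the mean at the largest
#' grid length, or `NA` when even the penultimate point is outside the
#' band.
#'
#' @param N sorted numeric vector of grid lengths.
#' @param means mean entropy per grid length.
#' @param tol_fraction relative tolerance (default 0.05).
#' @return grid length `N*`, or `NA`.
#' @export
find_stabilization_length <- function(N, means, tol_fraction = 0.05) {
  stopifnot(length(N) == length(means), !is.unsorted(N))
  ref <- means[length(means)]
  if (ref == 0) stop("reference mean at the largest length is zero")
  within <- abs(means - ref) <= tol_fraction * abs(ref)
  # smallest index from which all subsequent points are inside the band;
  # the final grid point qualifying alone (vacuously) does not count as
  # stabilisation
  ok_from <- rev(cumprod(rev(within))) > 0
  idx <- which(ok_from)[1L]
  if (is.na(idx) || idx == length(N)) return(NA_real_)
  N[idx]
}
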