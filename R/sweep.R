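#' Piecewise-constant demographic history
#'
#' Epochs run backward from the present in standard coalescent time units of
#' 2N0 generations (pair-coalescence rate 1 in a population of relative size
#' 1): with that scaling the expected TMRCA of a sample of two is 1 and, with
#' mutations dropped as Poisson(theta/2 x total branch length), E\[S\] =
#' theta * a1 and E\[pi\] = theta.
#'
#' @param start Epoch start times, strictly increasing from 0.
#' @param size Relative population sizes (> 0) per epoch.
#' @return data.frame of class `demography`.
#' @export
demography <- function(start, size) {
  if (length(start) != length(size)) stop("start and size lengths differ")
  if (start[1] != 0) stop("first epoch must start at time 0")
  if (is.unsorted(start, strictly = TRUE))
    stop("epoch times must be strictly increasing")
  if (any(size <= 0)) stop("relative sizes must be > 0")
  structure(data.frame(start = start, size = size),
            class = c("demography", "data.frame"))
}

#' Bottleneck demography
#'
#' Present-day relative size 1; a bottleneck of relative size `severity`
#' between `start` and `start + duration` (backward time, units of 2N0
#' generations); ancestral size 1 beyond.
#'
#' @param start Backward time at which the bottleneck begins.
#' @param duration Bottleneck duration.
#' @param severity Relative size during the bottleneck, in (0, 1].
#' @return A [demography()].
#' @export
bottleneck_demography <- function(start, duration, severity) {
  if (severity <= 0) stop("severity must be > 0")
  if (start < 0 || duration <= 0) stop("start >= 0 and duration > 0 required")
  if (start == 0)
    demography(c(0, duration), c(severity, 1))
  else
    demography(c(0, start, start + duration), c(1, severity, 1))
}

#' Simulate coalescent replicates under a piecewise-constant demography
#'
#' Hudson-style single-locus coalescent without recombination: waiting times
#' between coalescences are exponential with rate `C(k,2) / size(t)`,
#' rescaled across epoch boundaries; mutations are dropped on the genealogy
#' as Poisson(`theta/2` x total branch length) under the infinite-sites
#' model, uniformly over branches. Per replicate the segregating-site count
#' `S`, mean pairwise differences `pi` and total branch length are returned.
#'
#' @param n Sample size (haplotypes, >= 2).
#' @param demog A [demography()]; default constant size 1.
#' @param theta Scaled mutation rate 4 N0 mu per simulated window (> 0).
#' @param reps Number of replicates.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return data.frame with `S`, `pi`, `total_length` and `tmrca`, one row per
#'   replicate.
#' @export
simulate_coalescent <- function(n, demog = demography(0, 1), theta,
                                reps = 1L, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (theta <= 0) stop("theta must be > 0")
  if (!inherits(demog, "demography")) stop("demog must be a demography()")
  if (!is.null(seed)) set.seed(seed)
  ep_start <- demog$start
  ep_size <- demog$size
  n_ep <- length(ep_start)
  npairs <- n * (n - 1) / 2
  out_S <- out_pi <- out_len <- out_tmrca <- numeric(reps)
  for (r in seq_len(reps)) {
    # branch bookkeeping: per active lineage, number of descendants and
    # accumulated length; completed branches collect (desc, length)
    desc <- rep(1L, n)
    blen <- numeric(n)
    done_desc <- integer(2L * (n - 1L))
    done_len <- numeric(2L * (n - 1L))
    n_done <- 0L
    t_now <- 0
    ep <- 1L
    k <- n
    while (k > 1L) {
      rate <- k * (k - 1) / 2 / ep_size[ep]
      w <- stats::rexp(1L, rate)
      boundary <- if (ep < n_ep) ep_start[ep + 1L] else Inf
      if (t_now + w > boundary) {
        dt <- boundary - t_now
        blen[seq_len(k)] <- blen[seq_len(k)] + dt
        t_now <- boundary
        ep <- ep + 1L
        next
      }
      blen[seq_len(k)] <- blen[seq_len(k)] + w
      t_now <- t_now + w
      pair <- sample.int(k, 2L)
      i <- min(pair); j <- max(pair)
      done_desc[n_done + 1L] <- desc[i]; done_len[n_done + 1L] <- blen[i]
      done_desc[n_done + 2L] <- desc[j]; done_len[n_done + 2L] <- blen[j]
      n_done <- n_done + 2L
      desc[i] <- desc[i] + desc[j]
      blen[i] <- 0
      desc[j] <- desc[k]; blen[j] <- blen[k]
      k <- k - 1L
    }
    total_len <- sum(done_len[seq_len(n_done)])
    S <- stats::rpois(1L, theta / 2 * total_len)
    pi <- 0
    if (S > 0) {
      br <- sample.int(n_done, S, replace = TRUE,
                       prob = done_len[seq_len(n_done)])
      d <- done_desc[br]
      pi <- sum(d * (n - d)) / npairs
    }
    out_S[r] <- S
    out_pi[r] <- pi
    out_len[r] <- total_len
    out_tmrca[r] <- t_now
  }
  data.frame(S = out_S, pi = out_pi, total_length = out_len,
             tmrca = out_tmrca)
}

#' Expected pair-coalescence time under a piecewise-constant demography
#'
#' Closed form for the expected coalescence time of a pair of lineages
#' (units of 2N0 generations): integrating the piecewise-exponential
#' survival over the epochs gives
#' `E[T2] = sum_i x_i (1 - exp(-D_i/x_i)) prod_{j<i} exp(-D_j/x_j)`,
#' with `D_i` the epoch durations (the last infinite). Because any two
#' sampled lineages coalesce marginally as a pair, `theta * E[T2]` is the
#' expected pairwise diversity of a sample of any size, so the expected
#' diversity ratio between two demographies is the ratio of their `E[T2]`.
#'
#' @param demog A [demography()].
#' @return Expected pair-coalescence time.
#' @export
expected_pair_time <- function(demog) {
  starts <- demog$start
  sizes <- demog$size
  durations <- c(diff(starts), Inf)
  surv <- 1
  total <- 0
  for (i in seq_along(sizes)) {
    total <- total + surv * sizes[i] * (1 - exp(-durations[i] / sizes[i]))
    surv <- surv * exp(-durations[i] / sizes[i])
  }
  total
}

#' Calibrate bottleneck severity to a target diversity ratio
#'
#' Bisection on the bottleneck severity f in (0, 1] so that the ratio of
#' mean pi under the bottleneck demography to mean pi under the constant-size
#' demography (the genome-wide diversity ratio of the domesticate to its
#' wild progenitor) matches `target_ratio`. The expected ratio equals
#' `E[T2_bottleneck] / E[T2_constant]` ([expected_pair_time()]), which is
#' continuous and monotone in f, so the default `"analytic"` method bisects
#' the closed form and is free of Monte-Carlo error. The `"simulation"`
#' method instead bisects the ratio of mean pi over `reps` paired coalescent
#' replicates evaluated with common random seeds per step (a smooth monotone
#' estimate, exactly 1 at f = 1); it serves as an independent check of the
#' closed form.
#'
#' @param target_ratio Target ratio of mean diversities, in (0, 1).
#' @param bottleneck_start,bottleneck_duration Bottleneck epoch in coalescent
#'   units of 2N0 generations.
#' @param n Sample size per population.
#' @param theta Scaled mutation rate per window.
#' @param reps Replicates per ratio evaluation (simulation method).
#' @param tol Convergence tolerance on the achieved ratio.
#' @param seed Integer seed (simulation method).
#' @param method `"analytic"` (closed-form expected ratio) or
#'   `"simulation"` (paired Monte-Carlo evaluation).
#' @return List with `severity`, `achieved_ratio`, `demography` (the
#'   calibrated bottleneck [demography()]) and the evaluation settings.
#' @export
calibrate_bottleneck <- function(target_ratio, bottleneck_start = 0.08,
                                 bottleneck_duration = 0.04, n = 20L,
                                 theta = 20, reps = 2000L, tol = 0.01,
                                 seed = 1L,
                                 method = c("analytic", "simulation")) {
  method <- match.arg(method)
  if (target_ratio <= 0 || target_ratio > 1)
    stop("target_ratio must be in (0, 1]")
  if (target_ratio == 1)
    return(list(severity = 1, achieved_ratio = 1,
                demography = bottleneck_demography(bottleneck_start,
                                                   bottleneck_duration, 1),
                bottleneck_start = bottleneck_start,
                bottleneck_duration = bottleneck_duration,
                n = n, theta = theta, reps = reps))
  eval_ratio <- if (method == "analytic") {
    function(f)
      expected_pair_time(bottleneck_demography(bottleneck_start,
                                               bottleneck_duration, f))
  } else {
    function(f) {
      dem <- bottleneck_demography(bottleneck_start, bottleneck_duration, f)
      bot <- simulate_coalescent(n, dem, theta, reps, seed = seed)
      con <- simulate_coalescent(n, demography(0, 1), theta, reps,
                                 seed = seed)
      mean(bot$pi) / mean(con$pi)
    }
  }
  f_lo <- 1e-6
  r_lo <- eval_ratio(f_lo)
  if (target_ratio < r_lo)
    stop(sprintf(paste0("target ratio %.3f unreachable: attainable range ",
                        "is about [%.3f, 1] for this start/duration"),
                 target_ratio, r_lo))
  f_hi <- 1
  f <- NA_real_
  tol_use <- if (method == "analytic") min(tol, 1e-8) else tol
  for (it in seq_len(if (method == "analytic") 60L else 40L)) {
    f <- sqrt(f_lo * f_hi)  # bisect on log scale: ratio is log-sensitive
    r <- eval_ratio(f)
    if (abs(r - target_ratio) < tol_use) break
    if (r < target_ratio) f_lo <- f else f_hi <- f
  }
  list(severity = f, achieved_ratio = r,
       demography = bottleneck_demography(bottleneck_start,
                                          bottleneck_duration, f),
       bottleneck_start = bottleneck_start,
       bottleneck_duration = bottleneck_duration,
       n = n, theta = theta, reps = reps)
}

#' Empirical p-value for a diversity-ratio sweep test
#'
#' Simulates paired replicates (bottleneck vs constant size) of window pi and
#' ranks the observed ratio against the simulated per-replicate ratios:
#' `p = (1 + #\{ratio_sim <= ratio_obs\}) / (kept + 1)`. Replicates where the
#' constant-size window is monomorphic (pi = 0) are discarded and logged. A
#' small p indicates the observed window has less diversity in the
#' bottlenecked population than the bottleneck alone explains — the signature
#' of a local sweep.
#'
#' @param observed_ratio Observed pi ratio (>= 0).
#' @param demog_bottleneck Calibrated bottleneck [demography()].
#' @param n Sample size per population.
#' @param theta Scaled mutation rate per window (e.g. per 20-kb window).
#' @param reps Number of simulated replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `p`, `n_kept`, `n_discarded` and the simulated `ratios`.
#' @export
pi_ratio_test <- function(observed_ratio, demog_bottleneck, n = 20L,
                          theta = 20, reps = 100000L, seed = 1L) {
  if (observed_ratio < 0) stop("observed_ratio must be >= 0")
  if (reps < 100) stop("reps < 100 gives an unstable empirical p")
  set.seed(seed)
  bot <- simulate_coalescent(n, demog_bottleneck, theta, reps)
  con <- simulate_coalescent(n, demography(0, 1), theta, reps)
  keep <- con$pi > 0
  n_disc <- sum(!keep)
  if (n_disc > 0)
    message("pi_ratio_test: discarded ", n_disc,
            " replicates with monomorphic constant-size window")
  ratios <- bot$pi[keep] / con$pi[keep]
  p <- (1 + sum(ratios <= observed_ratio)) / (length(ratios) + 1)
  list(p = p, n_kept = length(ratios), n_discarded = n_disc, ratios = ratios)
}
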