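#' Draw random gLV parameters
#'
#' Growth rates and an interaction matrix with positive self-limitation on
#' the diagonal and sparse off-diagonal interactions: each off-diagonal entry
#' is non-zero with probability `connectance`, with magnitude drawn from a
#' half-normal with scale `interaction_sd` and a sign that is positive or
#' negative with equal probability.
#'
#' @param S number of taxa (>= 2).
#' @param connectance probability that an off-diagonal interaction is
#'   non-zero (0 < connectance <= 1; 0 gives a diagonal matrix).
#' @param interaction_sd half-normal scale of off-diagonal magnitudes.
#' @param seed RNG seed.
#' @param self_range range of the uniform self-limitation coefficients.
#' @param growth_range range of the uniform intrinsic growth rates.
#' @return list with `r` (length S) and `A` (S x S).
#' @export
sample_glv_params <- function(S, connectance = 0.3, interaction_sd = 0.5,
                              seed = 1L, self_range = c(0.8, 1.2),
                              growth_range = c(0.5, 1.5)) {
  if (S < 2) stop_("S must be at least 2")
  if (connectance < 0 || connectance > 1) stop_("connectance must lie in [0, 1]")
  with_seed_(seed, {
    r <- stats::runif(S, growth_range[1], growth_range[2])
    A <- matrix(0, S, S)
    off <- which(row(A) != col(A))
    present <- stats::runif(length(off)) < connectance
    mag <- abs(stats::rnorm(sum(present), 0, interaction_sd))
    sgn <- sample(c(-1, 1), sum(present), replace = TRUE)
    A[off[present]] <- sgn * mag
    diag(A) <- stats::runif(S, self_range[1], self_range[2])
    taxa <- sprintf("taxon%02d", seq_len(S))
    dimnames(A) <- list(taxa, taxa)
    names(r) <- taxa
    list(r = r, A = A)
  })
}

#' Integrate a gLV system with optional environmental noise
#'
#' Classical 4th-order Runge-Kutta integration with a fixed step given by the
#' spacing of `t_grid` (one step per grid interval; refine the grid for more
#' accuracy). After each step, multiplicative log-normal environmental noise
#' may be applied: each abundance is multiplied by
#' \eqn{\exp(\sigma \sqrt{\Delta t}\, z)}, z standard normal, so `noise_sd`
#' is a per-unit-time (diffusion-scaled) intensity. Abundances are floored at
#' 1e-12; integration aborts with an error if any abundance exceeds 1e6.
#'
#' @param r growth-rate vector.
#' @param A interaction matrix.
#' @param N0 positive initial abundances.
#' @param t_grid strictly increasing time grid; the trajectory is reported at
#'   every grid point.
#' @param noise_sd environmental noise intensity (0 = deterministic).
#' @param seed RNG seed (only relevant when `noise_sd > 0`).
#' @return matrix `length(t_grid)` x S of abundances, with `t_grid` as the
#'   `"times"` attribute.
#' @export
simulate_glv <- function(r, A, N0, t_grid, noise_sd = 0, seed = NULL) {
  S <- length(r)
  if (any(N0 <= 0)) stop_("N0 must be positive")
  if (any(diff(t_grid) <= 0)) stop_("t_grid must be strictly increasing")
  rhs <- function(N) N * (r - as.numeric(A %*% N))
  out <- matrix(NA_real_, length(t_grid), S)
  colnames(out) <- names(r)
  out[1, ] <- N <- as.numeric(N0)
  with_seed_(seed, {
    for (i in seq_along(t_grid)[-1]) {
      h <- t_grid[i] - t_grid[i - 1]
      k1 <- rhs(N)
      k2 <- rhs(N + h / 2 * k1)
      k3 <- rhs(N + h / 2 * k2)
      k4 <- rhs(N + h * k3)
      N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (noise_sd > 0)
        N <- N * exp(stats::rnorm(S, 0, noise_sd * sqrt(h)))
      N <- pmax(N, 1e-12)
      if (any(N > 1e6))
        stop_(sprintf("trajectory blew up (N > 1e6) at t = %g", t_grid[i]))
      out[i, ] <- N
    }
  })
  attr(out, "times") <- t_grid
  out
}

#' Multinomial sequencing counts from relative abundances
#'
#' @param rel probability vector (sums to 1).
#' @param depth sequencing depth (total reads).
#' @param seed RNG seed.
#' @return integer count vector summing to `depth`.
#' @export
counts_from_abundance <- function(rel, depth, seed = NULL) {
  if (abs(sum(rel) - 1) > 1e-8) stop_("rel must sum to 1")
  cnt <- with_seed_(seed, as.integer(stats::rmultinom(1, depth, rel)))
  names(cnt) <- names(rel)
  cnt
}

#' Synthetic two-regime sediment-core scenario
#'
#' Generates a ground-truth critical transition emulating the shape of a
#' dated sediment-core community record: two guilds of taxa compete under a
#' slowly ramping environmental driver that lowers the resident guild's
#' growth rates while raising the challenger's. The resident equilibrium's
#' dominant eigenvalue rises towards zero until the challenger invades and
#' the community flips abruptly to the alternative regime. The dense latent
#' trajectory is subsampled at `n_samples` stratigraphic ages, converted to
#' relative abundance, topped up with an "unclassified" background fraction,
#' and sequenced by multinomial draws at the given depth.
#'
#' @param S number of modeled taxa (split into two guilds; default 12).
#' @param n_samples number of core sub-samples (default 35).
#' @param depth sequencing depth per sample (default 20000 reads).
#' @param seed RNG seed; the whole scenario is reproducible from it.
#' @param age_range calendar ages (years CE) of the record ends.
#' @param noise_sd environmental noise intensity per sqrt(year).
#' @param background relative abundance assigned to the pooled unclassified
#'   background (default 0.2, leaving the modeled taxa ~80% of reads).
#' @param transition if FALSE the driver is held at its initial value and a
#'   stationary single-regime record is produced (ground-truth transition
#'   time `NA`).
#' @param dt integration step in years.
#' @return object of class `synthetic_scenario`: `table` (a [taxon_table] of
#'   counts including the unclassified column), `rel_abund` (sampled true
#'   relative abundances), `truth` (list: `transition_time`, realized flip of
#'   guild dominance; `threshold_time`, where the resident equilibrium loses
#'   linear stability; `regime` labels per sample; `r_fun`, `A`, `guilds`),
#'   `trajectory` (dense latent abundances), `t_grid`, `sample_times`,
#'   `params` (call settings).
#' @export
transition_scenario <- function(S = 12, n_samples = 35, depth = 20000,
                                seed = 1L, age_range = c(1200, 2010),
                                noise_sd = 0.03, background = 0.2,
                                transition = TRUE, dt = 0.5) {
  if (n_samples < 20) stop_("need at least 20 samples")
  if (S < 4 || S %% 2 != 0) stop_("S must be an even number >= 4")
  half <- S / 2
  gA <- seq_len(half); gB <- half + seq_len(half)
  t0 <- age_range[1]; t1 <- age_range[2]
  span <- t1 - t0
  with_seed_(seed, {
    # Interaction matrix: self-limitation, weak within-guild competition,
    # strong between-guild competition (bistable at guild level).
    A <- matrix(0, S, S)
    within <- 0.03; between_on_A <- 0.22; between_on_B <- 0.22
    for (i in seq_len(S)) for (j in seq_len(S)) {
      if (i == j) next
      same <- (i <= half) == (j <= half)
      A[i, j] <- if (same) within else if (i <= half) between_on_A else between_on_B
    }
    diag(A) <- 0.75
    A <- A * matrix(stats::runif(S * S, 0.85, 1.15), S, S)
    taxa <- sprintf("class%02d", seq_len(S))
    dimnames(A) <- list(taxa, taxa)
    # Driver: the environment progressively hurts the resident guild and
    # favours the challenger (growth rates in 1/year at decadal resolution).
    jitA <- stats::runif(half, 0.9, 1.1); jitB <- stats::runif(half, 0.9, 1.1)
    rA0 <- 0.30; rA1 <- if (transition) 0.02 else 0.30
    rB0 <- 0.10; rB1 <- if (transition) 0.55 else 0.10
    r_fun <- function(t) {
      f <- (t - t0) / span
      c(jitA * (rA0 + (rA1 - rA0) * f), jitB * (rB0 + (rB1 - rB0) * f))
    }
    t_grid <- seq(t0, t1, by = dt)
    # start at the resident-only equilibrium, challenger rare
    N0A <- as.numeric(solve(A[gA, gA], jitA * rA0))
    N <- c(pmax(N0A, 1e-3), rep(1e-3, half))
    traj <- matrix(NA_real_, length(t_grid), S, dimnames = list(NULL, taxa))
    traj[1, ] <- N
    for (i in seq_along(t_grid)[-1]) {
      h <- t_grid[i] - t_grid[i - 1]
      r_now <- r_fun((t_grid[i] + t_grid[i - 1]) / 2)
      rhs <- function(Nv) Nv * (r_now - as.numeric(A %*% Nv))
      k1 <- rhs(N); k2 <- rhs(N + h / 2 * k1)
      k3 <- rhs(N + h / 2 * k2); k4 <- rhs(N + h * k3)
      N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (noise_sd > 0) N <- N * exp(stats::rnorm(S, 0, noise_sd * sqrt(h)))
      N <- pmax(N, 1e-12)
      if (any(N > 1e6)) stop_("scenario trajectory blew up")
      traj[i, ] <- N
    }
    XA <- rowSums(traj[, gA, drop = FALSE])
    XB <- rowSums(traj[, gB, drop = FALSE])
    flip <- which(XB > XA)[1]
    if (transition && is.na(flip))
      stop_("scenario failed to transition (driver too weak)")
    transition_time <- if (transition) t_grid[flip] else NA_real_
    # time at which the resident equilibrium loses linear stability:
    # challenger invasion rate r_B(t) - a_BA * X_A*(t) crosses zero
    thr <- NA_real_
    if (transition) {
      inv <- vapply(t_grid, function(tt) {
        rr <- r_fun(tt)
        NAstar <- tryCatch(solve(A[gA, gA], rr[gA]), error = function(e) rep(0, half))
        NAstar <- pmax(NAstar, 0)
        max(rr[gB] - as.numeric(A[gB, gA, drop = FALSE] %*% NAstar))
      }, 0)
      cross <- which(inv > 0)[1]
      thr <- if (!is.na(cross)) t_grid[cross] else NA_real_
    }
    # subsample at the core ages, add unclassified background, sequence
    sample_times <- seq(t0, t1, length.out = n_samples)
    idx <- vapply(sample_times, function(tt) which.min(abs(t_grid - tt)), 1L)
    relS <- traj[idx, , drop = FALSE] / rowSums(traj[idx, , drop = FALSE])
    bg <- background * stats::runif(n_samples, 0.9, 1.1)
    rel <- cbind(relS * (1 - bg), unclassified = bg)
    rel <- rel / rowSums(rel)
    counts <- t(vapply(seq_len(n_samples), function(i)
      as.integer(stats::rmultinom(1, depth, rel[i, ])), integer(S + 1)))
    dimnames(counts) <- list(sprintf("s%02d", seq_len(n_samples)), colnames(rel))
    chron <- data.frame(sample_id = rownames(counts),
                        depth_cm = round(seq(137, 0, length.out = n_samples), 1),
                        age_year_ce = sample_times)
    taxonomy <- c(sprintf("k__Bacteria; p__synthetic; c__%s", taxa), "")
    tab <- taxon_table(counts, chron, taxonomy = taxonomy)
    regime <- if (transition) ifelse(sample_times < transition_time, 1L, 2L)
              else rep(1L, n_samples)
    structure(list(table = tab, rel_abund = rel,
                   truth = list(transition_time = transition_time,
                                threshold_time = thr,
                                regime = regime, r_fun = r_fun, A = A,
                                guilds = list(resident = taxa[gA],
                                              challenger = taxa[gB])),
                   trajectory = traj, t_grid = t_grid,
                   sample_times = sample_times, sample_idx = idx,
                   params = list(S = S, n_samples = n_samples, depth = depth,
                                 seed = as.integer(seed), age_range = age_range,
                                 noise_sd = noise_sd, background = background,
                                 transition = transition, dt = dt)),
              class = "synthetic_scenario")
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic scenario: S = %d taxa + background, %d samples, depth %d\n",
              p$S, p$n_samples, p$depth))
  if (is.na(x$truth$transition_time)) {
    cat("  single-regime (no transition)\n")
  } else {
    cat(sprintf("  true transition (guild flip) at %.0f CE; stability threshold at %.0f CE\n",
                x$truth$transition_time, x$truth$threshold_time))
    cat(sprintf("  regime sizes: %d | %d samples\n",
                sum(x$truth$regime == 1), sum(x$truth$regime == 2)))
  }
  invisible(x)
}

#' Latent community state series of a scenario
#'
#' Returns the scenario's one-dimensional community state
#' \eqn{\log(X_{resident})} (log total abundance of the resident guild),
#' sampled at `n` equally spaced times between the record start and `until`.
#' This is the natural variable in which critical slowing down appears as the
#' resident guild's equilibrium deteriorates, and is used to study
#' early-warning signals at higher temporal resolution than the 35 core
#' samples provide.
#'
#' @param scenario a `synthetic_scenario`.
#' @param n number of points (default 80).
#' @param until end of the sampled period; defaults to the true transition
#'   time (minus nothing) for transition scenarios, the record end otherwise.
#' @return data frame with columns `time` and `state`.
#' @export
scenario_state_series <- function(scenario, n = 80, until = NULL) {
  until <- until %||% (if (is.na(scenario$truth$transition_time))
    max(scenario$t_grid) else scenario$truth$transition_time)
  times <- seq(min(scenario$t_grid), until, length.out = n)
  idx <- vapply(times, function(tt) which.min(abs(scenario$t_grid - tt)), 1L)
  res <- scenario$truth$guilds$resident
  XA <- rowSums(scenario$trajectory[idx, res, drop = FALSE])
  data.frame(time = scenario$t_grid[idx], state = log(XA))
}

#' Ground-truth parameter-recovery experiment
#'
#' Generates a small community with known gLV parameters and a sequenced
#' near-equilibrium data set designed for benchmarking the ridge estimator:
#' a stable S-taxon system (self-limitation 0.3, off-diagonal interaction
#' magnitudes uniform in `mag_range` with balanced random signs, equilibrium
#' chosen interior with total abundance ~1) observed over `n_episodes`
#' perturbation-relaxation episodes - each starts from the equilibrium
#' perturbed by up to `pert` log-units and relaxes back - of `len_episode`
#' samples each, with environmental noise and multinomial sequencing noise on
#' top of a constant unmodeled background taxon (so that modeled proportions
#' are proportions of the whole community, not renormalized to 1). The
#' episodes are pooled into one regression via the `episodes` argument of
#' [glv()].
#'
#' @param seed RNG seed.
#' @param S number of taxa (default 3).
#' @param n_episodes,len_episode number and length of episodes (default
#'   6 x 10 = 60 samples).
#' @param depth sequencing depth (default 50000).
#' @param noise_sd environmental noise intensity (default 0.01).
#' @param mag_range range of off-diagonal interaction magnitudes.
#' @param pert maximum log-perturbation of episode starts (default 0.6).
#' @param delta sampling interval within an episode (time units).
#' @param h integration step.
#' @return list with `truth` (`r`, `A`), `observed` (samples x S matrix of
#'   community proportions), `ages`, `episodes`, and `fit` inputs ready for
#'   [glv()].
#' @export
recovery_experiment <- function(seed = 1L, S = 3, n_episodes = 6,
                                len_episode = 10, depth = 50000,
                                noise_sd = 0.01, mag_range = c(0.1, 0.3),
                                pert = 0.6, delta = 2.5, h = 0.25) {
  with_seed_(seed, {
    repeat {
      mag <- matrix(stats::runif(S * S, mag_range[1], mag_range[2]) *
                      sample(c(-1, 1), S * S, replace = TRUE), S, S)
      A <- mag; diag(A) <- 0.3
      Nstar <- seq(0.30, 0.37, length.out = S) / mean(seq(0.30, 0.37, length.out = S)) / S
      r <- as.numeric(A %*% Nstar)
      if (all(r > 0) &&
          max(Re(eigen(-diag(Nstar) %*% A, only.values = TRUE)$values)) < -0.05)
        break
    }
    taxa <- sprintf("taxon%02d", seq_len(S))
    dimnames(A) <- list(taxa, taxa); names(r) <- taxa
    Nmat <- NULL; ep <- integer(0); tt <- numeric(0)
    for (e in seq_len(n_episodes)) {
      N0 <- Nstar * exp(stats::runif(S, -pert, pert))
      tg <- seq(0, len_episode * delta, by = h)
      traj <- simulate_glv(r, A, N0, tg, noise_sd = noise_sd)
      idx <- vapply(seq_len(len_episode) * delta,
                    function(t) which.min(abs(tg - t)), 1L)
      Nmat <- rbind(Nmat, traj[idx, , drop = FALSE])
      ep <- c(ep, rep(e, len_episode))
      tt <- c(tt, seq_len(len_episode) * delta)
    }
    background <- 1.0
    p_full <- cbind(Nmat, background) / rowSums(cbind(Nmat, background))
    counts <- t(vapply(seq_len(nrow(p_full)), function(i)
      as.integer(stats::rmultinom(1, depth, p_full[i, ])), integer(S + 1)))
    p_obs <- counts[, seq_len(S), drop = FALSE] / rowSums(counts)
    colnames(p_obs) <- taxa
    list(truth = list(r = r, A = A, equilibrium = Nstar),
         observed = p_obs, ages = tt, episodes = ep,
         params = list(seed = as.integer(seed), S = S, depth = depth,
                       noise_sd = noise_sd, n_episodes = n_episodes,
                       len_episode = len_episode, delta = delta, pert = pert))
  })
}

#' Write a synthetic scenario to disk
#'
#' Emits the count table and chronology in the TSV formats
#' [read_taxon_table()] consumes, plus a JSON ground-truth sidecar
#' (transition time, regime labels, guilds, parameters).
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if missing).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(table = file.path(dir, "community_table.tsv"),
             chronology = file.path(dir, "chronology.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_taxon_table(scenario$table, paths["table"], paths["chronology"],
                    seed = scenario$params$seed)
  truth <- scenario$truth
  sidecar <- list(transition_time = truth$transition_time,
                  threshold_time = truth$threshold_time,
                  regime = truth$regime,
                  guilds = truth$guilds,
                  A = truth$A,
                  params = scenario$params)
  jsonlite::write_json(sidecar, paths["truth"], auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(paths)
}
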