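# Simulated annealing over assignment states: Metropolis sampling through
# the compiled kernel, Student-t equilibration testing, specific-heat-guided
# cooling, and post-anneal greedy minimization. Crosspeak draws happen in
# the kernel at the configured per-attempt probability; eligible draws
# suspend the kernel and the exchange move is evaluated at the R level.

#' Annealing schedule parameters
#'
#' Defaults follow the standard schedule: start at T = 1000, target an
#' ensemble energy drop of -2000 per cooling step, cap any single
#' temperature decrease at 10 units, require a two-sample t-test p-value
#' above 0.5 to declare equilibration, draw 1% of proposals as crosspeak
#' moves, size samples as `min(max(N * Cv^1.5 / 300, 1e4), 1e5)`, and stop
#' when T < 1, T*Cv < 200 or the failed/successful swap ratio of the last
#' sample exceeds 10000. The final state is refined by 100 greedy
#' minimization sweeps.
#'
#' @param t0 Initial temperature.
#' @param delta_e_target Target mean-energy drop per cooling step
#'   (negative).
#' @param max_t_step Largest allowed temperature decrease.
#' @param p_equil Equilibration p-value threshold.
#' @param crosspeak_move_prob Probability that a proposal is a crosspeak
#'   move rather than a spin-system move.
#' @param s_divisor,s_exponent,s_floor,s_ceiling Sample-size rule
#'   constants.
#' @param t_min,tcv_min,fail_ratio Termination thresholds.
#' @param n_minimize Number of post-anneal minimization sweeps.
#' @param welch Use Welch's t-test instead of the pooled-variance
#'   Student's test.
#' @param use_peak_cache Allow low-intensity crosspeaks (lowest 5% of
#'   their list) to be parked in a crosspeak cache.
#' @param attempts_factor Per-sample proposal budget, as a multiple of the
#'   sample size (bounds stalled sampling).
#' @param max_samples_per_t Upper bound on samples drawn at one
#'   temperature.
#' @param max_t_steps Safety bound on the number of cooling steps.
#' @return Object of class `annealing_params`.
#' @export
annealing_params <- function(t0 = 1000, delta_e_target = -2000,
                             max_t_step = 10, p_equil = 0.5,
                             crosspeak_move_prob = 0.01,
                             s_divisor = 300, s_exponent = 1.5,
                             s_floor = 10000, s_ceiling = 100000,
                             t_min = 1, tcv_min = 200, fail_ratio = 10000,
                             n_minimize = 100, welch = FALSE,
                             use_peak_cache = FALSE,
                             attempts_factor = 50, max_samples_per_t = 12,
                             max_t_steps = 1000) {
  stopifnot(t0 > 0, delta_e_target < 0, max_t_step > 0, p_equil > 0,
            s_floor >= 2, s_ceiling >= s_floor, t_min > 0, tcv_min > 0,
            fail_ratio > 0, n_minimize >= 0)
  structure(as.list(environment()), class = "annealing_params")
}

#' Metropolis acceptance decision
#'
#' Accepts every downhill proposal; an uphill proposal of size `delta_e`
#' is accepted with probability `exp(-delta_e / temperature)`.
#'
#' @param delta_e Proposed energy change.
#' @param temperature Current temperature (> 0).
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!(temperature > 0)) stop("temperature must be positive")
  delta_e <= 0 || stats::runif(1) < exp(-delta_e / temperature)
}

#' Specific-heat estimate from an energy sample
#'
#' `d<E>/dT = (<E^2> - <E>^2) / T^2` with population (divide-by-n)
#' moments; at the sample sizes used the n vs n-1 distinction is
#' negligible.
#'
#' @param sample Numeric vector of post-swap energies.
#' @param temperature Current temperature.
#' @return Non-negative specific heat.
#' @export
specific_heat <- function(sample, temperature) {
  stopifnot(temperature > 0, length(sample) >= 1)
  (mean(sample^2) - mean(sample)^2) / temperature^2
}

#' Next temperature of the cooling schedule
#'
#' `T_next = T + delta_e_target / Cv`, with the decrease capped at
#' `max_t_step` (10 by default) to avoid overcooling; a vanishing specific
#' heat applies the cap.
#'
#' @param temperature Current temperature.
#' @param cv Specific-heat estimate (>= 0).
#' @param params [annealing_params()].
#' @return The next temperature.
#' @export
next_temperature <- function(temperature, cv, params = annealing_params()) {
  stopifnot(cv >= 0)
  drop <- if (cv > 0) -params$delta_e_target / cv else Inf
  temperature - min(drop, params$max_t_step)
}

#' Next equilibration sample size
#'
#' `S = min(max(N * (dE/dT)^1.5 / 300, 10000), 100000)`: more sampling at
#' temperatures with high specific heat, scaled with protein size.
#'
#' @param n_residues Number of residues.
#' @param dedt Specific-heat estimate (>= 0).
#' @param params [annealing_params()].
#' @return Integer sample size.
#' @export
next_sample_size <- function(n_residues, dedt, params = annealing_params()) {
  stopifnot(n_residues >= 1, dedt >= 0)
  as.integer(round(min(max(n_residues * dedt^params$s_exponent /
                             params$s_divisor, params$s_floor),
                       params$s_ceiling)))
}

# two-tailed two-sample t-test p-value; pooled Student by default.
# Degenerate zero-variance samples get p = 1 (equal means) or 0.
t_test_p <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(1)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) return(as.numeric(mx == my))
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    tt <- (mx - my) / sqrt(se2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 == 0) return(as.numeric(mx == my))
    tt <- (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  2 * stats::pt(-abs(tt), df)
}

# ---- state <-> kernel index conversion (R is 1-based/NA, kernel 0-based/-1)
to_k <- function(x) {
  x <- as.integer(x) - 1L
  x[is.na(x)] <- -1L
  x
}
from_k <- function(x) {
  x <- as.integer(x)
  x[x < 0L] <- NA_integer_
  x + 1L
}

placeable_mask <- function(problem) {
  strsplit(problem$sequence, "")[[1]] != "P"
}

legal_instances <- function(problem, m, n) {
  which(is.finite(problem$ecs[problem$offset[m] + seq_len(problem$I[m]), n]))
}

# random initial state: spin systems shuffled onto shuffled placeable
# positions (random legal type set each); excess systems go to the cache
init_state <- function(problem) {
  M <- length(problem$systems)
  pos <- rep(NA_integer_, M)
  ts <- rep(1L, M)
  res2ss <- rep(NA_integer_, problem$n_res)
  slots <- which(placeable_mask(problem))
  slots <- if (length(slots) > 1) sample(slots) else slots
  si <- 1L
  for (m in sample.int(M)) {
    if (si > length(slots)) break
    n <- slots[si]
    ii <- legal_instances(problem, m, n)
    if (!length(ii)) next
    ts[m] <- if (length(ii) == 1L) ii else sample(ii, 1L)
    pos[m] <- n
    res2ss[n] <- m
    si <- si + 1L
  }
  st <- list(problem = problem, pos = pos, ts = ts, res2ss = res2ss,
             peak_cache = integer(0), energy = NA_real_)
  st$energy <- table_energy(problem, st$res2ss, st$ts)
  class(st) <- "assignment_state"
  st
}

run_kernel <- function(state, temperature, target_succ, max_attempts,
                       peak_prob = 0, peak_elig = logical(0)) {
  pr <- state$problem
  res <- mc_chunk(to_k(state$pos), state$ts - 1L, to_k(state$res2ss),
                  state$energy, pr$ecs, pr$adj, pr$offset_i, pr$I_i,
                  pr$placeable, temperature, as.integer(target_succ),
                  max_attempts, peak_prob, peak_elig)
  state$pos <- from_k(res$pos)
  state$ts <- res$ts + 1L
  state$res2ss <- from_k(res$res2ss)
  state$energy <- res$energy
  list(state = state, energies = res$energies, succ = res$succ,
       fail = res$fail, attempts = res$attempts,
       peak_request = res$peak_request)
}

# eligibility of every crosspeak for an exchange move in the current state
peak_eligibility <- function(state, params) {
  pr <- state$problem
  elig <- logical(length(pr$peaks))
  elig[pr$exch_peaks] <- TRUE
  if (isTRUE(params$use_peak_cache)) {
    elig[pr$cacheable & pr$owner > 0L] <- TRUE
    elig[state$peak_cache] <- TRUE
  }
  elig
}

has_exchangeable <- function(problem, params) {
  length(problem$exch_peaks) > 0L ||
    (isTRUE(params$use_peak_cache) && any(problem$cacheable))
}

# one sample of up to `s` post-swap energies at fixed temperature. The
# kernel draws crosspeak moves at the configured per-attempt probability
# and suspends only when an eligible peak is drawn; the move is then
# evaluated here.
collect_sample <- function(state, temperature, s, params) {
  exch <- has_exchangeable(state$problem, params)
  peak_prob <- if (exch) params$crosspeak_move_prob else 0
  energies <- numeric(s)
  succ <- 0L; fail <- 0; attempts <- 0
  max_att <- params$attempts_factor * s
  elig <- if (exch) peak_eligibility(state, params) else logical(0)
  while (succ < s && attempts < max_att) {
    res <- run_kernel(state, temperature, s - succ, max_att - attempts,
                      peak_prob, elig)
    state <- res$state
    if (res$succ > 0) energies[succ + seq_len(res$succ)] <- res$energies
    succ <- succ + res$succ
    fail <- fail + res$fail
    attempts <- attempts + res$attempts
    if (res$peak_request > 0 && succ < s && attempts < max_att) {
      pm <- attempt_peak_move(state, temperature, params,
                              g = res$peak_request)
      state <- pm$state
      attempts <- attempts + 1
      if (pm$accepted) {
        succ <- succ + 1L
        energies[succ] <- state$energy
        if (isTRUE(params$use_peak_cache))
          elig <- peak_eligibility(state, params)
      } else fail <- fail + 1
    } else if (res$peak_request == 0 && res$succ == 0 && res$attempts == 0) {
      break  # kernel found no element with a legal move
    }
  }
  list(state = state, energies = energies[seq_len(succ)], succ = succ,
       fail = fail, attempts = attempts)
}

#' Run one simulated annealing trajectory
#'
#' Initializes a random assignment at `t0`, alternates equilibration
#' (consecutive energy samples compared by a two-tailed Student's t-test)
#' with specific-heat-guided cooling, stops on the termination criteria,
#' and finishes with greedy local minimization. Deterministic for a fixed
#' seed.
#'
#' @param problem An [anneal_problem()].
#' @param params [annealing_params()].
#' @param seed Integer seed (optional; uses the current RNG state if
#'   `NULL`).
#' @return Object of class `assignment_state`: fields `pos`, `ts`,
#'   `res2ss`, `energy`, `trace` (one row per temperature), `problem`
#'   (possibly with exchanged crosspeaks).
#' @export
run_annealing <- function(problem, params = annealing_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(problem)
  temperature <- params$t0
  s <- params$s_floor
  trace <- list()
  tcv_armed <- FALSE
  for (step in seq_len(params$max_t_steps)) {
    last <- collect_sample(state, temperature, s, params)
    state <- last$state
    nsamp <- 1L
    while (length(last$energies) >= 2 && nsamp < params$max_samples_per_t) {
      nxt <- collect_sample(state, temperature, s, params)
      state <- nxt$state
      nsamp <- nsamp + 1L
      p <- if (length(nxt$energies) >= 2)
        t_test_p(last$energies, nxt$energies, params$welch) else 1
      last <- nxt
      if (p > params$p_equil) break
    }
    samp <- last$energies
    cv <- if (length(samp)) specific_heat(samp, temperature) else 0
    ratio <- if (last$succ > 0) last$fail / last$succ else Inf
    t_next <- next_temperature(temperature, cv, params)
    trace[[step]] <- data.frame(
      temperature = temperature, mean_energy = mean(samp), cv = cv,
      sample_size = s, samples = nsamp, succ = last$succ, fail = last$fail,
      acceptance = last$succ / max(last$succ + last$fail, 1))
    # the T*Cv criterion estimates the energy separating the ensemble
    # from the ground state; it is informative only after the ordering
    # transition, so it is armed with hysteresis once T*Cv has clearly
    # exceeded the threshold (small problems start below it at T0, where
    # the quantity says nothing about convergence)
    if (t_next * cv >= 2 * params$tcv_min) tcv_armed <- TRUE
    if (t_next < params$t_min ||
        (tcv_armed && t_next * cv < params$tcv_min) ||
        ratio > params$fail_ratio) break
    s <- next_sample_size(problem$n_res, cv, params)
    temperature <- t_next
  }
  state <- local_minimize(state, params)
  state$trace <- do.call(rbind, trace)
  state
}

# post-anneal steepest-descent refinement: kernel sweeps over spin-system
# placements interleaved with crosspeak exchange passes
local_minimize <- function(state, params) {
  pr <- state$problem
  exch <- has_exchangeable(pr, params)
  if (!exch) {
    res <- min_sweeps(to_k(state$pos), state$ts - 1L, to_k(state$res2ss),
                      state$energy, pr$ecs, pr$adj, pr$offset_i, pr$I_i,
                      pr$placeable, as.integer(params$n_minimize))
    state$pos <- from_k(res$pos)
    state$ts <- res$ts + 1L
    state$res2ss <- from_k(res$res2ss)
    state$energy <- res$energy
    return(state)
  }
  for (rep in seq_len(max(params$n_minimize, 1L))) {
    pr <- state$problem
    e0 <- state$energy
    res <- min_sweeps(to_k(state$pos), state$ts - 1L, to_k(state$res2ss),
                      state$energy, pr$ecs, pr$adj, pr$offset_i, pr$I_i,
                      pr$placeable, 1L)
    state$pos <- from_k(res$pos)
    state$ts <- res$ts + 1L
    state$res2ss <- from_k(res$res2ss)
    state$energy <- res$energy
    state <- peak_min_pass(state, params)
    if (state$energy > e0 - 1e-9) break
  }
  state
}

#' @export
print.assignment_state <- function(x, ...) {
  cat("<assignment_state> energy ", format(x$energy, digits = 8), "; ",
      sum(!is.na(x$pos)), "/", length(x$pos),
      " spin systems placed\n", sep = "")
  invisible(x)
}
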