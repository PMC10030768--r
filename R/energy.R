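# Pseudo-energy of an assignment state. Each placed spin system contributes
# an adjacency energy (inverted Gaussians over the match between its CA/CB/CO
# means and the CA(i-1)/CB(i-1)/CO(i-1) means of the spin system at the next
# residue) plus a chemical-shift energy derived from the Bayesian posterior
# probability of the placement given predicted shifts.

#' Energy-function parameters
#'
#' Defaults reproduce the standard parameterization: an adjacency term of
#' `c0 * exp(-1/2 (d/sigma_k)^2) + c1` per shared carbon resonance, with
#' `c0 = -100`, `c1 = +50` (so a perfect match contributes -50, a gross
#' mismatch +50, and the term crosses zero at a 0.2 ppm difference), and a
#' chemical-shift energy bounded in `[-50, +100]`.
#'
#' @param c0 Adjacency depth (negative).
#' @param c1 Adjacency offset (positive).
#' @param sigma_k Adjacency width (ppm), identical for CA, CB and CO. The
#'   default `0.2/sqrt(2 log 2)` places the zero crossing at 0.2 ppm.
#' @param e_cs_min Chemical-shift energy at posterior 1.
#' @param e_cs_max Upper clamp of the chemical-shift energy.
#' @return Object of class `energy_params`.
#' @export
energy_params <- function(c0 = -100, c1 = 50,
                          sigma_k = 0.2 / sqrt(2 * log(2)),
                          e_cs_min = -50, e_cs_max = 100) {
  if (!(c0 < 0 && c1 > 0 && abs(c0) > c1))
    stop("need c0 < 0 < c1 and |c0| > c1 so the adjacency term has a root")
  if (!(e_cs_min < 0 && e_cs_max > 0))
    stop("need e_cs_min < 0 < e_cs_max")
  if (sigma_k <= 0) stop("sigma_k must be positive")
  structure(list(c0 = c0, c1 = c1, sigma_k = sigma_k,
                 e_cs_min = e_cs_min, e_cs_max = e_cs_max),
            class = "energy_params")
}

#' Adjacency energy between two sequentially placed spin systems
#'
#' Sums, over the carbon resonances CA, CB and CO, an inverted-Gaussian
#' term comparing this spin system's own (i) mean shift with the (i-1)
#' mean shift of the spin system at the following residue. A resonance
#' missing from either system contributes exactly zero; a missing
#' neighbour gives zero total.
#'
#' @param shifts Named mean shifts of the spin system at residue n
#'   (labels among `CA`, `CB`, `CO`).
#' @param next_shifts Named mean shifts of the spin system at residue
#'   n+1 (labels among `CAm`, `CBm`, `COm`), or `NULL`.
#' @param params [energy_params()].
#' @return Energy (arbitrary units).
#' @export
adjacency_energy <- function(shifts, next_shifts, params = energy_params()) {
  if (is.null(next_shifts) || !length(next_shifts)) return(0)
  e <- 0
  for (k in c("CA", "CB", "CO")) {
    a <- if (k %in% names(shifts)) shifts[[k]] else NA_real_
    km <- paste0(k, "m")
    b <- if (km %in% names(next_shifts)) next_shifts[[km]] else NA_real_
    if (!is.finite(a) || !is.finite(b)) next
    e <- e + params$c0 * exp(-0.5 * ((a - b) / params$sigma_k)^2) + params$c1
  }
  e
}

# Chi-square statistic, degrees of freedom and likelihood profile of one
# observation vector against predictions at every residue position.
# (i-1)-type observations are compared against the predictions of the
# preceding residue; at n = 1 they are excluded from R.
likelihood_profile <- function(obs, pm) {
  n <- nrow(pm$delta)
  x2 <- numeric(n)
  df <- integer(n)
  for (lab in names(obs)) {
    base <- label_base(lab)
    if (!base %in% colnames(pm$delta)) next
    d <- pm$delta[, base]
    s <- pm$sigma[, base]
    if (label_is_prev(lab)) {         # row n uses prediction at n-1
      d <- c(NA_real_, d[-n])
      s <- c(NA_real_, s[-n])
    }
    z2 <- ((obs[[lab]] - d) / s)^2
    ok <- is.finite(z2)
    x2[ok] <- x2[ok] + z2[ok]
    df <- df + as.integer(ok)
  }
  lik <- ifelse(df > 0, stats::pchisq(x2, df = pmax(df, 1L),
                                      lower.tail = FALSE), 1)
  list(x2 = x2, df = df, likelihood = lik)
}

#' Chi-square likelihood of observed shifts at one residue position
#'
#' The statistic is the sum of squared standardized residuals between the
#' observed mean shifts and the predictions over every co-present
#' resonance among H, N, CA, CB, CO and the (i-1) carbons (compared
#' against residue n-1). The likelihood is the survival function of a
#' chi-square variable with as many degrees of freedom as resonances
#' entered. With zero co-present resonances the likelihood is defined as 1.
#'
#' @param obs Named numeric vector of observed mean shifts (labels among
#'   `H, N, CA, CB, CO, CAm, CBm, COm`).
#' @param predictions A `shift_predictions` object.
#' @param n Residue position (1-based).
#' @return `list(likelihood, x2, df)`.
#' @export
shift_likelihood <- function(obs, predictions, n) {
  pm <- pred_matrices(predictions)
  prof <- likelihood_profile(obs, pm)
  if (prof$df[n] == 0L)
    message("no co-present resonances at residue ", n, "; likelihood 1")
  list(likelihood = prof$likelihood[n], x2 = prof$x2[n], df = prof$df[n])
}

#' Bayesian posterior over placements and type sets of one spin system
#'
#' Builds, for spin system `ss`, the prior, likelihood, marginal and
#' posterior over all residue positions n and resonance type sets i. The
#' prior is 0 at impossible combinations (an amide-bearing type set at a
#' proline; optionally a CB-bearing type set at a glycine) and uniform
#' `1/C` over the `C` possible ones. Likelihoods follow
#' [shift_likelihood()]; the posterior is the normalized product. If every
#' likelihood underflows to zero the posterior is defined as identically
#' zero (the system is then maximally penalized everywhere, favouring the
#' cache).
#'
#' @param ss A spin system.
#' @param predictions A `shift_predictions` object.
#' @param glycine_rule Also forbid CB-bearing type sets at glycines
#'   (default `FALSE`).
#' @return Object of class `posterior_matrix` with matrices `prior`,
#'   `likelihood`, `posterior` (I x N), scalar `marginal` and count `C`.
#' @export
posterior_matrix <- function(ss, predictions, glycine_rule = FALSE) {
  posterior_core(ss, pred_matrices(predictions), glycine_rule)
}

# core of posterior_matrix against precomputed prediction matrices
posterior_core <- function(ss, pm, glycine_rule = FALSE) {
  aa <- strsplit(pm$sequence, "")[[1]]
  n <- length(aa)
  I <- length(ss$type_sets)
  prior <- lik <- matrix(0, I, n)
  for (i in seq_len(I)) {
    means <- ss$type_sets[[i]]$means
    legal <- rep(TRUE, n)
    if (any(c("H", "N") %in% names(means))) legal[aa == "P"] <- FALSE
    if (glycine_rule && "CB" %in% names(means)) legal[aa == "G"] <- FALSE
    prior[i, legal] <- 1
    lik[i, ] <- likelihood_profile(means, pm)$likelihood
  }
  C <- sum(prior)
  if (C == 0)
    stop("spin system ", ss$id, " cannot be placed anywhere (C = 0)")
  prior <- prior / C
  marginal <- sum(prior * lik)
  post <- if (marginal > 0) prior * lik / marginal else matrix(0, I, n)
  structure(list(prior = prior, likelihood = lik, posterior = post,
                 marginal = marginal, C = C, ss_id = ss$id),
            class = "posterior_matrix")
}

#' Chemical-shift energy from a posterior probability
#'
#' `E = e_cs_min / log(I_m * N) * log(p * I_m * N)`, clamped from above at
#' `e_cs_max`. A posterior of 1 gives `e_cs_min` (-50 by default), the
#' uninformative value `1/(I_m N)` gives 0, and `p = 0` maps to the clamp
#' (`+100`). The log base cancels and is immaterial.
#'
#' @param p Posterior probability (vectorized).
#' @param i_m Number of resonance type sets of the spin system.
#' @param n_res Number of residues in the sequence.
#' @param params [energy_params()].
#' @return Energy (same length as `p`).
#' @export
chemical_shift_energy <- function(p, i_m, n_res, params = energy_params()) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- i_m * n_res
  if (m <= 1) return(rep(params$e_cs_min, length(p)))
  e <- ifelse(p <= 0, params$e_cs_max,
              params$e_cs_min / log(m) * log(p * m))
  pmin(e, params$e_cs_max)
}

#' Total energy of an assignment state (full recomputation)
#'
#' Independent, from-scratch evaluation of the state's energy: the sum
#' over placed spin systems of chemical-shift energy (from the stored
#' posterior matrices) plus adjacency energy against the spin system at
#' the following residue, computed directly through
#' [chemical_shift_energy()] and [adjacency_energy()] rather than the
#' annealer's incremental bookkeeping. Cached spin systems contribute 0.
#'
#' @param state An `assignment_state`.
#' @return Energy (arbitrary units).
#' @export
total_energy <- function(state) {
  problem <- state$problem
  n <- problem$n_res
  e <- 0
  for (pos in seq_len(n)) {
    m <- state$res2ss[pos]
    if (is.na(m)) next
    i <- state$ts[m]
    ssm <- problem$systems[[m]]
    post <- problem$posteriors[[m]]$posterior[i, pos]
    e <- e + chemical_shift_energy(post, length(ssm$type_sets), n,
                                   problem$energy_params)
    if (pos < n && !is.na(state$res2ss[pos + 1L])) {
      l <- state$res2ss[pos + 1L]
      e <- e + adjacency_energy(ssm$type_sets[[i]]$means,
                                problem$systems[[l]]$type_sets[[state$ts[l]]]$means,
                                problem$energy_params)
    }
  }
  e
}
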