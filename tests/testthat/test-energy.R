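test_that("adjacency energy reproduces its anchors and missing-term rules", {
  ep <- energy_params()
  # one shared resonance, zero difference: c0 + c1 = -50
  expect_equal(adjacency_energy(c(CA = 56), c(CAm = 56), ep), -50)
  # abscissa intercept at 0.2 ppm by construction of sigma_k
  expect_equal(adjacency_energy(c(CA = 56), c(CAm = 56.2), ep), 0,
               tolerance = 1e-10)
  # large mismatch tends to +c1
  expect_equal(adjacency_energy(c(CA = 56), c(CAm = 156), ep), 50)
  # three perfect matches: K (c0 + c1)
  expect_equal(adjacency_energy(c(CA = 56, CB = 30, CO = 176),
                                c(CAm = 56, CBm = 30, COm = 176), ep), -150)
  # a missing CB on either side contributes exactly zero
  expect_equal(adjacency_energy(c(CA = 56, CO = 176),
                                c(CAm = 56, CBm = 30, COm = 176), ep), -100)
  # unoccupied following residue
  expect_equal(adjacency_energy(c(CA = 56), NULL, ep), 0)
})

test_that("adjacency energy stays within [K(c0+c1), K c1]", {
  ep <- energy_params()
  set.seed(11)
  for (k in 1:200) {
    own <- c(CA = runif(1, 40, 70), CB = runif(1, 15, 75),
             CO = runif(1, 170, 182))
    nxt <- c(CAm = runif(1, 40, 70), CBm = runif(1, 15, 75),
             COm = runif(1, 170, 182))
    drop_own <- runif(3) < 0.3
    drop_nxt <- runif(3) < 0.3
    own <- own[!drop_own]
    nxt <- nxt[!drop_nxt]
    K <- sum(names(own) %in% c("CA", "CB", "CO") &
               paste0(names(own), "m") %in% names(nxt))
    e <- adjacency_energy(own, nxt, ep)
    expect_gte(e, K * (ep$c0 + ep$c1) - 1e-9)
    expect_lte(e, K * ep$c1 + 1e-9)
  }
})

test_that("the chi-square likelihood matches closed-form and normal oracles", {
  delta <- matrix(c(8.2, 119, 56, 30, 176), 1, 5,
                  dimnames = list(NULL, c("H", "N", "CA", "CB", "CO")))
  sigma <- matrix(0.5, 1, 5, dimnames = dimnames(delta))
  preds <- make_predictions("A", delta, sigma)
  # all residuals zero -> survival at 0 is 1
  r0 <- shift_likelihood(c(CA = 56, CB = 30), preds, 1)
  expect_equal(r0$likelihood, 1)
  expect_equal(r0$df, 2L)
  # R = 2, X2 = 2: chi-square survival is exp(-X2/2) = exp(-1)
  r2 <- shift_likelihood(c(CA = 56.5, CB = 30.5), preds, 1)
  expect_equal(r2$x2, 2)
  expect_equal(r2$likelihood, 0.3678794, tolerance = 1e-6)
  # R = 1, X2 = 1: equals 2(1 - Phi(1)) by the normal-CDF oracle
  r1 <- shift_likelihood(c(CA = 56.5), preds, 1)
  expect_equal(r1$likelihood, 0.3173105, tolerance = 1e-6)
})

test_that("likelihood is monotonically non-increasing in the statistic", {
  delta <- matrix(c(8.2, 119, 56, 30, 176), 1, 5,
                  dimnames = list(NULL, c("H", "N", "CA", "CB", "CO")))
  sigma <- matrix(1, 1, 5, dimnames = dimnames(delta))
  preds <- make_predictions("A", delta, sigma)
  liks <- vapply(seq(0, 5, by = 0.25), function(d)
    shift_likelihood(c(CA = 56 + d, CB = 30 + d), preds, 1)$likelihood, 0)
  expect_true(all(diff(liks) <= 1e-12))
})

test_that("(i-1) resonances are compared against the preceding residue", {
  delta <- rbind(c(NA, NA, 50, NA, NA), c(8.2, 119, 60, NA, NA))
  colnames(delta) <- c("H", "N", "CA", "CB", "CO")
  sigma <- delta * 0 + 1
  preds <- make_predictions("PA", delta, sigma)
  r <- shift_likelihood(c(CA = 60, CAm = 51), preds, 2)
  expect_equal(r$df, 2L)
  expect_equal(r$x2, 1)          # CAm vs residue 1's CA prediction
  # at n = 1 there is no predecessor: the (i-1) resonance drops out
  r1 <- shift_likelihood(c(CA = 50, CAm = 51), preds, 1)
  expect_equal(r1$df, 1L)
})

test_that("the prior masks prolines and the posterior follows Bayes", {
  sp <- standard_spectra()
  set <- assemble_spin_systems(list(peak_df(sp$HSQC, c(8.2, 119.0))))
  ss <- set$systems[[1]]
  delta <- matrix(NA_real_, 3, 5,
                  dimnames = list(NULL, c("H", "N", "CA", "CB", "CO")))
  sigma <- delta
  delta[, "CA"] <- c(50, 63, 45)                   # never observed below
  sigma[, "CA"] <- 1
  preds <- make_predictions("APG", delta, sigma)
  pm <- posterior_matrix(ss, preds)
  # amide-bearing type set cannot sit on the proline: prior (1/2, 0, 1/2)
  expect_equal(pm$prior[1, ], c(0.5, 0, 0.5))
  expect_equal(pm$C, 2)
  # with no co-present resonances all likelihoods are 1: posterior = prior
  expect_equal(pm$posterior[1, ], pm$prior[1, ])

  # a decisive likelihood concentrates the posterior
  delta2 <- delta; delta2[, "H"] <- c(8.2, NA, 50)
  sigma2 <- delta; sigma2[, "H"] <- 0.01
  pm2 <- posterior_matrix(ss, make_predictions("APG", delta2, sigma2))
  expect_gt(pm2$posterior[1, 1], 1 - 1e-10)
})

test_that("posteriors normalize over placements and type sets", {
  set.seed(21)
  sp <- small_problem(length = 14, seed = 9,
                      noise = default_peak_noise(), p_proline = 0.15)
  for (post in sp$problem$posteriors) {
    expect_equal(sum(post$prior), 1, tolerance = 1e-12)
    if (post$marginal > 0)
      expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  }
})

test_that("chemical-shift energy hits its anchors and clamps", {
  ep <- energy_params()
  expect_equal(chemical_shift_energy(1, 2, 100, ep), -50)
  expect_equal(chemical_shift_energy(0, 2, 100, ep), 100)
  expect_equal(chemical_shift_energy(1 / 200, 2, 100, ep), 0)
  # the clamp engages for tiny but positive posteriors
  expect_equal(chemical_shift_energy(1e-300, 2, 100, ep), 100)
  # degenerate single-possibility problem
  expect_equal(chemical_shift_energy(0.4, 1, 1, ep), -50)
  # bounds over the whole range
  p <- c(0, 10^seq(-12, 0, by = 0.5))
  e <- chemical_shift_energy(p, 3, 50, ep)
  expect_true(all(e >= ep$e_cs_min - 1e-12 & e <= ep$e_cs_max + 1e-12))
})

test_that("total energy composes spin-system terms with caching rules", {
  sp <- small_problem(length = 8, seed = 2)
  pr <- sp$problem
  M <- length(pr$systems)
  # all spin systems cached: zero energy
  st <- structure(list(problem = pr, pos = rep(NA_integer_, M),
                       ts = rep(1L, M),
                       res2ss = rep(NA_integer_, pr$n_res),
                       peak_cache = integer(0), energy = 0),
                  class = "assignment_state")
  expect_equal(total_energy(st), 0)
  # a single placed system with empty neighbours contributes E_cs only
  st$pos[1] <- 3L
  st$res2ss[3] <- 1L
  post <- pr$posteriors[[1]]$posterior[1, 3]
  expect_equal(total_energy(st),
               chemical_shift_energy(post, pr$I[1], pr$n_res,
                                     pr$energy_params))
})
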