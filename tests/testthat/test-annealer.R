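test_that("the Metropolis criterion accepts downhill always and uphill by Boltzmann", {
  set.seed(4)
  expect_true(metropolis_accept(-5, 1))
  expect_true(metropolis_accept(0, 1000))
  # ln 2 trick: acceptance frequency should be ~0.5
  n <- 4000
  acc <- mean(vapply(seq_len(n), function(i)
    metropolis_accept(10 * log(2), 10), TRUE))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
  # astronomically uphill move at T = 1 is never taken
  expect_false(any(vapply(1:200, function(i)
    metropolis_accept(1e6, 1), TRUE)))
})

test_that("specific heat follows the energy-variance estimator", {
  expect_equal(specific_heat(rep(-10, 50), 5), 0)
  # hand arithmetic: var_pop({-100,-200}) = 2500; / T^2 = 25
  expect_equal(specific_heat(c(-100, -200), 10), 25)
  s <- rnorm(100)
  expect_equal(specific_heat(s, 2), specific_heat(s, 1) / 4)
})

test_that("the cooling schedule targets the energy drop and caps the step", {
  p <- annealing_params()
  expect_equal(next_temperature(100, 400, p), 95)   # -2000/400 = -5
  expect_equal(next_temperature(100, 50, p), 90)    # uncapped 40 -> cap 10
  expect_equal(next_temperature(100, 0, p), 90)     # zero Cv applies the cap
  expect_equal(next_temperature(100, 1e9, p), 100, tolerance = 1e-5)
})

test_that("sample sizes respect floor, ceiling and the scaling law", {
  p <- annealing_params()
  expect_equal(next_sample_size(100, 100, p), 10000L)   # 333 -> floor
  expect_equal(next_sample_size(371, 10000, p), 100000L) # ceiling
  expect_equal(next_sample_size(100, 0, p), 10000L)
  # interior regime follows N * Cv^1.5 / 300
  expect_equal(next_sample_size(300, 500, p),
               as.integer(round(300 * 500^1.5 / 300)))
})

test_that("the pooled Student t-test matches a hand-computed toy and edge cases", {
  # x = (1,2,3), y = (2,3,4): t = -1/sqrt(2/3), df = 4, p = 0.2878641
  expect_equal(bbanneal:::t_test_p(c(1, 2, 3), c(2, 3, 4)), 0.2878641,
               tolerance = 1e-6)
  # identical constant samples equilibrate with p = 1
  expect_equal(bbanneal:::t_test_p(rep(5, 10), rep(5, 10)), 1)
  # constant but different samples cannot be equilibrated
  expect_equal(bbanneal:::t_test_p(rep(5, 10), rep(6, 10)), 0)
  # steadily separated samples give a vanishing p
  expect_lt(bbanneal:::t_test_p(rnorm(200, 0, 1), rnorm(200, 10, 1)), 1e-10)
  # Welch flavour agrees with the pooled test for equal sizes/variances
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(bbanneal:::t_test_p(x, y, welch = TRUE),
               stats::t.test(x, y)$p.value, tolerance = 1e-10)
})

test_that("annealing solves a trivial problem, minimizes, and is deterministic", {
  sp <- small_problem(sequence = "PAGKVSWD", seed = 13)
  pr <- sp$problem
  params <- annealing_params()
  r1 <- run_annealing(pr, params, seed = 5)
  r2 <- run_annealing(pr, params, seed = 5)
  expect_identical(r1$res2ss, r2$res2ss)
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$trace, r2$trace)

  # the final energy cannot exceed the initial random placement's
  set.seed(5)
  init <- bbanneal:::init_state(pr)
  expect_lte(r1$energy, init$energy)

  # exact subset-DP enumeration: the annealer reaches the global minimum
  expect_equal(r1$energy, brute_force_min(pr), tolerance = 1e-6)
  aa <- strsplit(sp$truth$sequence, "")[[1]]
  placed <- which(!is.na(r1$res2ss))
  ref <- sp$truth$reference
  for (n in placed) {
    am <- pr$systems[[r1$res2ss[n]]]$amide
    expect_lt(abs(am[["H"]] - ref$H[n]), 1e-9)
  }
})

test_that("energy bookkeeping matches full recomputation after kernel sampling", {
  sp <- small_problem(length = 12, seed = 31, noise = default_peak_noise())
  set.seed(9)
  st <- bbanneal:::init_state(sp$problem)
  res <- bbanneal:::run_kernel(st, temperature = 200, target_succ = 5000,
                               max_attempts = 2e4)
  st2 <- res$state
  expect_lt(abs(st2$energy - total_energy(st2)), 1e-6)
  expect_lt(abs(st2$energy -
                  bbanneal:::table_energy(st2$problem, st2$res2ss, st2$ts)),
            1e-6)
})

test_that("greedy minimization is monotone and idempotent at its fixed point", {
  sp <- small_problem(length = 12, seed = 8)
  set.seed(2)
  st <- bbanneal:::init_state(sp$problem)
  p <- annealing_params()
  m1 <- bbanneal:::local_minimize(st, p)
  expect_lte(m1$energy, st$energy)
  m2 <- bbanneal:::local_minimize(m1, p)
  expect_equal(m2$energy, m1$energy)
  expect_identical(m2$res2ss, m1$res2ss)
})

test_that("crosspeak exchange keeps peak conservation and exact bookkeeping", {
  sp <- small_problem(length = 30, seed = 7, noise = default_peak_noise(),
                      degenerate_pairs = 2)
  pr <- sp$problem
  expect_gt(length(pr$exch_peaks), 0L)
  set.seed(3)
  st <- bbanneal:::init_state(pr)
  params <- annealing_params()
  acc <- 0L
  for (i in 1:2000) {
    g <- pr$exch_peaks[sample.int(length(pr$exch_peaks), 1L)]
    out <- bbanneal:::attempt_peak_move(st, 1000, params, g = g)
    acc <- acc + out$accepted
    st <- out$state
    pr <- st$problem
  }
  expect_gt(acc, 0L)
  # conservation: every peak is owned by exactly one system (cache empty)
  expect_equal(sort(unlist(pr$membership)), seq_along(pr$peaks))
  expect_lt(abs(st$energy - total_energy(st)), 1e-6)
})
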