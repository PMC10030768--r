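test_that("the generator emits the expected peaks with correct boundary chemistry", {
  truth <- simulate_dataset(length = 30, p_proline = 0, seed = 5)
  expect_equal(nrow(truth$peak_lists$HSQC), 30L)           # one amide each
  # residue 1 emits nothing referencing a residue 0
  t1 <- truth$truth[truth$truth$residue == 1, ]
  expect_false(any(grepl("m$", t1$type)))
  expect_equal(sort(unique(t1$type)),
               sort(c("amide", "CO", "CA", "CB")))
  # every other residue carries the full sequential set (minus glycine CB)
  aa <- strsplit(truth$sequence, "")[[1]]
  i <- which(aa != "G" & c("X", aa[-30]) != "G")[3]        # interior, no G
  expect_equal(sort(truth$truth$type[truth$truth$residue == i &
                                       truth$truth$spectrum == "HNCACB"]),
               c("CA", "CAm", "CB", "CBm"))
})

test_that("prolines break the amide root and glycines drop CB peaks", {
  truth <- simulate_dataset(sequence = "MKPGVA", noise = c(H = 0, N = 0, C = 0),
                            seed = 2)
  expect_false(3 %in% truth$truth$residue)                 # proline emits none
  expect_false(is.finite(truth$shifts[3, "H"]))
  expect_false(is.finite(truth$shifts[4, "CB"]))           # glycine
  # residue after glycine has no CBm peaks
  t5 <- truth$truth[truth$truth$residue == 5, ]
  expect_false("CBm" %in% t5$type)
  # reference marks the proline unassignable
  expect_true(is.na(truth$reference$H[3]))
})

test_that("noise is applied per nucleus and seeds make byte-identical lists", {
  t0 <- simulate_dataset(length = 15, noise = c(H = 0, N = 0, C = 0), seed = 9)
  # zero noise: HSQC positions equal the true shifts exactly
  hs <- t0$peak_lists$HSQC
  expect_equal(hs$w1, t0$shifts[hs$residue, "H"])
  expect_equal(hs$w2, t0$shifts[hs$residue, "N"])
  t1 <- simulate_dataset(length = 15, seed = 9)
  t2 <- simulate_dataset(length = 15, seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_peak_list(t1$peak_lists$HNCACB, f1)
  write_peak_list(t2$peak_lists$HNCACB, f2)
  expect_identical(readLines(f1), readLines(f2))
  # noise magnitudes differ by nucleus
  tn <- simulate_dataset(length = 200, seed = 4)
  hs <- tn$peak_lists$HSQC
  dh <- hs$w1 - tn$shifts[hs$residue, "H"]
  dn <- hs$w2 - tn$shifts[hs$residue, "N"]
  expect_lt(sd(dh), 0.006)
  expect_gt(sd(dn), 0.02)
})

test_that("degradation retains, deletes and respects contiguous mode", {
  truth <- simulate_dataset(length = 40, p_proline = 0, seed = 6)
  # identity condition
  same <- degrade_dataset(truth, degradation_spec(seed = 1))
  expect_equal(vapply(same$peak_lists, nrow, 0L),
               vapply(truth$peak_lists, nrow, 0L))
  # killing the CO class removes HNCO and HN(CA)CO entirely
  noco <- degrade_dataset(truth, degradation_spec(retain = c(CO = 0), seed = 1))
  expect_equal(nrow(noco$peak_lists$HNCO), 0L)
  expect_equal(nrow(noco$peak_lists$HNCACO), 0L)
  expect_equal(nrow(noco$peak_lists$HNCA), nrow(truth$peak_lists$HNCA))
  # contiguous mode deletes disjoint runs of five consecutive residues
  con <- degrade_dataset(truth, degradation_spec(ss_retention = 0.5,
                                                 mode = "contiguous5",
                                                 seed = 3))
  kept <- sort(unique(con$peak_lists$HSQC$residue))
  deleted <- setdiff(seq_len(40), kept)
  runs <- split(deleted, cumsum(c(1, diff(deleted) != 1)))
  expect_true(all(vapply(runs, length, 0L) == 5L))
  expect_equal(length(deleted), 20L)
})

test_that("artifact injection reaches the target fraction at list-maximum intensity", {
  truth <- simulate_dataset(length = 25, p_proline = 0, seed = 8)
  n_real <- sum(vapply(truth$peak_lists[names(truth$peak_lists) != "HSQC"],
                       nrow, 0L))
  cont <- inject_artifacts(truth, fraction = 0.2, seed = 2)
  n_art <- sum(cont$truth$type == "artifact")
  expect_equal(n_art, round(0.2 * n_real / 0.8))
  expect_equal(n_art / (n_real + n_art), 0.2, tolerance = 0.01)
  for (sp in setdiff(names(cont$peak_lists), "HSQC")) {
    df <- cont$peak_lists[[sp]]
    art <- is.na(df$residue)
    if (any(art))
      expect_equal(max(abs(df$intensity[art])), max(abs(df$intensity)))
  }
  # fraction 0 is the identity
  expect_identical(inject_artifacts(truth, 0)$truth, truth$truth)
})

test_that("about 32% of draws fall outside one SD of the residue-type mean", {
  st <- residue_type_stats()
  truth <- simulate_dataset(length = 2500, p_proline = 0, seed = 12)
  aa <- strsplit(truth$sequence, "")[[1]]
  out <- 0L; tot <- 0L
  for (r in c("H", "N", "CA", "CB", "CO")) {
    mu <- sdv <- rep(NA_real_, length(aa))
    for (a in unique(aa)) {
      ms <- bbanneal:::stats_lookup(st, a, r)
      mu[aa == a] <- ms["mean"]; sdv[aa == a] <- ms["sd"]
    }
    z <- abs(truth$shifts[, r] - mu) / sdv
    out <- out + sum(z > 1, na.rm = TRUE)
    tot <- tot + sum(is.finite(z))
  }
  expect_gt(tot, 1e4)
  expect_equal(out / tot, 2 * pnorm(-1), tolerance = 0.05)
})
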