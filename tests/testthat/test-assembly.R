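sp <- standard_spectra()

test_that("ambiguous HNCA dimensions resolve against established resonances", {
  # worked example: an established CA(i-1) of 56.0 ppm (from HN(CO)CA)
  # forces an HNCA peak at 58.0 ppm to be the CA (0.3 ppm tolerance)
  peaks <- list(peak_df(sp$HNCOCA, c(8.20, 119.0, 56.0)),
                peak_df(sp$HNCA, c(8.20, 119.0, 58.0)))
  set <- assemble_spin_systems(peaks)
  expect_length(set$systems, 1L)
  ss <- set$systems[[1]]
  expect_length(ss$type_sets, 1L)
  expect_equal(ss$type_sets[[1]]$means[["CA"]], 58.0)
  expect_equal(ss$type_sets[[1]]$means[["CAm"]], 56.0)
})

test_that("amide-matching peaks with compatible carbons form one spin system", {
  peaks <- list(peak_df(sp$HSQC, c(8.20, 119.0)),
                peak_df(sp$HNCO, c(8.21, 119.1, 176.4)))
  set <- assemble_spin_systems(peaks)
  expect_length(set$systems, 1L)
  expect_equal(set$systems[[1]]$group, 1L)
  expect_equal(sort(ss_ids <- vapply(set$systems[[1]]$obs,
                                     function(e) e$peak, 0L))[c(1, 5)],
               c(1L, 2L))
})

test_that("conflicting carbons on a shared amide spawn sibling systems in one group", {
  # two residues with degenerate amides: two HNCA/HN(CO)CA pairs implying
  # two distinct (CA, CA-) combinations
  peaks <- list(
    peak_df(sp$HNCA,   c(8.20, 119.0, 58.0)),   # residue A: CA
    peak_df(sp$HNCOCA, c(8.20, 119.0, 52.0)),   # residue A: CA-
    peak_df(sp$HNCA,   c(8.21, 119.1, 61.0)),   # residue B: CA
    peak_df(sp$HNCOCA, c(8.21, 119.1, 47.0)))   # residue B: CA-
  set <- assemble_spin_systems(peaks)
  expect_length(set$systems, 2L)
  expect_equal(unique(vapply(set$systems, function(s) s$group, 0L)), 1L)

  # brute-force oracle: enumerate all 2-partitions of the four peaks and
  # keep those where every part admits a consistent labeling
  tol <- default_tolerances()[["C"]]
  vals <- c(58, 52, 61, 47)
  is_hnca <- c(TRUE, FALSE, TRUE, FALSE)        # HNCA = {CA, CAm}, HNCOCA = {CAm}
  part_ok <- function(members) {
    v <- vals[members]; h <- is_hnca[members]
    labelings <- expand.grid(lapply(h, function(x)
      if (x) c("CA", "CAm") else "CAm"), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(labelings))) {
      lab <- unlist(labelings[r, ])
      ok <- TRUE
      for (l in unique(lab)) {
        vv <- v[lab == l]
        if (length(vv) > 1 && diff(range(vv)) > tol) ok <- FALSE
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  # the assembled partition must be one of the consistent 2-partitions
  got <- lapply(set$systems, function(s)
    sort(unique(vapply(s$obs, function(e) e$peak, 0L))))
  expect_true(all(vapply(got, part_ok, TRUE)))
  # and no single system can hold all four peaks consistently
  expect_false(part_ok(1:4))
})

test_that("type-set enumeration is exhaustive, duplicate-free and consistent", {
  # lone HNCA peak: CA or CA- are both viable
  set1 <- assemble_spin_systems(list(peak_df(sp$HNCA, c(8.2, 119.0, 56.0))))
  expect_length(set1$systems[[1]]$type_sets, 2L)

  # two HNCA peaks at 54.1 and 58.3: label swap gives 2 sets, not 4
  set2 <- assemble_spin_systems(list(
    peak_df(sp$HNCA, c(8.2, 119.0, 54.1, 8.2, 119.0, 58.3))))
  tsets <- set2$systems[[1]]$type_sets
  # brute-force oracle over all 4 labelings of the two carbon dimensions
  tol <- default_tolerances()[["C"]]
  ok <- 0L
  for (l1 in c("CA", "CAm")) for (l2 in c("CA", "CAm"))
    if (l1 != l2 || abs(54.1 - 58.3) <= tol) ok <- ok + 1L
  expect_equal(length(tsets), ok)
  expect_equal(length(tsets), 2L)

  # paired HNCA + HN(CO)CA resolves the ambiguity completely
  set3 <- assemble_spin_systems(list(
    peak_df(sp$HNCA, c(8.2, 119.0, 54.1, 8.2, 119.0, 58.3)),
    peak_df(sp$HNCOCA, c(8.2, 119.0, 54.1))))
  expect_length(set3$systems[[1]]$type_sets, 1L)
})

test_that("mean shifts are arithmetic means that track membership", {
  set <- assemble_spin_systems(list(
    peak_df(sp$HNCA, c(8.2, 119.0, 56.00)),
    peak_df(sp$HNCOCA, c(8.2, 119.0, 51.0)),
    peak_df(sp$HNCACB, c(8.2, 119.0, 56.04))))
  ss <- set$systems[[1]]
  ms <- mean_shifts(ss, 1L)
  expect_equal(ms[["CA"]], 56.02)
  expect_equal(ms[["CAm"]], 51.0)
  # single observation: the mean is the observation
  expect_equal(ms[["N"]], 119.0)
})

test_that("assembly conserves peaks and is idempotent on clean data", {
  truth <- simulate_dataset(length = 20, noise = c(H = 0, N = 0, C = 0),
                            p_proline = 0.1, seed = 3)
  set <- assemble_spin_systems(truth$peak_lists)
  n_in_systems <- sum(vapply(set$systems, function(s)
    length(unique(vapply(s$obs, function(e) e$peak, 0L))), 0L))
  expect_equal(n_in_systems, set$n_peaks)

  # one spin system per amide-bearing residue under zero noise
  aa <- strsplit(truth$sequence, "")[[1]]
  expect_equal(length(set$systems), sum(aa != "P"))

  # re-assembling the emitted systems' peaks reproduces the partition
  parts <- lapply(set$systems, function(s)
    sort(unique(vapply(s$obs, function(e) e$peak, 0L))))
  set2 <- assemble_spin_systems(truth$peak_lists)
  parts2 <- lapply(set2$systems, function(s)
    sort(unique(vapply(s$obs, function(e) e$peak, 0L))))
  expect_identical(parts, parts2)
})
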