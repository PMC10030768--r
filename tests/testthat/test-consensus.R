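# fabricate run states over a real problem so vote patterns are exact
fake_run <- function(problem, res2ss) {
  pos <- rep(NA_integer_, length(problem$systems))
  for (n in which(!is.na(res2ss))) pos[res2ss[n]] <- n
  structure(list(problem = problem, pos = pos,
                 ts = rep(1L, length(problem$systems)),
                 res2ss = res2ss, peak_cache = integer(0), energy = 0),
            class = "assignment_state")
}

test_that("consensus requires a strict majority and ties stay unassigned", {
  sp <- small_problem(length = 6, seed = 14)
  pr <- sp$problem
  n <- pr$n_res
  # build the true placement: system whose amide matches residue n
  res2ss_true <- rep(NA_integer_, n)
  for (m in seq_along(pr$systems)) {
    d <- abs(sp$truth$reference$H - pr$systems[[m]]$amide[["H"]])
    res2ss_true[which.min(d)] <- m
  }
  alt <- res2ss_true
  placed <- which(!is.na(alt))
  alt[placed[1:2]] <- alt[placed[2:1]]           # swap two systems

  # 11/20 majority assigns; 10/20 tie does not
  runs <- c(replicate(11, fake_run(pr, res2ss_true), simplify = FALSE),
            replicate(9, fake_run(pr, alt), simplify = FALSE))
  cons <- build_consensus(runs, pr)
  expect_equal(cons$table$votes[placed[1]], 11)
  expect_equal(cons$table$status[placed[1]], "assigned")
  expect_equal(cons$table$spin_system[placed[1]],
               pr$ss_ids[res2ss_true[placed[1]]])

  runs_tie <- c(replicate(10, fake_run(pr, res2ss_true), simplify = FALSE),
                replicate(10, fake_run(pr, alt), simplify = FALSE))
  cons_tie <- build_consensus(runs_tie, pr)
  expect_equal(cons_tie$table$status[placed[1]], "unassigned")
  # residues where all runs agree are assigned either way
  agree <- placed[-(1:2)]
  expect_true(all(cons_tie$table$status[agree] == "assigned"))

  # unanimous runs reproduce the single-run placement
  cons_u <- build_consensus(replicate(20, fake_run(pr, res2ss_true),
                                      simplify = FALSE), pr)
  expect_equal(cons_u$table$spin_system[placed],
               pr$ss_ids[res2ss_true[placed]])
  expect_error(build_consensus(list(), pr), "at least one")
})

test_that("curation applies the three acceptance rules and only removes", {
  sp <- small_problem(length = 12, seed = 3)
  pr <- sp$problem
  res2ss_true <- rep(NA_integer_, pr$n_res)
  for (m in seq_along(pr$systems)) {
    d <- abs(sp$truth$reference$H - pr$systems[[m]]$amide[["H"]])
    res2ss_true[which.min(d)] <- m
  }
  cons <- build_consensus(replicate(20, fake_run(pr, res2ss_true),
                                    simplify = FALSE), pr)
  n <- nchar(cons$sequence)
  tab <- cons$table

  # rule 1: two connectivities, however poor the posterior
  tab$connectivities[2] <- 2L; tab$posterior[2] <- 0.01
  # rule 2: one connectivity and posterior >= 3/N
  tab$connectivities[3] <- 1L; tab$posterior[3] <- 3 / n + 0.001
  # rule 3: posterior > 0.5 alone
  tab$connectivities[4] <- 0L; tab$posterior[4] <- 0.6
  # none of the rules
  tab$connectivities[5] <- 0L; tab$posterior[5] <- 0.4
  tab$connectivities[6] <- 1L; tab$posterior[6] <- 1 / n
  cons$table <- tab
  cur <- curate_assignments(cons)
  expect_equal(cur$table$status[2:4], rep("assigned", 3))
  expect_equal(cur$table$status[5:6], rep("unassigned", 2))

  # monotone: curation never assigns anything the consensus left open
  newly <- cur$table$status == "assigned" & cons$table$status == "unassigned"
  expect_false(any(newly))
})

test_that("scoring labels matched, missing and mismatched residues", {
  sp <- small_problem(length = 10, seed = 21, p_proline = 0.1)
  pr <- sp$problem
  res2ss_true <- rep(NA_integer_, pr$n_res)
  for (m in seq_along(pr$systems)) {
    d <- abs(sp$truth$reference$H - pr$systems[[m]]$amide[["H"]])
    res2ss_true[which.min(d)] <- m
  }
  cons <- curate_assignments(build_consensus(
    replicate(5, fake_run(pr, res2ss_true), simplify = FALSE), pr))
  ref <- sp$truth$reference
  sc <- score_assignments(cons, ref)
  expect_equal(unname(sc$fractions["matched"]), 1)
  expect_equal(sum(sc$fractions), 1)

  # reference assigned, result unassigned -> missing
  cons2 <- cons
  assigned <- which(cons2$table$status == "assigned")
  drop <- assigned[1]
  cons2$table$status[drop] <- "unassigned"
  cons2$table[drop, c("H", "N")] <- NA
  sc2 <- score_assignments(cons2, ref)
  expect_equal(sc2$labels$label[sc2$labels$residue == drop], "missing")

  # result assigned where the reference is unassigned -> mismatched
  cons3 <- cons
  ref3 <- ref
  ref3[drop, c("H", "N")] <- NA
  sc3 <- score_assignments(cons3, ref3)
  expect_equal(sc3$labels$label[sc3$labels$residue == drop], "mismatched")

  # wrong amide shifts -> mismatched
  cons4 <- cons
  cons4$table$H[drop] <- cons4$table$H[drop] + 1
  sc4 <- score_assignments(cons4, ref)
  expect_equal(sc4$labels$label[sc4$labels$residue == drop], "mismatched")
})
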