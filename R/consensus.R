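# Ensemble consensus: majority vote of the spin system placed at each
# residue over independent annealing runs, followed by rule-based
# curation (connectivity counts and posterior probabilities) and scoring
# against a reference assignment.

#' Majority-vote consensus over annealing runs
#'
#' A residue is tentatively assigned the spin system placed there in a
#' strict majority (>50%) of runs; an exact tie leaves it unassigned. The
#' consensus placement's posterior probability and connectivity count are
#' computed from the consensus configuration against the input
#' spin-system set.
#'
#' @param runs List of `assignment_state` objects over the same problem.
#' @param problem The [anneal_problem()] the runs were started from.
#' @return Object of class `consensus_result`; `as.data.frame()` yields
#'   the per-residue table.
#' @export
build_consensus <- function(runs, problem) {
  if (!length(runs)) stop("need at least one annealing run")
  n_runs <- length(runs)
  n <- problem$n_res
  aa <- strsplit(problem$sequence, "")[[1]]
  M <- length(problem$systems)

  cons_ss <- rep(NA_integer_, n)
  cons_ts <- rep(NA_integer_, n)
  votes <- integer(n)
  for (pos in seq_len(n)) {
    placed <- vapply(runs, function(r) r$res2ss[pos], 0L)
    placed <- placed[!is.na(placed)]
    if (!length(placed)) next
    tab <- table(placed)
    top <- as.integer(names(tab)[which.max(tab)])
    if (max(tab) * 2L > n_runs) {
      cons_ss[pos] <- top
      votes[pos] <- max(tab)
      # consensus type set: most frequent among the voting runs (indices
      # are taken against the input problem's enumeration)
      tss <- vapply(runs, function(r)
        if (!is.na(r$res2ss[pos]) && r$res2ss[pos] == top)
          r$ts[top] else NA_integer_, 0L)
      tss <- tss[!is.na(tss) & tss <= length(problem$systems[[top]]$type_sets)]
      cons_ts[pos] <- if (length(tss)) {
        tt <- table(tss)
        as.integer(names(tt)[which.max(tt)])
      } else 1L
    } else votes[pos] <- max(tab)
  }

  post <- conn <- rep(NA_real_, n)
  shifts <- matrix(NA_real_, n, 5,
                   dimnames = list(NULL, c("H", "N", "CA", "CB", "CO")))
  tolC <- problem$tolerances[["C"]]
  means_at <- function(pos) {
    if (is.na(cons_ss[pos])) return(NULL)
    problem$systems[[cons_ss[pos]]]$type_sets[[cons_ts[pos]]]$means
  }
  n_conn <- function(a, b) {        # a at n, b at n+1
    if (is.null(a) || is.null(b)) return(0L)
    cnt <- 0L
    for (k in c("CA", "CB", "CO")) {
      km <- paste0(k, "m")
      if (k %in% names(a) && km %in% names(b) &&
          abs(a[[k]] - b[[km]]) <= tolC) cnt <- cnt + 1L
    }
    cnt
  }
  for (pos in seq_len(n)) {
    m <- cons_ss[pos]
    if (is.na(m)) next
    i <- cons_ts[pos]
    post[pos] <- problem$posteriors[[m]]$posterior[i, pos]
    me <- means_at(pos)
    for (r in colnames(shifts)) if (r %in% names(me)) shifts[pos, r] <- me[[r]]
    conn[pos] <- n_conn(me, if (pos < n) means_at(pos + 1L)) +
      n_conn(if (pos > 1) means_at(pos - 1L), me)
  }

  tab <- data.frame(
    residue = seq_len(n), aa = aa,
    status = ifelse(is.na(cons_ss), "unassigned", "assigned"),
    spin_system = ifelse(is.na(cons_ss), NA_character_,
                         problem$ss_ids[cons_ss]),
    votes = votes, vote_fraction = votes / n_runs,
    posterior = post, connectivities = conn,
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(shifts))
  structure(list(table = tab, n_runs = n_runs,
                 sequence = problem$sequence,
                 tolerances = problem$tolerances, curated = FALSE),
            class = "consensus_result")
}

#' Curate consensus assignments
#'
#' A tentative consensus assignment is kept only if (1) it has at least
#' two connectivities with adjacent consensus spin systems, or (2) at
#' least one connectivity and a posterior probability of at least `3/N`,
#' or (3) a posterior probability above 0.5. Everything else becomes
#' unassigned; curation never adds assignments.
#'
#' @param consensus A `consensus_result`.
#' @return The curated `consensus_result`.
#' @export
curate_assignments <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_result"))
  tab <- consensus$table
  n <- nchar(consensus$sequence)
  keep <- !is.na(tab$spin_system) &
    (tab$connectivities >= 2L |
       (tab$connectivities >= 1L & tab$posterior >= 3 / n) |
       tab$posterior > 0.5)
  drop <- tab$status == "assigned" & !keep
  tab$status[drop] <- "unassigned"
  tab$spin_system[drop] <- NA_character_
  tab[drop, c("posterior", "connectivities", "H", "N", "CA", "CB", "CO")] <- NA
  consensus$table <- tab
  consensus$curated <- TRUE
  consensus
}

#' @export
as.data.frame.consensus_result <- function(x, ...) x$table

#' @export
print.consensus_result <- function(x, ...) {
  st <- table(factor(x$table$status, c("assigned", "unassigned")))
  cat("<consensus_result> ", if (x$curated) "curated, " else "uncurated, ",
      x$n_runs, " runs: ", st[["assigned"]], " assigned / ",
      st[["unassigned"]], " unassigned residues\n", sep = "")
  invisible(x)
}

#' Score assignments against a reference
#'
#' Per scorable (non-proline) residue: `matched` if the assigned amide
#' group is the same as the reference's (H and N mean shifts within the
#' matching tolerance) or if both are unassigned; `missing` if the
#' reference assigns an amide but the result does not; `mismatched` if
#' the result assigns one that differs from the reference or that the
#' reference leaves unassigned.
#'
#' @param result A `consensus_result` (or `backbone_assignment`).
#' @param reference `data.frame` with columns `residue`, `H`, `N` (`NA`
#'   shifts = unassigned in the reference).
#' @param tolerances Per-nucleus matching cutoffs used for amide-group
#'   identity.
#' @return Object of class `assignment_score` with `fractions` (matched,
#'   mismatched, missing) and the per-residue `labels`.
#' @export
score_assignments <- function(result, reference,
                              tolerances = default_tolerances()) {
  if (inherits(result, "backbone_assignment")) result <- result$consensus
  tab <- result$table
  aa <- strsplit(result$sequence, "")[[1]]
  if (max(reference$residue) > length(aa))
    stop("reference refers to residues outside the sequence")
  refH <- refN <- rep(NA_real_, length(aa))
  refH[reference$residue] <- reference$H
  refN[reference$residue] <- reference$N
  scorable <- which(aa != "P")
  lab <- character(length(scorable))
  for (j in seq_along(scorable)) {
    n <- scorable[j]
    ref_asgn <- is.finite(refH[n]) && is.finite(refN[n])
    res_asgn <- tab$status[n] == "assigned"
    lab[j] <- if (!ref_asgn && !res_asgn) "matched"
    else if (ref_asgn && !res_asgn) "missing"
    else if (!ref_asgn && res_asgn) "mismatched"
    else if (abs(tab$H[n] - refH[n]) <= tolerances[["H"]] &&
             abs(tab$N[n] - refN[n]) <= tolerances[["N"]]) "matched"
    else "mismatched"
  }
  fr <- table(factor(lab, c("matched", "mismatched", "missing")))
  fr <- as.numeric(fr) / length(lab)
  names(fr) <- c("matched", "mismatched", "missing")
  structure(list(fractions = fr,
                 labels = data.frame(residue = scorable, label = lab)),
            class = "assignment_score")
}

#' @export
print.assignment_score <- function(x, ...) {
  f <- x$fractions
  cat(sprintf("<assignment_score> matched %.1f%%, mismatched %.1f%%, missing %.1f%% (%d scorable residues)\n",
              100 * f["matched"], 100 * f["mismatched"], 100 * f["missing"],
              nrow(x$labels)))
  invisible(x)
}
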