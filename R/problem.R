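# An assignment problem bundles the assembled spin systems, the shift
# predictions and the energy parameters, and precomputes the flat lookup
# tables the Monte Carlo kernel consumes:
#   ecs  : A x N matrix, chemical-shift energy of instance a (= spin system
#          m with type set i) placed at residue n; +Inf where the prior is 0
#   adj  : A x A matrix, adjacency energy of instance a at residue n against
#          instance b at residue n+1
#   mi   : A x 3 matrix of own CA/CB/CO mean shifts per instance
#   mp   : A x 3 matrix of (i-1) CA/CB/CO mean shifts per instance
# where A = total number of (spin system, type set) instances.

#' Build an assignment problem
#'
#' @param systems A `spin_system_set` from [assemble_spin_systems()].
#' @param predictions A `shift_predictions` object for the sequence.
#' @param energy_params [energy_params()].
#' @param glycine_rule Forbid CB-bearing type sets at glycines.
#' @return Object of class `assignment_problem`.
#' @export
anneal_problem <- function(systems, predictions,
                           energy_params = bbanneal::energy_params(),
                           glycine_rule = FALSE) {
  stopifnot(inherits(systems, "spin_system_set"))
  sequence <- attr(predictions, "sequence")
  problem <- list(systems = systems$systems,
                  tolerances = systems$tolerances,
                  n_peaks = systems$n_peaks,
                  predictions = predictions,
                  pm = pred_matrices(predictions),
                  sequence = sequence,
                  n_res = nchar(sequence),
                  energy_params = energy_params,
                  glycine_rule = glycine_rule)
  problem$posteriors <- lapply(problem$systems, posterior_core,
                               pm = problem$pm,
                               glycine_rule = glycine_rule)
  problem$peaks <- systems$peaks
  problem$groups <- vapply(problem$systems, function(s) s$group, 0L)
  owner <- integer(length(problem$peaks))
  for (m in seq_along(problem$systems))
    owner[ss_peak_ids(problem$systems[[m]])] <- m
  problem$owner <- owner
  problem$peak_group <- problem$groups[owner]
  problem$group_members <- split(seq_along(problem$systems), problem$groups)
  # crosspeak-cache eligibility: lowest 5% of |intensity| within each list
  ints <- vapply(problem$peaks, function(p)
    if (is.finite(p$intensity)) abs(p$intensity) else NA_real_, 0)
  specs <- vapply(problem$peaks, function(p) p$spectrum, "")
  cacheable <- rep(FALSE, length(ints))
  for (sp in unique(specs)) {
    i <- which(specs == sp & is.finite(ints))
    if (length(i) >= 2L)
      cacheable[i] <- ints[i] <= stats::quantile(ints[i], 0.05)
  }
  problem$cacheable <- cacheable
  # peaks eligible for exchange moves: members of multi-system groups
  gsz <- table(problem$groups)
  multi <- as.integer(names(gsz)[gsz > 1L])
  problem$exch_peaks <- which(problem$peak_group %in% multi)
  # per-peak observation templates (original candidate label sets) and
  # candidate matrices, used by the crosspeak-move configuration rebuild
  problem$peak_entries <- lapply(problem$peaks, function(p)
    lapply(seq_along(p$shifts), function(d) list(
      peak = p$gid, dim = d, shift = p$shifts[d],
      nucleus = p$nuclei[d], cands = p$cands[[d]])))
  problem$peak_candm <- lapply(problem$peaks, function(p) {
    m <- matrix(FALSE, length(p$shifts), length(RES_LABELS),
                dimnames = list(NULL, RES_LABELS))
    for (d in seq_along(p$shifts)) m[d, p$cands[[d]]] <- TRUE
    m
  })
  problem$membership <- lapply(problem$systems,
                               function(s) sort(ss_peak_ids(s)))
  problem$cfg_cache <- new.env(parent = emptyenv())
  problem <- rebuild_tables(problem)
  class(problem) <- "assignment_problem"
  problem
}

# per-instance derived rows for one spin system: chemical-shift energy
# over residues (+Inf where impossible) and own/(i-1) carbon means
instance_rows <- function(ss, post, n_res, ep) {
  I <- length(ss$type_sets)
  ecs <- matrix(Inf, I, n_res)
  mi <- mp <- matrix(NA_real_, I, 3)
  for (i in seq_len(I)) {
    legal <- post$prior[i, ] > 0
    ecs[i, legal] <- chemical_shift_energy(post$posterior[i, legal],
                                           I, n_res, ep)
    means <- ss$type_sets[[i]]$means
    for (k in 1:3) {
      lab <- c("CA", "CB", "CO")[k]
      if (lab %in% names(means)) mi[i, k] <- means[[lab]]
      labm <- paste0(lab, "m")
      if (labm %in% names(means)) mp[i, k] <- means[[labm]]
    }
  }
  list(ecs = ecs, mi = mi, mp = mp, I = I)
}

# adjacency energies of instance rows a (at n) against rows b (at n+1)
adj_block <- function(mi_a, mp_b, ep) {
  out <- matrix(0, nrow(mi_a), nrow(mp_b))
  for (k in 1:3) {
    d <- outer(mi_a[, k], mp_b[, k], "-")
    term <- ep$c0 * exp(-0.5 * (d / ep$sigma_k)^2) + ep$c1
    term[!is.finite(term)] <- 0
    out <- out + term
  }
  out
}

# (re)compute all flat kernel tables from systems + posteriors
rebuild_tables <- function(problem) {
  sys <- problem$systems
  M <- length(sys)
  n <- problem$n_res
  ep <- problem$energy_params
  I <- vapply(sys, function(s) length(s$type_sets), 0L)
  offset <- cumsum(c(0L, I[-M]))
  A <- sum(I)
  ecs <- matrix(Inf, A, n)
  mi <- mp <- matrix(NA_real_, A, 3)
  for (m in seq_len(M)) {
    rows <- instance_rows(sys[[m]], problem$posteriors[[m]], n, ep)
    a <- offset[m] + seq_len(I[m])
    ecs[a, ] <- rows$ecs
    mi[a, ] <- rows$mi
    mp[a, ] <- rows$mp
  }
  problem$I <- I
  problem$offset <- offset
  problem$I_i <- as.integer(I)
  problem$offset_i <- as.integer(offset)
  problem$A <- A
  problem$ecs <- ecs
  problem$mi <- mi
  problem$mp <- mp
  problem$adj <- adj_block(mi, mp, ep)
  problem$ss_ids <- vapply(sys, function(s) s$id, "")
  problem$placeable <- strsplit(problem$sequence, "")[[1]] != "P"
  problem
}

# incremental table update after a crosspeak move: only the instances of
# `changed` spin systems are recomputed; everything else is block-copied
update_tables <- function(problem, changed, cfgs) {
  old_I <- problem$I
  old_offset <- problem$offset
  M <- length(problem$systems)
  n <- problem$n_res
  ep <- problem$energy_params
  I <- old_I
  for (j in seq_along(changed)) I[changed[j]] <- cfgs[[j]]$I
  offset <- cumsum(c(0L, I[-M]))
  A <- sum(I)
  keep <- setdiff(seq_len(M), changed)
  old_rows <- unlist(lapply(keep, function(m)
    old_offset[m] + seq_len(old_I[m])), use.names = FALSE)
  new_rows <- unlist(lapply(keep, function(m)
    offset[m] + seq_len(I[m])), use.names = FALSE)
  ecs <- matrix(Inf, A, n)
  mi <- mp <- matrix(NA_real_, A, 3)
  adj <- matrix(0, A, A)
  ecs[new_rows, ] <- problem$ecs[old_rows, , drop = FALSE]
  mi[new_rows, ] <- problem$mi[old_rows, , drop = FALSE]
  mp[new_rows, ] <- problem$mp[old_rows, , drop = FALSE]
  adj[new_rows, new_rows] <- problem$adj[old_rows, old_rows, drop = FALSE]
  for (j in seq_along(changed)) {
    m <- changed[j]
    a <- offset[m] + seq_len(I[m])
    ecs[a, ] <- cfgs[[j]]$ecs
    mi[a, ] <- cfgs[[j]]$mi
    mp[a, ] <- cfgs[[j]]$mp
  }
  for (j in seq_along(changed)) {
    m <- changed[j]
    a <- offset[m] + seq_len(I[m])
    adj[a, ] <- adj_block(mi[a, , drop = FALSE], mp, ep)
    adj[, a] <- adj_block(mi, mp[a, , drop = FALSE], ep)
  }
  problem$I <- I
  problem$offset <- offset
  problem$I_i <- as.integer(I)
  problem$offset_i <- as.integer(offset)
  problem$A <- A
  problem$ecs <- ecs
  problem$mi <- mi
  problem$mp <- mp
  problem$adj <- adj
  problem
}

#' @export
print.assignment_problem <- function(x, ...) {
  cat("<assignment_problem> ", length(x$systems), " spin systems, ",
      x$n_res, " residues, ", x$A, " (system, type set) instances\n", sep = "")
  invisible(x)
}

# energy recomputed from the flat tables (cheap bookkeeping check; the
# fully independent path is total_energy())
table_energy <- function(problem, res2ss, ts) {
  n <- problem$n_res
  a_of <- function(m) problem$offset[m] + ts[m]
  e <- 0
  for (pos in seq_len(n)) {
    m <- res2ss[pos]
    if (is.na(m)) next
    a <- a_of(m)
    e <- e + problem$ecs[a, pos]
    if (pos < n && !is.na(res2ss[pos + 1L]))
      e <- e + problem$adj[a, a_of(res2ss[pos + 1L])]
  }
  e
}
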