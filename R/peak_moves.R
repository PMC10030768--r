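# Crosspeak moves. Peaks of amide-degenerate spin-system groups (and,
# optionally, low-intensity peaks eligible for the crosspeak cache) may
# move between group members during annealing. The resonance type sets of
# a spin system -- and hence its mean shifts, posterior and energies --
# depend only on its peak membership and the peaks' candidate label sets,
# so a move is evaluated by re-deriving that configuration directly: a
# joint candidate-pruning pass, the pruned type-set enumeration, and the
# Bayesian posterior. Configurations are memoized per membership, the
# energy change is computed locally, and the kernel tables are updated
# incrementally only when a move is accepted. Clashes reject the move
# outright.

# jointly prune candidate labels against resonances forced by resolved
# entries; NULL = no consistent labeling can exist
prune_candidates <- function(shifts, candm, tol8) {
  repeat {
    ncand <- rowSums(candm)
    if (any(ncand == 0L)) return(NULL)
    resolved <- ncand == 1L
    changed <- FALSE
    for (l in seq_len(ncol(candm))) {
      r <- resolved & candm[, l]
      if (!any(r)) next
      v <- shifts[r]
      if (max(v) - min(v) > tol8[l]) return(NULL)
      est <- mean(v)
      amb <- candm[, l] & !resolved
      if (any(amb)) {
        bad <- amb & abs(shifts - est) > tol8[l]
        if (any(bad)) {
          candm[bad, l] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  candm
}

compute_config <- function(problem, gids) {
  tol <- problem$tolerances
  ents <- unlist(problem$peak_entries[gids], recursive = FALSE)
  shifts <- vapply(ents, function(e) e$shift, 0)
  candm <- do.call(rbind, problem$peak_candm[gids])
  tol8 <- vapply(RES_LABELS, function(l) tol[[label_nucleus(l)]], 0)
  # amide coherence across the whole membership
  for (l in c("H", "N")) {
    v <- shifts[candm[, l] & rowSums(candm) == 1L]
    if (length(v) && max(v) - min(v) > tol[[l]]) return(list(ok = FALSE))
  }
  candm <- prune_candidates(shifts, candm, tol8)
  if (is.null(candm)) return(list(ok = FALSE))
  for (k in seq_along(ents)) ents[[k]]$cands <- RES_LABELS[candm[k, ]]
  ss <- list(obs = ents,
             amide = c(H = mean(shifts[candm[, "H"]]),
                       N = mean(shifts[candm[, "N"]])))
  tsets <- enumerate_type_sets(ss, tol)
  if (isTRUE(attr(tsets, "fallback"))) return(list(ok = FALSE))
  ss$type_sets <- tsets
  post <- tryCatch(posterior_core(ss, problem$pm, problem$glycine_rule),
                   error = function(e) NULL)
  if (is.null(post)) return(list(ok = FALSE))
  rows <- instance_rows(ss, post, problem$n_res, problem$energy_params)
  list(ok = TRUE, ss = ss, post = post, I = rows$I,
       ecs = rows$ecs, mi = rows$mi, mp = rows$mp)
}

# sorted-vector insert/remove (memberships are kept sorted so that cache
# keys are canonical without re-sorting)
sv_remove <- function(x, g) x[x != g]
sv_insert <- function(x, g) {
  i <- findInterval(g, x)
  if (i == 0L) c(g, x) else if (i == length(x)) c(x, g)
  else c(x[seq_len(i)], g, x[(i + 1L):length(x)])
}

# memoized spin-system configuration for a peak membership (the
# configuration depends only on the peak set, so entries stay valid for
# the lifetime of the problem and across runs; `gids` must be sorted)
ss_config <- function(problem, gids) {
  key <- paste(gids, collapse = ",")
  cache <- problem$cfg_cache
  val <- get0(key, envir = cache, inherits = FALSE)
  if (!is.null(val)) return(val)
  val <- compute_config(problem, gids)
  count <- get0("..count", envir = cache, inherits = FALSE)
  if (is.null(count)) count <- 0L
  if (count < 50000L) {
    assign(key, val, envir = cache)
    assign("..count", count + 1L, envir = cache)
  }
  val
}

# adjacency energy between one instance's own-carbon row and another's
# (i-1) row (length-3 vectors; NA = resonance missing)
adj_pair_rows <- function(mi_row, mp_row, ep) {
  d <- mi_row - mp_row
  ok <- is.finite(d)
  if (!any(ok)) return(0)
  sum(ep$c0 * exp(-0.5 * (d[ok] / ep$sigma_k)^2) + ep$c1)
}

# energy contribution of a set of residue positions, with the instances
# of `changed` spin systems overridden by candidate configurations
local_energy <- function(state, positions, changed = integer(0),
                         cfgs = NULL, ts_over = NULL) {
  pr <- state$problem
  ep <- pr$energy_params
  e <- 0
  for (n in positions) {
    m <- state$res2ss[n]
    if (is.na(m)) next
    ci <- match(m, changed)
    if (!is.na(ci)) {
      ecs_v <- cfgs[[ci]]$ecs[ts_over[ci], n]
      mi_row <- cfgs[[ci]]$mi[ts_over[ci], ]
    } else {
      a <- pr$offset[m] + state$ts[m]
      ecs_v <- pr$ecs[a, n]
      mi_row <- pr$mi[a, ]
    }
    e <- e + ecs_v
    if (n < pr$n_res) {
      l <- state$res2ss[n + 1L]
      if (!is.na(l)) {
        li <- match(l, changed)
        mp_row <- if (!is.na(li)) cfgs[[li]]$mp[ts_over[li], ]
        else pr$mp[pr$offset[l] + state$ts[l], ]
        e <- e + adj_pair_rows(mi_row, mp_row, ep)
      }
    }
  }
  e
}

# residue positions whose energy terms a change to `changed` can touch
affected_positions <- function(state, changed) {
  p <- state$pos[changed]
  p <- p[!is.na(p)]
  unique(pmax(1L, c(p - 1L, p)))
}

# evaluate a candidate peak re-membership; NULL if it clashes.
# membership: list of new (sorted) peak-id sets, one per entry of
# `changed`; `changed` defaults to the list's names.
evaluate_peak_change <- function(state, membership, random_ts = TRUE,
                                 changed = as.integer(names(membership))) {
  pr <- state$problem
  cfgs <- vector("list", length(changed))
  for (j in seq_along(changed)) {
    if (!length(membership[[j]])) return(NULL)   # a system may not empty
    cfgs[[j]] <- ss_config(pr, membership[[j]])
    if (!cfgs[[j]]$ok) return(NULL)
  }
  ts_over <- integer(length(changed))
  for (j in seq_along(changed)) {
    n <- state$pos[changed[j]]
    if (is.na(n)) {
      ts_over[j] <- 1L
    } else {
      legal <- which(is.finite(cfgs[[j]]$ecs[, n]))
      if (!length(legal)) return(NULL)
      ts_over[j] <- if (length(legal) == 1L || !random_ts) legal[1]
      else legal[sample.int(length(legal), 1L)]
    }
  }
  posns <- affected_positions(state, changed)
  dE <- local_energy(state, posns, changed, cfgs, ts_over) -
    local_energy(state, posns)
  list(changed = changed, cfgs = cfgs, ts_over = ts_over, dE = dE)
}

commit_peak_change <- function(state, ev, membership, peak_cache) {
  pr <- state$problem
  for (j in seq_along(ev$changed)) {
    m <- ev$changed[j]
    ss <- ev$cfgs[[j]]$ss
    ss$id <- pr$systems[[m]]$id
    ss$group <- pr$systems[[m]]$group
    pr$systems[[m]] <- ss
    pr$posteriors[[m]] <- ev$cfgs[[j]]$post
    pr$membership[[m]] <- membership[[j]]
    pr$owner[membership[[j]]] <- m
  }
  pr$owner[peak_cache] <- 0L
  pr <- update_tables(pr, ev$changed, ev$cfgs)
  state$problem <- pr
  state$ts[ev$changed] <- ev$ts_over
  state$peak_cache <- peak_cache
  state$energy <- state$energy + ev$dE
  state
}

# candidate re-membership for one move of peak g (memberships sorted)
peak_move_membership <- function(problem, peak_cache, g, kind,
                                 target = NULL, partner = NULL) {
  src <- problem$owner[g]
  if (kind == "move") {
    changed <- c(src, target)
    mem <- list(sv_remove(problem$membership[[src]], g),
                sv_insert(problem$membership[[target]], g))
  } else if (kind == "swap") {
    tgt <- problem$owner[partner]
    changed <- c(src, tgt)
    mem <- list(sv_insert(sv_remove(problem$membership[[src]], g), partner),
                sv_insert(sv_remove(problem$membership[[tgt]], partner), g))
  } else if (kind == "cache") {
    changed <- src
    mem <- list(sv_remove(problem$membership[[src]], g))
    peak_cache <- c(peak_cache, g)
  } else if (kind == "uncache") {
    changed <- target
    mem <- list(sv_insert(problem$membership[[target]], g))
    peak_cache <- peak_cache[peak_cache != g]
  }
  names(mem) <- changed
  list(membership = mem, peak_cache = peak_cache, changed = changed)
}

# one Metropolis crosspeak move attempt. The element is drawn uniformly
# over all crosspeaks; a peak with no productive move (not in a
# degenerate overlap group, not cache-eligible) is a no-op counted as an
# unsuccessful proposal.
attempt_peak_move <- function(state, temperature, params, g = NULL) {
  pr <- state$problem
  if (is.null(g)) g <- sample.int(length(pr$peaks), 1L)
  use_cache <- isTRUE(params$use_peak_cache)
  exchangeable <- g %in% pr$exch_peaks
  cached <- pr$owner[g] == 0L
  if (!exchangeable && !(use_cache && (pr$cacheable[g] || cached)))
    return(list(state = state, accepted = FALSE))
  members <- pr$group_members[[as.character(pr$peak_group[g])]]
  kinds <- character(0)
  if (cached) {
    if (length(members)) kinds <- "uncache"
  } else {
    others <- setdiff(members, pr$owner[g])
    if (exchangeable && length(others)) kinds <- c("move", "swap")
    if (use_cache && pr$cacheable[g]) kinds <- c(kinds, "cache")
  }
  if (!length(kinds)) return(list(state = state, accepted = FALSE))
  kind <- kinds[sample.int(length(kinds), 1L)]
  target <- partner <- NULL
  if (kind %in% c("move", "uncache")) {
    pool <- if (kind == "move") setdiff(members, pr$owner[g]) else members
    target <- pool[sample.int(length(pool), 1L)]
  } else if (kind == "swap") {
    pool <- setdiff(members, pr$owner[g])
    tgt <- pool[sample.int(length(pool), 1L)]
    pk <- pr$membership[[tgt]]
    partner <- pk[sample.int(length(pk), 1L)]
  }
  cand <- peak_move_membership(pr, state$peak_cache, g, kind, target, partner)
  ev <- evaluate_peak_change(state, cand$membership, changed = cand$changed)
  if (is.null(ev)) return(list(state = state, accepted = FALSE))
  if (metropolis_accept(ev$dE, temperature))
    list(state = commit_peak_change(state, ev, cand$membership,
                                    cand$peak_cache), accepted = TRUE)
  else
    list(state = state, accepted = FALSE)
}

# greedy crosspeak pass for local minimization: accept only decreases
peak_min_pass <- function(state, params) {
  elig <- state$problem$exch_peaks
  for (g in elig) {
    pr <- state$problem
    if (pr$owner[g] == 0L) next
    members <- pr$group_members[[as.character(pr$peak_group[g])]]
    others <- setdiff(members, pr$owner[g])
    cands <- lapply(others, function(t)
      peak_move_membership(pr, state$peak_cache, g, "move", target = t))
    for (t in others) {
      for (h in pr$membership[[t]])
        cands[[length(cands) + 1L]] <-
          peak_move_membership(pr, state$peak_cache, g, "swap", partner = h)
    }
    for (cand in cands) {
      ev <- evaluate_peak_change(state, cand$membership, random_ts = FALSE,
                                 changed = cand$changed)
      if (!is.null(ev) && ev$dE < -1e-9) {
        state <- commit_peak_change(state, ev, cand$membership,
                                    cand$peak_cache)
        break
      }
    }
  }
  state
}
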