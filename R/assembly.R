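# Spin-system assembly: crosspeaks sharing an amide H-N root are gathered
# into spin systems; amide-degenerate systems form groups whose peaks may
# exchange during annealing; ambiguous carbon dimensions are resolved
# against established resonances and any residual ambiguity is enumerated
# as resonance type sets.

# flatten one or more peak-list data.frames into internal peak records
combine_peaks <- function(peak_lists) {
  if (is.data.frame(peak_lists)) peak_lists <- list(peak_lists)
  peaks <- list()
  for (pl in peak_lists) {
    spec <- attr(pl, "spectrum")
    if (is.null(spec)) stop("peak list lacks its spectrum definition")
    nd <- length(spec$dim_nuclei)
    for (i in seq_len(nrow(pl))) {
      peaks[[length(peaks) + 1L]] <- list(
        gid = length(peaks) + 1L,
        spectrum = spec$name,
        shifts = as.numeric(pl[i, paste0("w", seq_len(nd))]),
        nuclei = spec$dim_nuclei,
        cands = spec$dim_types,
        intensity = pl$intensity[i])
    }
  }
  peaks
}

new_spin_system <- function(peak) {
  obs <- lapply(seq_along(peak$shifts), function(d) list(
    peak = peak$gid, dim = d, shift = peak$shifts[d],
    nucleus = peak$nuclei[d], cands = peak$cands[[d]]))
  list(id = NA_character_, group = NA_integer_, obs = obs,
       type_sets = list(), amide = c(H = NA_real_, N = NA_real_))
}

# mean shift of each label over entries already resolved to a single label
established_means <- function(ss) {
  lab <- vapply(ss$obs, function(e)
    if (length(e$cands) == 1L) e$cands else NA_character_, "")
  sh <- vapply(ss$obs, function(e) e$shift, 0)
  ok <- !is.na(lab)
  if (!any(ok)) return(numeric(0))
  vapply(split(sh[ok], lab[ok]), mean, 0)
}

amide_means <- function(ss) {
  est <- established_means(ss)
  c(H = unname(est["H"]), N = unname(est["N"]))
}

# candidate label viable for an entry given established values?
viable_cands <- function(entry, est, tolerances) {
  keep <- vapply(entry$cands, function(l) {
    if (!l %in% names(est)) return(TRUE)
    abs(entry$shift - est[[l]]) <= tolerances[[label_nucleus(l)]]
  }, TRUE)
  entry$cands[keep]
}

# does the peak admit a labeling consistent with the spin system?
peak_fits <- function(ss, peak, tolerances) {
  est <- established_means(ss)
  for (d in seq_along(peak$shifts)) {
    entry <- list(shift = peak$shifts[d], cands = peak$cands[[d]])
    if (!length(viable_cands(entry, est, tolerances))) return(FALSE)
  }
  TRUE
}

# iteratively prune candidate labels against established resonances until
# no entry changes; an elimination that would empty an entry is skipped
# (the residual inconsistency is handled at type-set enumeration)
resolve_types <- function(ss, tolerances) {
  repeat {
    est <- established_means(ss)
    changed <- FALSE
    for (k in seq_along(ss$obs)) {
      e <- ss$obs[[k]]
      if (length(e$cands) == 1L) next
      keep <- viable_cands(e, est, tolerances)
      if (length(keep) && length(keep) < length(e$cands)) {
        ss$obs[[k]]$cands <- keep
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ss$amide <- amide_means(ss)
  ss
}

add_peak_to_ss <- function(ss, peak, tolerances) {
  est <- established_means(ss)
  for (d in seq_along(peak$shifts)) {
    entry <- list(peak = peak$gid, dim = d, shift = peak$shifts[d],
                  nucleus = peak$nuclei[d], cands = peak$cands[[d]])
    keep <- viable_cands(entry, est, tolerances)
    if (length(keep)) entry$cands <- keep
    ss$obs[[length(ss$obs) + 1L]] <- entry
  }
  resolve_types(ss, tolerances)
}

#' Assemble crosspeaks into spin systems and overlap groups
#'
#' Peaks are gathered greedily: the first unconsumed peak seeds a spin
#' system, and any peak whose amide H and N shifts match within tolerance
#' joins it. After every addition, ambiguous resonance types are resolved
#' against resonances already established in the system (a candidate label
#' is eliminated when its shift violates the tolerance against an
#' established resonance of that label). A peak that matches on the amide
#' but clashes on a further resonance spawns a sibling spin system in the
#' same group; the crosspeaks of multi-member groups are marked
#' exchangeable for the annealer. Seeding follows input order, so assembly
#' is deterministic.
#'
#' @param peak_lists One peak-list `data.frame` (from [read_peak_list()])
#'   or a list of them.
#' @param tolerances Per-nucleus matching cutoffs in ppm.
#' @return Object of class `spin_system_set`: fields `systems` (list of
#'   spin systems, each with resolved observations, enumerated
#'   `type_sets` and a `group` id), `tolerances`, `n_peaks`.
#' @export
assemble_spin_systems <- function(peak_lists, tolerances = default_tolerances()) {
  peaks <- combine_peaks(peak_lists)
  if (!length(peaks)) stop("no peaks to assemble")
  p_h <- vapply(peaks, function(p) p$shifts[match("H", p$nuclei)], 0)
  p_n <- vapply(peaks, function(p) p$shifts[match("N", p$nuclei)], 0)
  consumed <- logical(length(peaks))
  systems <- list()
  group <- 0L
  while (any(!consumed)) {
    seed_i <- which(!consumed)[1L]
    consumed[seed_i] <- TRUE
    group <- group + 1L
    sibs <- list(resolve_types(new_spin_system(peaks[[seed_i]]), tolerances))
    repeat {
      progress <- FALSE
      open <- which(!consumed)
      if (!length(open)) break
      # vectorized amide preselection against all current siblings
      cand_mask <- rep(FALSE, length(open))
      for (ss in sibs) {
        am <- ss$amide
        cand_mask <- cand_mask |
          (abs(p_h[open] - am["H"]) <= tolerances[["H"]] &
           abs(p_n[open] - am["N"]) <= tolerances[["N"]])
      }
      for (pi in open[cand_mask]) {
        if (consumed[pi]) next
        p <- peaks[[pi]]
        placed <- FALSE
        clashed <- FALSE
        for (si in seq_along(sibs)) {
          am <- sibs[[si]]$amide
          if (abs(p$shifts[match("H", p$nuclei)] - am["H"]) > tolerances[["H"]] ||
              abs(p$shifts[match("N", p$nuclei)] - am["N"]) > tolerances[["N"]])
            next
          if (peak_fits(sibs[[si]], p, tolerances)) {
            sibs[[si]] <- add_peak_to_ss(sibs[[si]], p, tolerances)
            placed <- TRUE
            break
          } else clashed <- TRUE
        }
        if (!placed && clashed) {
          sibs[[length(sibs) + 1L]] <-
            resolve_types(new_spin_system(p), tolerances)
          placed <- TRUE
        }
        if (placed) {
          consumed[pi] <- TRUE
          progress <- TRUE
        }
      }
      if (!progress) break
    }
    for (ss in sibs) {
      ss$group <- group
      systems[[length(systems) + 1L]] <- ss
    }
  }
  for (k in seq_along(systems)) {
    systems[[k]]$id <- paste0("ss", k)
    systems[[k]] <- finalize_type_sets(systems[[k]], tolerances)
  }
  structure(list(systems = systems, tolerances = tolerances,
                 n_peaks = length(peaks), peaks = peaks),
            class = "spin_system_set")
}

#' @export
print.spin_system_set <- function(x, ...) {
  g <- vapply(x$systems, function(s) s$group, 0L)
  cat("<spin_system_set> ", length(x$systems), " spin systems from ",
      x$n_peaks, " peaks; ", sum(table(g) > 1L),
      " overlap group(s) with >1 member\n", sep = "")
  invisible(x)
}

#' Enumerate the resonance type sets of a spin system
#'
#' Produces every internally consistent assignment of the system's still
#' ambiguous dimensions to concrete resonance labels. A combination is
#' consistent when, for every label, all contributing shifts (resolved and
#' newly assigned) agree within the nucleus tolerance. A spin system with
#' no ambiguous dimensions has exactly one type set.
#'
#' @param ss A spin system from [assemble_spin_systems()].
#' @param tolerances Per-nucleus cutoffs in ppm.
#' @param max_sets Upper bound on enumerated type sets; exceeding it marks
#'   the result as truncated.
#' @return List of type sets, each `list(labels, means)` where `labels`
#'   assigns one label per observation and `means` holds the arithmetic
#'   mean shift per label present. Attribute `"fallback"` is `TRUE` when
#'   no fully consistent labeling exists (or enumeration overflowed) and a
#'   best-effort single type set was kept instead.
#' @export
enumerate_type_sets <- function(ss, tolerances = default_tolerances(),
                                max_sets = 64L) {
  nent <- length(ss$obs)
  cands <- lapply(ss$obs, function(e) e$cands)
  shifts <- vapply(ss$obs, function(e) e$shift, 0)
  tol_of <- vapply(RES_LABELS, function(l)
    tolerances[[label_nucleus(l)]], 0)
  label_means <- function(labels) vapply(split(shifts, labels), mean, 0)

  # depth-first enumeration with running per-label shift ranges; a branch
  # is pruned as soon as some label's range exceeds its tolerance
  results <- list()
  overflow <- FALSE
  nodes <- 0L
  labels <- character(nent)
  lo <- hi <- stats::setNames(rep(NA_real_, length(RES_LABELS)), RES_LABELS)
  rec <- function(k, lo, hi) {
    if (overflow) return()
    nodes <<- nodes + 1L
    if (nodes > 50000L || length(results) >= max_sets) {
      overflow <<- TRUE
      return()
    }
    if (k > nent) {
      results[[length(results) + 1L]] <<- labels
      return()
    }
    s <- shifts[k]
    for (l in cands[[k]]) {
      nlo <- min(lo[[l]], s, na.rm = TRUE)
      nhi <- max(hi[[l]], s, na.rm = TRUE)
      if (nhi - nlo > tol_of[[l]]) next
      labels[k] <<- l
      lo2 <- lo; hi2 <- hi
      lo2[[l]] <- nlo; hi2[[l]] <- nhi
      rec(k + 1L, lo2, hi2)
      if (overflow) return()
    }
  }
  rec(1L, lo, hi)

  if (length(results) && !overflow) {
    out <- lapply(results, function(lb)
      list(labels = lb, means = label_means(lb)))
  } else if (length(results)) {
    out <- lapply(results, function(lb)
      list(labels = lb, means = label_means(lb)))
    attr(out, "fallback") <- TRUE
  } else {
    # residual inconsistency (degenerate overlap): fall back to the first
    # candidate labeling so the system keeps at least one type set
    lb <- vapply(cands, function(cc) cc[1], "")
    out <- list(list(labels = lb, means = label_means(lb)))
    attr(out, "fallback") <- TRUE
  }
  out
}

finalize_type_sets <- function(ss, tolerances) {
  ss$type_sets <- enumerate_type_sets(ss, tolerances)
  ss
}

#' Mean shifts of a spin system under one type set
#'
#' Arithmetic mean, per resonance label, over every observation the type
#' set assigns to that label. Labels with no contributing observation are
#' absent from the result.
#'
#' @param ss A spin system.
#' @param type_set Index into `ss$type_sets` or a type set object.
#' @return Named numeric vector of mean shifts (ppm).
#' @export
mean_shifts <- function(ss, type_set = 1L) {
  ts <- if (is.numeric(type_set)) ss$type_sets[[type_set]] else type_set
  shifts <- vapply(ss$obs, function(e) e$shift, 0)
  vapply(split(shifts, ts$labels), mean, 0)
}

# unique peak ids contained in a spin system
ss_peak_ids <- function(ss) unique(vapply(ss$obs, function(e) e$peak, 0L))
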