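# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the packaged residue-type statistics.

# peak-list data.frame in the shape read_peak_list() returns
peak_df <- function(spectrum, shifts, intensity = NULL) {
  nd <- length(spectrum$dim_nuclei)
  m <- matrix(shifts, ncol = nd, byrow = TRUE)
  out <- data.frame(id = seq_len(nrow(m)), spectrum = spectrum$name)
  for (d in seq_len(nd)) out[[paste0("w", d)]] <- m[, d]
  out$intensity <- if (is.null(intensity)) NA_real_ else intensity
  attr(out, "spectrum") <- spectrum
  out
}

# shift_predictions object from explicit delta/sigma matrices
# (rows = residues, columns H N CA CB CO; NA = no prediction)
make_predictions <- function(sequence, delta, sigma) {
  aa <- strsplit(sequence, "")[[1]]
  res_names <- c("H", "N", "CA", "CB", "CO")
  rows <- list()
  for (i in seq_along(aa)) for (r in seq_along(res_names)) {
    if (!is.finite(delta[i, r])) next
    rows[[length(rows) + 1L]] <- data.frame(
      residue_index = i, aa = aa[i], resonance = res_names[r],
      delta_pred = delta[i, r], sigma = sigma[i, r], source = "table",
      stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, rows)
  class(preds) <- c("shift_predictions", "data.frame")
  attr(preds, "sequence") <- sequence
  preds
}

# exact minimum energy over every assignment state: a dynamic program
# over (set of systems already placed, instance occupying the previous
# slot), covering type-set choices, empty positions and cached systems
brute_force_min <- function(problem) {
  M <- length(problem$systems)
  stopifnot(M <= 12)                     # 2^M subset table
  slots <- which(bbanneal:::placeable_mask(problem))
  A <- problem$A
  inst_sys <- rep(seq_len(M), problem$I)
  nsub <- bitwShiftL(1L, M)
  dp <- matrix(Inf, A + 1L, nsub)        # row 1 = previous slot empty
  dp[1L, 1L] <- 0
  for (j in seq_along(slots)) {
    n <- slots[j]
    adjacent <- j > 1L && slots[j] == slots[j - 1L] + 1L
    ndp <- matrix(Inf, A + 1L, nsub)
    for (sub in which(apply(is.finite(dp), 2, any))) {
      base <- dp[, sub]
      # leave this slot empty
      ndp[1L, sub] <- min(ndp[1L, sub], min(base))
      for (a in seq_len(A)) {
        m <- inst_sys[a]
        bit <- bitwShiftL(1L, m - 1L)
        if (bitwAnd(sub - 1L, bit) > 0L) next       # system already used
        e_cs <- problem$ecs[a, n]
        if (!is.finite(e_cs)) next
        addv <- if (adjacent) c(0, problem$adj[, a]) else numeric(A + 1L)
        val <- min(base + addv) + e_cs
        tgt <- sub + bit
        if (val < ndp[a + 1L, tgt]) ndp[a + 1L, tgt] <- val
      }
    }
    dp <- ndp
  }
  min(dp)                                # unplaced systems are cached (0)
}

# small noise-free synthetic problem ready for annealing
small_problem <- function(length = 10, seed = 42, noise = c(H = 0, N = 0, C = 0),
                          sequence = NULL, p_proline = 0,
                          degenerate_pairs = 0) {
  truth <- simulate_dataset(sequence = sequence, length = length,
                            noise = noise, p_proline = p_proline,
                            degenerate_pairs = degenerate_pairs, seed = seed)
  systems <- assemble_spin_systems(truth$peak_lists)
  preds <- read_shift_predictions(sequence = truth$sequence,
                                  mode = "residue_stats")
  list(truth = truth, systems = systems,
       problem = anneal_problem(systems, preds))
}
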