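# Ground-truthed synthetic triple-resonance data. True shifts are drawn
# per residue from residue-type Gaussian statistics; crosspeaks are
# emitted per spectrum with Gaussian measurement noise (0.003 ppm 1H,
# 0.04 ppm 15N, 0.04 ppm 13C by default). Degradation transforms emulate
# sparse data (per-peak-type retention, spin-system deletion singly or in
# contiguous five-residue stretches) and artifact contamination.

#' Default crosspeak position noise
#'
#' Gaussian standard deviations added to true resonance values when
#' emitting crosspeaks: 0.003 ppm for 1H, 0.04 ppm for 15N and 13C.
#' @return Named numeric vector.
#' @export
default_peak_noise <- function() c(H = 0.003, N = 0.04, C = 0.04)

#' Generate a ground-truthed synthetic dataset
#'
#' Draws per-residue true H, N, CA, CB, CO shifts from the residue-type
#' Gaussians in `stats`, then emits crosspeak lists for the seven
#' standard backbone experiments; each peak coordinate is the true value
#' plus Gaussian noise. Prolines emit no amide-rooted peaks (and carry no
#' H); glycines have no CB; residue 1 emits no peaks referencing a
#' residue 0.
#'
#' @param sequence One-letter sequence, or `NULL` to draw one at random.
#' @param length Sequence length when `sequence` is `NULL`.
#' @param stats Residue-type statistics ([residue_type_stats()]).
#' @param noise Named per-nucleus noise SDs in ppm (0 = noise-free).
#' @param p_proline Proline frequency of randomly drawn sequences.
#' @param degenerate_pairs Number of residue pairs forced to share amide
#'   shifts within tolerance (stress fixture for overlap groups).
#' @param spectra Which of the seven standard spectra to emit.
#' @param seed Optional integer seed.
#' @return Object of class `synthetic_truth`: `sequence`, true `shifts`
#'   (N x 5), `peak_lists` (named list of peak `data.frame`s),
#'   `reference` (residue, H, N true amide shifts; the true assignment
#'   map).
#' @export
simulate_dataset <- function(sequence = NULL, length = 60,
                             stats = residue_type_stats(),
                             noise = default_peak_noise(),
                             p_proline = 0.05, degenerate_pairs = 0,
                             spectra = names(standard_spectra()),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequence)) {
    if (length < 3) stop("need length >= 3")
    prob <- ifelse(AA_LETTERS == "P", p_proline,
                   (1 - p_proline) / 19)
    sequence <- paste(sample(AA_LETTERS, length, replace = TRUE, prob = prob),
                      collapse = "")
  }
  validate_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  n <- base::length(aa)
  res_names <- c("H", "N", "CA", "CB", "CO")
  shifts <- matrix(NA_real_, n, 5, dimnames = list(NULL, res_names))
  for (i in seq_len(n)) {
    for (r in res_names) {
      if (r == "H" && aa[i] == "P") next
      if (r == "CB" && aa[i] == "G") next
      ms <- stats_lookup(stats, aa[i], r)
      if (!is.finite(ms["mean"]))
        stop("statistics missing for amino acid ", aa[i], " resonance ", r)
      shifts[i, r] <- stats::rnorm(1, ms["mean"], ms["sd"])
    }
  }
  if (degenerate_pairs > 0) {
    amide <- which(aa != "P")
    tol <- default_tolerances()
    for (k in seq_len(degenerate_pairs)) {
      pr <- sample(amide, 2)
      shifts[pr[2], "H"] <- shifts[pr[1], "H"] +
        stats::runif(1, -0.3, 0.3) * tol[["H"]]
      shifts[pr[2], "N"] <- shifts[pr[1], "N"] +
        stats::runif(1, -0.3, 0.3) * tol[["N"]]
    }
  }

  defs <- standard_spectra()[spectra]
  # emission plan: per spectrum, the resonance-type content of each peak
  emission <- list(
    HSQC     = list(character(0)),
    HNCO     = list("COm"),
    HNCACO   = list("CO", "COm"),
    HNCA     = list("CA", "CAm"),
    HNCOCA   = list("CAm"),
    HNCACB   = list("CA", "CB", "CAm", "CBm"),
    CBCACONH = list("CAm", "CBm"))

  lists <- list()
  truth_rows <- list()
  for (sp in names(defs)) {
    rows <- list()
    for (i in seq_len(n)) {
      if (aa[i] == "P") next                      # no amide root
      for (lab in emission[[sp]]) {
        carbons <- c(H = unname(shifts[i, "H"]), N = unname(shifts[i, "N"]))
        if (base::length(lab)) {
          src <- if (label_is_prev(lab)) i - 1L else i
          if (src < 1L) next
          v <- shifts[src, label_base(lab)]
          if (!is.finite(v)) next                 # e.g. glycine CB
          carbons <- c(carbons, C = unname(v))
        }
        nuc <- c("H", "N", if (base::length(lab)) "C")
        obs <- carbons + stats::rnorm(base::length(carbons), 0, noise[nuc])
        int <- exp(stats::rnorm(1, log(1e6), 0.4)) *
          (if (base::length(lab) && label_base(lab) == "CB") -1 else 1)
        rows[[base::length(rows) + 1L]] <-
          c(obs, intensity = int, residue = i)
        truth_rows[[base::length(truth_rows) + 1L]] <- data.frame(
          spectrum = sp, residue = i,
          type = if (base::length(lab)) lab else "amide",
          stringsAsFactors = FALSE)
      }
    }
    nd <- base::length(defs[[sp]]$dim_nuclei)
    if (base::length(rows)) {
      m <- do.call(rbind, rows)
      df <- data.frame(id = seq_len(nrow(m)), spectrum = sp)
      for (d in seq_len(nd)) df[[paste0("w", d)]] <- m[, d]
      df$intensity <- m[, nd + 1L]
      df$residue <- as.integer(m[, nd + 2L])
    } else {
      df <- data.frame(id = integer(0), spectrum = character(0))
      for (d in seq_len(nd)) df[[paste0("w", d)]] <- numeric(0)
      df$intensity <- numeric(0)
      df$residue <- integer(0)
    }
    attr(df, "spectrum") <- defs[[sp]]
    lists[[sp]] <- df
  }
  reference <- data.frame(residue = seq_len(n),
                          H = shifts[, "H"], N = shifts[, "N"])
  reference[aa == "P", c("H", "N")] <- NA_real_
  structure(list(sequence = sequence, shifts = shifts, peak_lists = lists,
                 truth = do.call(rbind, truth_rows), reference = reference),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nchar(x$sequence), " residues; peaks: ",
      paste(names(x$peak_lists),
            vapply(x$peak_lists, nrow, 0L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Describe a data-degradation condition
#'
#' @param retain Named retention probabilities per peak class: `CA`,
#'   `CB`, `CO` (keyed by the carbon content of the peak) and `HSQC`.
#' @param ss_retention Fraction of spin systems (residues) retained.
#' @param mode Spin-system deletion mode: `"random"` residues or
#'   `"contiguous5"` (disjoint stretches of five consecutive residues).
#' @param artifact_fraction Fraction of carbon crosspeaks that are
#'   artifacts after injection (e.g. 0.2).
#' @param seed Optional integer seed.
#' @return Object of class `degradation_spec`.
#' @export
degradation_spec <- function(retain = c(CA = 1, CB = 1, CO = 1, HSQC = 1),
                             ss_retention = 1,
                             mode = c("random", "contiguous5"),
                             artifact_fraction = 0, seed = NULL) {
  mode <- match.arg(mode)
  full <- c(CA = 1, CB = 1, CO = 1, HSQC = 1)
  full[names(retain)] <- retain
  stopifnot(all(full >= 0 & full <= 1), ss_retention >= 0, ss_retention <= 1,
            artifact_fraction >= 0, artifact_fraction < 1)
  structure(list(retain = full, ss_retention = ss_retention, mode = mode,
                 artifact_fraction = artifact_fraction, seed = seed),
            class = "degradation_spec")
}

# peak class of each row of a peak list ("CA", "CB", "CO" or "HSQC")
peak_class <- function(df) {
  ifelse(df$spectrum == "HSQC", "HSQC",
         ifelse(is.na(df$type) | df$type == "amide", "HSQC",
                label_base(df$type)))
}

#' Degrade a synthetic dataset
#'
#' Applies spin-system deletion (random residues or disjoint contiguous
#' five-residue stretches) followed by per-peak Bernoulli retention keyed
#' by peak class, then optional artifact injection. Deterministic per
#' seed.
#'
#' @param truth A `synthetic_truth`.
#' @param spec A [degradation_spec()].
#' @param stats Residue-type statistics (for artifact injection).
#' @return A degraded `synthetic_truth` (the `reference` is unchanged:
#'   deleted residues count as missing when scoring).
#' @export
degrade_dataset <- function(truth, spec, stats = residue_type_stats()) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(spec, "degradation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  aa <- strsplit(truth$sequence, "")[[1]]
  amide <- which(aa != "P")
  deleted <- integer(0)
  if (spec$ss_retention < 1) {
    n_del <- round((1 - spec$ss_retention) * base::length(amide))
    if (spec$mode == "random") {
      deleted <- sample(amide, n_del)
    } else {
      runs <- max(1L, round(n_del / 5))
      starts <- integer(0)
      guard <- 0L
      while (base::length(starts) < runs && guard < 10000L) {
        guard <- guard + 1L
        s <- sample.int(nchar(truth$sequence) - 4L, 1L)
        if (!any(abs(starts - s) < 6L)) starts <- c(starts, s)
      }
      deleted <- intersect(unlist(lapply(starts, function(s) s:(s + 4L))),
                           amide)
    }
  }
  for (sp in names(truth$peak_lists)) {
    df <- truth$peak_lists[[sp]]
    if (!nrow(df)) next
    df$type <- truth$truth[truth$truth$spectrum == sp, "type"]
    keep <- !(df$residue %in% deleted)
    cls <- peak_class(df)
    p <- spec$retain[cls]
    keep <- keep & (stats::runif(nrow(df)) <= p)
    df <- df[keep, , drop = FALSE]
    tr <- truth$truth[truth$truth$spectrum == sp, , drop = FALSE][keep, , drop = FALSE]
    df$type <- NULL
    truth$peak_lists[[sp]] <- df
    truth$truth <- rbind(truth$truth[truth$truth$spectrum != sp, ], tr)
  }
  if (spec$artifact_fraction > 0)
    truth <- inject_artifacts(truth, spec$artifact_fraction, stats)
  truth
}

#' Inject artifact crosspeaks
#'
#' Adds randomly generated carbon crosspeaks until the requested fraction
#' of all CA/CB/CO-bearing peaks are artifacts. Each artifact picks a
#' random amide-bearing residue and a peak type its spectra can produce;
#' every dimension is drawn from the residue-type Gaussian of the
#' corresponding atom, and the peak receives the maximum intensity of its
#' list (so it is never eligible for the crosspeak cache).
#'
#' @param truth A `synthetic_truth`.
#' @param fraction Target artifact fraction among carbon peaks.
#' @param stats Residue-type statistics.
#' @param seed Optional integer seed.
#' @return The contaminated `synthetic_truth`.
#' @export
inject_artifacts <- function(truth, fraction = 0.2,
                             stats = residue_type_stats(), seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (fraction == 0) return(truth)
  aa <- strsplit(truth$sequence, "")[[1]]
  carbon_specs <- setdiff(names(truth$peak_lists), "HSQC")
  n_carbon <- sum(vapply(truth$peak_lists[carbon_specs], nrow, 0L))
  n_art <- round(fraction * n_carbon / (1 - fraction))
  emission <- list(HNCO = "COm", HNCACO = c("CO", "COm"),
                   HNCA = c("CA", "CAm"), HNCOCA = "CAm",
                   HNCACB = c("CA", "CB", "CAm", "CBm"),
                   CBCACONH = c("CAm", "CBm"))
  draw <- function(a, r) {
    ms <- stats_lookup(stats, a, r)
    stats::rnorm(1, ms["mean"], ms["sd"])
  }
  for (k in seq_len(n_art)) {
    sp <- carbon_specs[sample.int(base::length(carbon_specs), 1L)]
    types <- emission[[sp]]
    repeat {
      lab <- types[sample.int(base::length(types), 1L)]
      i <- sample(which(aa != "P"), 1L)
      src <- if (label_is_prev(lab)) i - 1L else i
      if (src >= 1L && !(label_base(lab) == "CB" && aa[src] == "G")) break
    }
    df <- truth$peak_lists[[sp]]
    w <- c(draw(aa[i], "H"), draw(aa[i], "N"), draw(aa[src], label_base(lab)))
    row <- data.frame(id = if (nrow(df)) max(df$id) + 1L else 1L,
                      spectrum = sp, w1 = w[1], w2 = w[2], w3 = w[3],
                      intensity = if (nrow(df)) max(abs(df$intensity)) else 1e6,
                      residue = NA_integer_)
    at <- attr(df, "spectrum")
    df <- rbind(df, row)
    attr(df, "spectrum") <- at
    truth$peak_lists[[sp]] <- df
    truth$truth <- rbind(truth$truth,
                         data.frame(spectrum = sp, residue = NA_integer_,
                                    type = "artifact",
                                    stringsAsFactors = FALSE))
  }
  truth
}

#' Structure-predictor-quality predictions for a synthetic dataset
#'
#' Emulates predictions from a good structure-based (or sequence-specific
#' random-coil) shift predictor: each residue's prediction is its true
#' shift plus Gaussian error of the predictor's reported accuracy, with
#' that accuracy attached as the prediction error. Complements the
#' `residue_stats` mode (type mean with type SD), which emulates
#' database-only knowledge.
#'
#' @param truth A `synthetic_truth`.
#' @param sigma Named per-resonance predictor RMSDs in ppm
#'   (default [structure_sigma_defaults()]).
#' @param seed Optional integer seed.
#' @return A `shift_predictions` object.
#' @export
synthetic_predictions <- function(truth, sigma = structure_sigma_defaults(),
                                  seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit(truth$sequence, "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    for (r in c("H", "N", "CA", "CB", "CO")) {
      v <- truth$shifts[i, r]
      if (!is.finite(v)) next
      rows[[base::length(rows) + 1L]] <- data.frame(
        residue_index = i, aa = aa[i], resonance = r,
        delta_pred = v + stats::rnorm(1, 0, sigma[[r]]),
        sigma = unname(sigma[[r]]), source = "table",
        stringsAsFactors = FALSE)
    }
  }
  preds <- do.call(rbind, rows)
  class(preds) <- c("shift_predictions", "data.frame")
  attr(preds, "sequence") <- truth$sequence
  preds
}
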