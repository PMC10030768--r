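#' Read a protein sequence from FASTA
#'
#' The file must contain exactly one record. The sequence is returned as an
#' upper-case one-letter string; residues are indexed 1-based throughout the
#' package, so the "i-1" resonances of the spin system placed at position n
#' refer to residue n-1.
#'
#' @param path Path to a FASTA file with a single amino-acid record.
#' @return Single upper-case character string.
#' @export
read_sequence <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) != 1L)
    stop("expected exactly one FASTA record, found ", length(recs))
  seq <- toupper(gsub("[[:space:]]", "", as.character(recs[[1]])))
  validate_sequence(seq)
  seq
}

validate_sequence <- function(seq) {
  letters <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters, AA_LETTERS)
  if (length(bad))
    stop("illegal amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  invisible(seq)
}

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a Sparky-style peak list
#'
#' Whitespace-delimited peak lists as written by NMRFAM-SPARKY: an optional
#' non-numeric assignment-label column (ignored), one shift column per
#' spectrum dimension, and an optional trailing intensity ("Data Height")
#' column. Header and comment lines are skipped.
#'
#' @param path Path to the peak list.
#' @param spectrum A [spectrum_definition()] describing the experiment.
#' @return A `data.frame` with columns `id`, `spectrum`, `w1`..`wD`,
#'   `intensity` (NA where absent); the spectrum definition is attached as
#'   attribute `"spectrum"`. Row order follows file order.
#' @export
read_peak_list <- function(path, spectrum) {
  stopifnot(inherits(spectrum, "spectrum_def"))
  nd <- length(spectrum$dim_nuclei)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    # header lines ("Assignment w1 w2 ...") and label columns are non-numeric
    num <- suppressWarnings(as.numeric(toks))
    if (is.na(num[1]) && grepl("Assignment|w1|Height", line)) next
    if (is.na(num[1])) {            # leading assignment label: drop it
      toks <- toks[-1]
      num <- num[-1]
    }
    if (anyNA(num))
      stop("malformed numeric field on line ", ln, " of ", path)
    if (!(length(num) == nd || length(num) == nd + 1L))
      stop("line ", ln, " of ", path, " has ", length(num),
           " numeric fields; expected ", nd, " (+ optional intensity)")
    rows[[length(rows) + 1L]] <-
      c(num[seq_len(nd)], if (length(num) > nd) num[nd + 1L] else NA_real_)
  }
  if (!length(rows)) {
    warning("empty peak list: ", path)
    m <- matrix(numeric(0), ncol = nd + 1L)
  } else m <- do.call(rbind, rows)
  out <- data.frame(id = seq_len(nrow(m)), spectrum = rep(spectrum$name, nrow(m)))
  for (d in seq_len(nd)) out[[paste0("w", d)]] <- m[, d]
  out$intensity <- m[, nd + 1L]
  attr(out, "spectrum") <- spectrum
  out
}

#' Write a Sparky-style peak list
#'
#' Inverse of [read_peak_list()]: writes an `Assignment` label column
#' (`?-?-?`), shifts to three decimals, and an intensity column when any
#' intensity is present.
#'
#' @param peaks Peak `data.frame` as returned by [read_peak_list()].
#' @param path Output path.
#' @export
write_peak_list <- function(peaks, path) {
  nd <- sum(grepl("^w[0-9]+$", names(peaks)))
  has_int <- any(is.finite(peaks$intensity))
  hdr <- paste(c("Assignment", paste0("w", seq_len(nd)),
                 if (has_int) "Data Height"), collapse = "\t")
  lab <- paste(rep("?", nd), collapse = "-")
  lines <- hdr
  for (i in seq_len(nrow(peaks))) {
    v <- sprintf("%.3f", unlist(peaks[i, paste0("w", seq_len(nd))]))
    int <- if (has_int) sprintf("%.3f", peaks$intensity[i])
    lines <- c(lines, paste(c(lab, v, int), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Packaged residue-type chemical-shift statistics
#'
#' Loads the per-amino-acid mean and standard deviation of backbone H, N,
#' CA, CB and CO chemical shifts. The packaged table
#' (`residue_type_stats_synthetic.tsv`) is a synthetic BMRB-like fixture:
#' values approximate the familiar empirical BMRB distributions so that the
#' residue-statistics prediction mode and the synthetic data generator work
#' offline. Supply `path` to use real database statistics instead.
#'
#' @param path Optional path to a TSV with columns
#'   `aa`, `resonance`, `mean`, `sd`.
#' @return `data.frame` with those four columns.
#' @export
residue_type_stats <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residue_type_stats_synthetic.tsv",
                        package = "bbanneal", mustWork = TRUE)
  st <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "resonance", "mean", "sd") %in% names(st)))
  if (any(st$sd <= 0)) stop("residue-type statistics must have sd > 0")
  need <- expand.grid(aa = AA_LETTERS, resonance = c("N", "CA", "CO"),
                      stringsAsFactors = FALSE)
  have <- paste(st$aa, st$resonance)
  if (!all(paste(need$aa, need$resonance) %in% have))
    stop("residue-type statistics incomplete")
  st
}

stats_lookup <- function(stats, aa, resonance) {
  i <- which(stats$aa == aa & stats$resonance == resonance)
  if (!length(i)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = stats$mean[i[1]], sd = stats$sd[i[1]])
}

#' Default per-resonance prediction errors
#'
#' Global root-mean-square prediction errors attached to structure-based
#' shift predictions (ppm): 0.45 (H), 2.4 (N), 0.8 (CA), 0.95 (CB),
#' 0.9 (CO).
#' @return Named numeric vector.
#' @export
structure_sigma_defaults <- function()
  c(H = 0.45, N = 2.4, CA = 0.8, CB = 0.95, CO = 0.9)

#' Random-coil prediction errors
#'
#' Reported errors of sequence-specific random-coil shift predictions,
#' appropriate for intrinsically disordered proteins (ppm): 0.16 (H),
#' 1.0 (N), 0.42 (CA), 0.37 (CB), 0.43 (CO).
#' @return Named numeric vector.
#' @export
random_coil_sigma_defaults <- function()
  c(H = 0.16, N = 1.0, CA = 0.42, CB = 0.37, CO = 0.43)

#' Read or construct per-residue shift predictions
#'
#' In `"table"` mode a TSV of predicted shifts (columns `residue_index`,
#' `aa`, `resonance`, `delta_pred` and optionally `sigma`) is read; rows
#' without a `sigma` get the global per-resonance error from `sigma`
#' (defaults: structure-based prediction RMSDs). Residues of the sequence
#' absent from the table fall back to residue-type statistics. In
#' `"residue_stats"` mode every residue's prediction is the per-type mean
#' with the distribution SD as error.
#'
#' Chemistry is enforced: prolines carry no amide-H prediction and glycines
#' no CB. Missing predictions simply drop the corresponding resonance from
#' the chi-square downstream.
#'
#' @param path Prediction table path (`table` mode) or `NULL`.
#' @param sequence One-letter sequence string.
#' @param stats Residue-type statistics, see [residue_type_stats()].
#' @param mode `"table"` or `"residue_stats"`.
#' @param sigma Named per-resonance global errors used in `table` mode when
#'   the table has no `sigma` column.
#' @return `data.frame` (class `shift_predictions`) with columns
#'   `residue_index`, `aa`, `resonance`, `delta_pred`, `sigma`, `source`;
#'   the sequence is attached as attribute `"sequence"`.
#' @export
read_shift_predictions <- function(path = NULL, sequence,
                                   stats = residue_type_stats(),
                                   mode = c("residue_stats", "table"),
                                   sigma = structure_sigma_defaults()) {
  mode <- match.arg(mode)
  validate_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  res_names <- c("H", "N", "CA", "CB", "CO")

  from_stats <- function(idx) {
    out <- list()
    for (i in idx) {
      for (r in res_names) {
        if (r == "H" && aa[i] == "P") next
        if (r == "CB" && aa[i] == "G") next
        ms <- stats_lookup(stats, aa[i], r)
        if (!is.finite(ms["mean"])) next
        out[[length(out) + 1L]] <- data.frame(
          residue_index = i, aa = aa[i], resonance = r,
          delta_pred = unname(ms["mean"]), sigma = unname(ms["sd"]),
          source = "residue_stats", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }

  if (mode == "residue_stats") {
    preds <- from_stats(seq_len(n))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(c("residue_index", "aa", "resonance", "delta_pred")
                  %in% names(tab)))
    if (any(tab$residue_index < 1 | tab$residue_index > n))
      stop("prediction residue index outside sequence (1..", n, ")")
    if (any(tab$aa != aa[tab$residue_index]))
      stop("prediction table amino acids disagree with the sequence")
    if (!all(tab$resonance %in% res_names))
      stop("unknown resonance in prediction table")
    sg <- if ("sigma" %in% names(tab)) tab$sigma else rep(NA_real_, nrow(tab))
    sg[!is.finite(sg)] <- sigma[tab$resonance[!is.finite(sg)]]
    keep <- !(tab$resonance == "H" & tab$aa == "P") &
            !(tab$resonance == "CB" & tab$aa == "G")
    preds <- data.frame(residue_index = tab$residue_index, aa = tab$aa,
                        resonance = tab$resonance,
                        delta_pred = tab$delta_pred, sigma = sg,
                        source = "table", stringsAsFactors = FALSE)[keep, ]
    missing_res <- setdiff(seq_len(n), unique(preds$residue_index))
    if (length(missing_res)) preds <- rbind(preds, from_stats(missing_res))
    preds <- preds[order(preds$residue_index, match(preds$resonance, res_names)), ]
  }
  if (any(preds$sigma <= 0)) stop("prediction errors must be positive")
  if (anyDuplicated(preds[c("residue_index", "resonance")]))
    stop("duplicate prediction for a (residue, resonance) pair")
  rownames(preds) <- NULL
  class(preds) <- c("shift_predictions", "data.frame")
  attr(preds, "sequence") <- sequence
  preds
}

# N x 5 matrices of predicted shifts and errors (NA where no prediction)
pred_matrices <- function(preds) {
  sequence <- attr(preds, "sequence")
  n <- nchar(sequence)
  res_names <- c("H", "N", "CA", "CB", "CO")
  delta <- sig <- matrix(NA_real_, n, 5, dimnames = list(NULL, res_names))
  ij <- cbind(preds$residue_index, match(preds$resonance, res_names))
  delta[ij] <- preds$delta_pred
  sig[ij] <- preds$sigma
  list(delta = delta, sigma = sig, sequence = sequence)
}

#' Write the final assignment table
#'
#' Tab-separated, one row per residue: index, amino acid, status
#' (`assigned`/`unassigned`), spin-system id, ensemble vote fraction,
#' posterior probability, connectivity count, and the assigned spin
#' system's mean H, N, CA, CB, CO shifts.
#'
#' @param result A `consensus_result` or `backbone_assignment` object.
#' @param path Output path.
#' @export
write_assignment_table <- function(result, path) {
  tab <- as.data.frame(result)
  num <- vapply(tab, is.numeric, TRUE) & names(tab) != "residue"
  tab[num] <- lapply(tab[num], function(x) ifelse(is.na(x), NA, round(x, 4)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an assignment table
#'
#' @param path Path written by [write_assignment_table()].
#' @return `data.frame` with the table's columns.
#' @export
read_assignment_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Export assigned chemical shifts as an NMR-STAR loop
#'
#' Writes a minimal NMR-STAR 3.1 `_Atom_chem_shift` loop containing the
#' mean shift of every resonance of every assigned residue.
#'
#' @param result A `consensus_result` or `backbone_assignment` object.
#' @param path Output path.
#' @export
write_star_shifts <- function(result, path) {
  tab <- as.data.frame(result)
  lines <- c("data_assignments", "", "save_assigned_chemical_shifts",
             "   _Assigned_chem_shift_list.Sf_category  assigned_chemical_shifts",
             "   loop_",
             "      _Atom_chem_shift.ID",
             "      _Atom_chem_shift.Seq_ID",
             "      _Atom_chem_shift.Comp_ID",
             "      _Atom_chem_shift.Atom_ID",
             "      _Atom_chem_shift.Val")
  atom_ids <- c(H = "H", N = "N", CA = "CA", CB = "CB", CO = "C")
  k <- 0L
  for (i in seq_len(nrow(tab))) {
    if (tab$status[i] != "assigned") next
    for (r in names(atom_ids)) {
      v <- tab[[r]][i]
      if (is.null(v) || !is.finite(v)) next
      k <- k + 1L
      lines <- c(lines, sprintf("      %d %d %s %s %.3f", k, tab$residue[i],
                                tab$aa[i], atom_ids[[r]], v))
    }
  }
  lines <- c(lines, "   stop_", "save_")
  writeLines(lines, path)
  invisible(path)
}
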