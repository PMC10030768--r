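# Resonance labels used throughout. The "m" suffix marks an (i-1) resonance:
# CAm is the Calpha of the preceding residue observed through this amide.
RES_LABELS <- c("H", "N", "CA", "CB", "CO", "CAm", "CBm", "COm")

#' Default shift-matching tolerances
#'
#' Per-nucleus chemical-shift matching cutoffs (ppm) used during spin-system
#' assembly and connectivity counting: 0.03 ppm for amide protons, 0.3 ppm
#' for nitrogen and carbon.
#'
#' @return Named numeric vector with elements `H`, `N`, `C`.
#' @export
default_tolerances <- function() c(H = 0.03, N = 0.3, C = 0.3)

#' Define a triple-resonance spectrum
#'
#' A spectrum definition names the experiment, its dimensions (nucleus class
#' per dimension) and the candidate resonance-type labels each dimension can
#' carry. Ambiguity lives in the candidate sets: the carbon dimension of an
#' HNCA peak, for example, can be the residue's own Calpha (`CA`) or that of
#' the preceding residue (`CAm`).
#'
#' @param name Identifier, e.g. `"HNCA"`.
#' @param dim_nuclei Character vector of nucleus classes, one per dimension;
#'   each must be `"H"`, `"N"` or `"C"`.
#' @param dim_types List of character vectors, one per dimension, giving the
#'   candidate resonance-type labels for that dimension (subset of
#'   `H, N, CA, CB, CO, CAm, CBm, COm`).
#' @param tolerances Named per-nucleus matching cutoffs in ppm
#'   (see [default_tolerances()]).
#' @return An object of class `spectrum_def`.
#' @export
spectrum_definition <- function(name, dim_nuclei, dim_types,
                                tolerances = default_tolerances()) {
  stopifnot(is.character(name), length(name) == 1L)
  dim_nuclei <- as.character(dim_nuclei)
  if (!all(dim_nuclei %in% c("H", "N", "C")))
    stop("dim_nuclei must be 'H', 'N' or 'C'")
  if (length(dim_types) != length(dim_nuclei))
    stop("dim_types must have one candidate set per dimension")
  for (d in seq_along(dim_types)) {
    if (!all(dim_types[[d]] %in% RES_LABELS))
      stop("unknown resonance label in dim_types for spectrum ", name)
    if (length(dim_types[[d]]) < 1L)
      stop("empty candidate set in spectrum ", name)
  }
  tol <- tolerances[dim_nuclei]
  if (any(!is.finite(tol)) || any(tol <= 0))
    stop("tolerances must be strictly positive for every dimension nucleus")
  structure(list(name = name, dim_nuclei = dim_nuclei,
                 dim_types = dim_types, tolerances = unname(tol)),
            class = "spectrum_def")
}

#' @export
print.spectrum_def <- function(x, ...) {
  cands <- vapply(x$dim_types, paste, "", collapse = "/")
  cat("<spectrum_def> ", x$name, ": ",
      paste0(x$dim_nuclei, "[", cands, "]", collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Standard backbone triple-resonance spectrum set
#'
#' Definitions for the seven canonical backbone assignment experiments:
#' HSQC, HNCO, HN(CA)CO, HNCA, HN(CO)CA, HNCACB and CBCA(CO)NH. All share
#' the amide H-N root; carbon dimensions carry the usual intra/sequential
#' ambiguity (e.g. HNCA: `CA` or `CAm`).
#'
#' @param tolerances Per-nucleus matching cutoffs in ppm.
#' @return Named list of `spectrum_def` objects.
#' @export
standard_spectra <- function(tolerances = default_tolerances()) {
  sd <- function(name, types)
    spectrum_definition(name, c("H", "N", "C")[seq_along(types)], types,
                        tolerances)
  list(
    HSQC     = sd("HSQC",     list("H", "N")),
    HNCO     = sd("HNCO",     list("H", "N", "COm")),
    HNCACO   = sd("HNCACO",   list("H", "N", c("CO", "COm"))),
    HNCA     = sd("HNCA",     list("H", "N", c("CA", "CAm"))),
    HNCOCA   = sd("HNCOCA",   list("H", "N", "CAm")),
    HNCACB   = sd("HNCACB",   list("H", "N", c("CA", "CB", "CAm", "CBm"))),
    CBCACONH = sd("CBCACONH", list("H", "N", c("CAm", "CBm")))
  )
}

# nucleus class of a resonance label ("CAm" -> "C", "H" -> "H", ...)
label_nucleus <- function(label) {
  ifelse(label == "H", "H", ifelse(label == "N", "N", "C"))
}

# base (i)-level atom of a label: "CAm" -> "CA"
label_base <- function(label) sub("m$", "", label)

# TRUE for (i-1)-type labels
label_is_prev <- function(label) grepl("m$", label)
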