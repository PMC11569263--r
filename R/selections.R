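#' Transmembrane-helix residue-range presets
#'
#' Residue ranges (human Orai1 numbering, 1-based, inclusive) for the four
#' transmembrane helices. Two TM3 presets are provided: `TM3` (170-195) is
#' the display/selection range, `TM3_FIT` (179-185) the narrower range used
#' for superposition-based RMSD.
#'
#' @format Named list of length-2 integer vectors `c(first, last)`.
#' @export
tm_presets <- list(
  TM1     = c(80L, 110L),
  TM2     = c(120L, 150L),
  TM3     = c(170L, 195L),
  TM3_FIT = c(179L, 185L),
  TM4     = c(235L, 262L)
)

#' Build an atom selection specification
#'
#' A selection combines an inclusive residue-number range, a set of atom
#' names and a set of subunit (chain) identifiers. All three conditions must
#' hold for an atom to match.
#'
#' @param residues Length-2 numeric `c(lo, hi)` (inclusive, `lo <= hi`), a
#'   single residue number, or the name of a preset in [tm_presets].
#' @param atom_names Character vector of atom names (e.g. `"CA"`, `"CG"`).
#' @param subunits Character vector of subunit ids, or `"all"`.
#' @return An object of class `"selection_spec"`.
#' @examples
#' selection_spec("TM1")                       # Calpha of residues 80-110
#' selection_spec(181, c("CA", "CG"), "A")
#' @export
selection_spec <- function(residues, atom_names = "CA", subunits = "all") {
  if (is.character(residues)) {
    if (!residues %in% names(tm_presets))
      stop("unknown residue-range preset '", residues, "'")
    residues <- tm_presets[[residues]]
  }
  if (length(residues) == 1L) residues <- c(residues, residues)
  stopifnot(length(residues) == 2L, is.numeric(residues))
  if (residues[1] > residues[2])
    stop("residue range lo > hi: ", residues[1], " > ", residues[2])
  structure(
    list(residues = as.integer(residues),
         atom_names = as.character(atom_names),
         subunits = as.character(subunits)),
    class = "selection_spec")
}

#' @export
format.selection_spec <- function(x, ...) {
  sprintf("residues %d-%d, atoms {%s}, subunits {%s}",
          x$residues[1], x$residues[2],
          paste(x$atom_names, collapse = ","),
          paste(x$subunits, collapse = ","))
}

#' @export
print.selection_spec <- function(x, ...) {
  cat("<selection_spec>", format(x), "\n")
  invisible(x)
}

#' Select atoms from a frame
#'
#' Returns the atoms of `frame` matching the residue range AND atom names
#' AND subunits of `spec`, in their original order. Selection is idempotent
#' and order-stable.
#'
#' @param frame A [md_frame] object.
#' @param spec A [selection_spec].
#' @return A data frame of atom records (subset of `frame$atoms`).
#' @export
select_atoms <- function(frame, spec) {
  stopifnot(inherits(frame, "md_frame"), inherits(spec, "selection_spec"))
  a <- frame$atoms
  keep <- a$residue_number >= spec$residues[1] &
          a$residue_number <= spec$residues[2] &
          a$atom_name %in% spec$atom_names
  if (!identical(spec$subunits, "all"))
    keep <- keep & a$subunit_id %in% spec$subunits
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("empty selection: ", format(spec))
  a[keep, , drop = FALSE]
}

# coordinate matrix (n x 3) of a selection (or of all atoms if spec NULL)
sel_coords <- function(frame, spec = NULL) {
  a <- if (is.null(spec)) frame$atoms else select_atoms(frame, spec)
  m <- cbind(a$x, a$y, a$z)
  colnames(m) <- c("x", "y", "z")
  m
}
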