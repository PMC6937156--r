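# The four N-sulfamoyl transition-state analogs: elemental formulas, a
# Hill-notation parser and a formula-weight utility.

#' Standard atomic weights
#'
#' Atomic weights (g/mol) to 3 decimals. Sulfur is carried as 32.065 (the
#' 2005 IUPAC conventional value): with the current abridged 32.06 the
#' 2-decimal formula weights printed for these compounds (226.21, 540.59,
#' 232.2) do not all reproduce; with 32.065 they do. See the methods
#' vignette.
#'
#' @return named numeric vector, element symbol -> g/mol.
#' @export
atomic_weights <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.990, Mg = 24.305,
    P = 30.974, S = 32.065, Cl = 35.453, K = 39.098, Ca = 40.078,
    Mn = 54.938, Fe = 55.845, Cu = 63.546, Zn = 65.380, Br = 79.904)
}

#' Parse a Hill-notation formula string
#'
#' @param formula e.g. "C5H10N2O6S". Counts default to 1.
#' @return named integer vector, element -> count.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(stats::setNames(as.integer(formula), names(formula)))
  }
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Molecular weight of an elemental formula
#'
#' Sum of count x standard atomic weight, reported to 2 decimals (round half
#' up) by default.
#'
#' @param formula Hill-notation string or named element->count vector.
#' @param digits decimals to round to (half-up); NULL for full precision.
#' @return weight in g/mol.
#' @export
molecular_weight <- function(formula, digits = 2) {
  counts <- parse_formula(formula)
  if (any(counts <= 0)) stop("formula counts must be positive")
  w <- atomic_weights()
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown) > 0)
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  mw <- sum(counts * w[names(counts)])
  if (is.null(digits)) mw else round_half_up(mw, digits)
}

#' Round half away from zero
#'
#' The tables here render 2-decimal values with conventional (half-up)
#' rounding, not the half-to-even rule of [round()].
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Catalog of the N-sulfamoyl transition-state analogs
#'
#' The four inhibitors mimicking the tetrahedral intermediate of
#' carboxypeptidase-catalyzed hydrolysis: N-sulfamoyl derivatives of Glu,
#' Leu, Arg and Phe. Atom names follow the scheme used in the subsite
#' distance tables: sulfamoyl S18/N17/N19/O20/O21, Calpha C13, carboxylate
#' C14/O15/O16. The SGlu formula is as determined analytically; the other
#' three are derived from the parent amino acid plus the sulfamoyl
#' substitution (-H +SO2NH2) and flagged `derived`.
#'
#' @return data.frame with one row per ligand: code, chemical name, formula,
#'   mw (g/mol), derived flag; atom-name sets are attached as the
#'   `atom_scheme` attribute (shared by all four ligands).
#' @export
ligand_catalog <- function() {
  cat <- data.frame(
    code = c("SGlu", "SLeu", "SArg", "SPhe"),
    name = c("N-(aminosulfonyl)-L-glutamic acid",
             "N-(aminosulfonyl)-L-leucine",
             "N-(aminosulfonyl)-L-arginine",
             "N-(aminosulfonyl)-L-phenylalanine"),
    formula = c("C5H10N2O6S", "C6H14N2O4S", "C6H15N5O4S", "C9H12N2O4S"),
    derived = c(FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  cat$mw <- vapply(cat$formula, molecular_weight, numeric(1))
  attr(cat, "atom_scheme") <- list(
    sulfamoyl = c("S18", "N17", "N19", "O20", "O21"),
    carboxylate = c("C14", "O15", "O16"),
    calpha = "C13")
  cat
}
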