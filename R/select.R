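# Atom addressing: altloc-aware resolution of a single atom, Calpha
# selections, and identification of the bound ligand het group.

.apply_altloc <- function(rows, policy, altloc_char, what) {
  if (nrow(rows) <= 1) return(rows)
  alts <- rows$alt_loc
  if (all(!nzchar(alts)))
    stop("ambiguous atom match (duplicate records, no altloc) for ", what)
  if (policy == "explicit") {
    if (is.null(altloc_char)) stop("altloc policy 'explicit' needs altloc_char")
    rows <- rows[rows$alt_loc == altloc_char, , drop = FALSE]
    if (nrow(rows) == 0) stop("no altloc '", altloc_char, "' for ", what)
  } else if (policy == "first") {
    rows <- rows[1, , drop = FALSE]
  } else { # highest_occupancy, ties to lexicographically smallest altloc
    rows <- rows[order(-rows$occupancy, rows$alt_loc), , drop = FALSE][1, , drop = FALSE]
  }
  if (nrow(rows) > 1) stop("ambiguous atom match after altloc policy for ", what)
  rows
}

#' Identify the bound ligand hetero group
#'
#' The ligand is taken to be the unique non-water hetero group with at least
#' 3 atoms, which excludes monoatomic species (Zn2+, Ca2+, Na+) and waters.
#' If several groups qualify (e.g. a bound sulfate alongside the inhibitor),
#' `res_name` must name the ligand explicitly.
#'
#' @param structure a `tsa_structure`.
#' @param res_name optional het code disambiguating between candidate groups.
#' @return data.frame with the ligand group's chain_id, res_seq, i_code,
#'   res_name (one row).
#' @export
ligand_group <- function(structure, res_name = NULL) {
  a <- structure$atoms
  het <- a[a$is_hetero & !(toupper(a$res_name) %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(het) == 0) stop("no hetero groups: structure has no ligand")
  key <- paste(het$chain_id, het$res_seq, het$i_code, het$res_name, sep = "|")
  sizes <- table(key)
  cand <- names(sizes)[sizes >= 3]
  if (!is.null(res_name)) {
    cand <- cand[vapply(strsplit(cand, "\\|"), function(p) p[4] == res_name,
                        logical(1))]
  }
  if (length(cand) == 0) stop("no ligand group (>=3 atoms) found")
  if (length(cand) > 1)
    stop("multiple candidate ligand groups (",
         paste(cand, collapse = "; "),
         "); disambiguate with res_name")
  p <- strsplit(cand, "\\|")[[1]]
  data.frame(chain_id = p[1], res_seq = as.integer(p[2]), i_code = p[3],
             res_name = p[4], stringsAsFactors = FALSE)
}

#' Resolve a single atom by name and residue
#'
#' Applies the altloc policy so a query yields exactly one atom or a defined
#' error. Pass `ligand = TRUE` to address atoms of the bound ligand group
#' (see [ligand_group()]) without knowing its residue number, or
#' `metal = "ZN"` to address a monoatomic metal ion by element.
#'
#' @param structure a `tsa_structure`.
#' @param name atom name, e.g. "CA", "OE2", "S18".
#' @param res_seq author residue number; ignored when `ligand` or `metal` is
#'   used.
#' @param chain optional chain id.
#' @param res_name optional residue/het code filter.
#' @param ligand if TRUE, restrict to the ligand het group.
#' @param metal optional element symbol of a metal ion (e.g. "ZN");
#'   overrides `name`.
#' @param altloc policy: "highest_occupancy" (default; ties broken by the
#'   lexicographically smallest altloc character), "first", or "explicit".
#' @param altloc_char altloc character for the "explicit" policy.
#' @return one-row data.frame (an atom record).
#' @export
resolve_atom <- function(structure, name, res_seq = NULL, chain = NULL,
                         res_name = NULL, ligand = FALSE, metal = NULL,
                         altloc = c("highest_occupancy", "first", "explicit"),
                         altloc_char = NULL) {
  altloc <- match.arg(altloc)
  a <- structure$atoms
  if (nrow(a) == 0) stop("empty structure")
  what <- if (!is.null(metal)) paste0("metal ", metal)
          else paste0(if (ligand) "ligand atom " else "atom ", name,
                      if (!is.null(res_seq)) paste0(" in residue ", res_seq) else "")
  if (!is.null(metal)) {
    sel <- a$is_hetero & a$element == toupper(metal)
    if (!any(sel)) { # fall back to res_name (some files lack element column)
      sel <- a$is_hetero & toupper(a$res_name) == toupper(metal)
    }
  } else {
    sel <- a$name == name
    if (ligand) {
      lg <- ligand_group(structure, res_name)
      sel <- sel & a$is_hetero & a$chain_id == lg$chain_id &
        a$res_seq == lg$res_seq & a$i_code == lg$i_code &
        a$res_name == lg$res_name
    } else {
      if (!is.null(res_seq)) sel <- sel & a$res_seq == res_seq
      if (!is.null(res_name)) sel <- sel & a$res_name == res_name
    }
    if (!is.null(chain)) sel <- sel & a$chain_id == chain
  }
  rows <- a[sel, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("missing atom: no match for ", what, " in ", structure$label)
  .apply_altloc(rows, altloc, altloc_char, what)
}

#' Atom position as a 3-vector
#' @param atom one-row atom record (from [resolve_atom()]).
#' @return numeric length-3 vector (x, y, z) in Angstrom.
#' @export
atom_position <- function(atom) c(atom$x, atom$y, atom$z)

#' Alpha-carbon coordinates of the protein chain
#'
#' Selects CA atoms of non-hetero residues (hydrogens and the calcium ion —
#' also named "CA" but hetero — are never included), resolving alternate
#' locations per policy.
#'
#' @inheritParams resolve_atom
#' @return data.frame with chain_id, res_seq, i_code, res_name, x, y, z in
#'   source-file residue order.
#' @export
calpha_coords <- function(structure,
                          altloc = c("highest_occupancy", "first", "explicit"),
                          altloc_char = NULL) {
  altloc <- match.arg(altloc)
  a <- structure$atoms
  ca <- a[!a$is_hetero & a$name == "CA" & a$element != "H" &
            a$element != "CA", , drop = FALSE]
  if (nrow(ca) == 0) return(ca[, c("chain_id", "res_seq", "i_code", "res_name",
                                   "x", "y", "z")])
  key <- paste(ca$chain_id, ca$res_seq, ca$i_code, sep = "|")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    .apply_altloc(ca[key == k, , drop = FALSE], altloc, altloc_char,
                  paste("CA of", k))
  }))
  rownames(out) <- NULL
  out[, c("chain_id", "res_seq", "i_code", "res_name", "x", "y", "z")]
}
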