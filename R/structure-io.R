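#' @keywords internal
"_PACKAGE"

# Columns of the atom table carried by every tsa_structure. Kept flat (one
# data.frame) so selections are plain logical indexing.
.atom_cols <- c("serial", "name", "alt_loc", "res_name", "chain_id", "res_seq",
                "i_code", "x", "y", "z", "occupancy", "b_factor", "element",
                "is_hetero")

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns serial, name, alt_loc, res_name,
#'   chain_id, res_seq, i_code, x, y, z, occupancy, b_factor, element,
#'   is_hetero.
#' @param label identifier, e.g. an accession.
#' @param cell optional numeric length-6 unit cell (a, b, c, alpha, beta,
#'   gamma).
#' @param space_group optional space-group symbol.
#' @return An object of class `tsa_structure`.
#' @export
new_structure <- function(atoms, label = "", cell = NULL, space_group = NULL) {
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  rownames(atoms) <- NULL
  structure(list(label = label, atoms = atoms, cell = cell,
                 space_group = space_group),
            class = "tsa_structure")
}

#' @export
print.tsa_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<tsa_structure> %s: %d atoms (%d protein, %d hetero), %d residues\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(a), sum(!a$is_hetero), sum(a$is_hetero),
              length(unique(paste(a$chain_id, a$res_seq, a$i_code)))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `tsa_structure`.
#' @param protein_only if TRUE, count only non-hetero, non-hydrogen atoms.
#' @return integer count.
#' @export
n_atoms <- function(structure, protein_only = FALSE) {
  a <- structure$atoms
  if (protein_only) a <- a[!a$is_hetero & a$element != "H", , drop = FALSE]
  nrow(a)
}

.guess_element <- function(name, res_name) {
  # PDB names put 2-letter elements (ZN, CA ion, NA, FE) flush left; organic
  # atoms start with the element letter after any digit prefix (e.g. 1HB).
  nm <- gsub("[0-9']", "", name)
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("ZN", "CA", "NA", "MG", "FE", "CL", "MN", "CU", "BR")
  rn <- toupper(res_name)
  ifelse(two %in% known2 & rn %in% known2 & rn == two,
         two, toupper(substr(nm, 1, 1)))
}

#' Read a coordinate file
#'
#' Parses ATOM/HETATM records from a PDB v3.3 fixed-column file or the
#' `atom_site` loop of an mmCIF file into a [new_structure()] object. Waters
#' and metal ions are retained (tagged hetero); hydrogens are retained but
#' excluded from default atom selections such as [calpha_coords()].
#'
#' @param path file path.
#' @param dialect "pdb" or "mmcif"; default guesses from the file extension
#'   (.cif/.mmcif vs anything else).
#' @param label structure label; defaults to the file name without extension.
#' @return a `tsa_structure`.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "auto")
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  if (dialect == "pdb") read_pdb(path, label) else read_mmcif(path, label)
}

#' @rdname read_structure
#' @export
read_pdb <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(keep) == 0) stop("empty structure: no ATOM/HETATM records in ", path)
  ln <- lines[keep]
  f <- function(a, b) substr(ln, a, b)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v) & nzchar(trimws(s)))
    if (length(bad) > 0)
      stop(sprintf("parse error in %s line %d: bad %s field '%s'",
                   path, keep[bad[1]], what, s[bad[1]]))
    v
  }
  cryst <- lines[substr(lines, 1, 6) == "CRYST1"]
  cell <- NULL; sg <- NULL
  if (length(cryst) >= 1) {
    cl <- cryst[1]
    cv <- suppressWarnings(as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                                        substr(cl, 25, 33), substr(cl, 34, 40),
                                        substr(cl, 41, 47), substr(cl, 48, 54))))
    if (all(is.finite(cv))) cell <- cv
    sg <- trimws(substr(cl, 56, 66))
  }
  elem <- trimws(f(77, 78))
  name <- trimws(f(13, 16))
  res_name <- trimws(f(18, 20))
  elem <- ifelse(nzchar(elem), toupper(elem), .guess_element(name, res_name))
  x <- num(f(31, 38), "x"); y <- num(f(39, 46), "y"); z <- num(f(47, 54), "z")
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z)))
    stop("parse error in ", path, ": missing coordinate field")
  occ <- num(f(55, 60), "occupancy"); occ[!is.finite(occ)] <- 1
  bf <- num(f(61, 66), "b_factor"); bf[!is.finite(bf)] <- 0
  atoms <- data.frame(
    serial = as.integer(num(f(7, 11), "serial")),
    name = name,
    alt_loc = trimws(f(17, 17)),
    res_name = res_name,
    chain_id = trimws(f(22, 22)),
    res_seq = as.integer(num(f(23, 26), "res_seq")),
    i_code = trimws(f(27, 27)),
    x = x, y = y, z = z,
    occupancy = occ, b_factor = bf, element = elem,
    is_hetero = rec[keep] == "HETATM",
    stringsAsFactors = FALSE)
  new_structure(atoms, label = label, cell = cell, space_group = sg)
}

#' @rdname read_structure
#' @export
read_mmcif <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0) stop("no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  rows <- character(0)
  for (i in body_start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || l == "#" || startsWith(l, "loop_") || startsWith(l, "_"))
      break
    rows <- c(rows, l)
  }
  if (length(rows) == 0) stop("empty structure: no atom_site rows in ", path)
  tok <- strsplit(rows, "[[:space:]]+")
  nf <- lengths(tok)
  if (any(nf != length(tags)))
    stop(sprintf("parse error in %s: atom_site row %d has %d fields, expected %d",
                 path, which(nf != length(tags))[1],
                 nf[nf != length(tags)][1], length(tags)))
  m <- do.call(rbind, tok)
  colnames(m) <- tags
  pick <- function(...) {
    for (t in c(...)) if (t %in% tags) return(m[, t])
    rep(NA_character_, nrow(m))
  }
  clean <- function(v) ifelse(v %in% c(".", "?") | is.na(v), "", v)
  numv <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (any(!is.finite(out) & nzchar(clean(v))))
      stop("parse error in ", path, ": bad ", what, " value")
    out
  }
  occ <- numv(pick("occupancy"), "occupancy"); occ[!is.finite(occ)] <- 1
  bf <- numv(pick("B_iso_or_equiv"), "B"); bf[!is.finite(bf)] <- 0
  name <- gsub('"', "", clean(pick("auth_atom_id", "label_atom_id")))
  res_name <- clean(pick("auth_comp_id", "label_comp_id"))
  elem <- clean(pick("type_symbol"))
  elem <- ifelse(nzchar(elem), toupper(elem), .guess_element(name, res_name))
  atoms <- data.frame(
    serial = as.integer(numv(pick("id"), "id")),
    name = name,
    alt_loc = clean(pick("label_alt_id")),
    res_name = res_name,
    chain_id = clean(pick("auth_asym_id", "label_asym_id")),
    res_seq = as.integer(numv(pick("auth_seq_id", "label_seq_id"), "seq id")),
    i_code = clean(pick("pdbx_PDB_ins_code")),
    x = numv(pick("Cartn_x"), "x"),
    y = numv(pick("Cartn_y"), "y"),
    z = numv(pick("Cartn_z"), "z"),
    occupancy = occ, b_factor = bf, element = elem,
    is_hetero = pick("group_PDB") == "HETATM",
    stringsAsFactors = FALSE)
  new_structure(atoms, label = label)
}

.pdb_atom_name <- function(name, element) {
  # Element symbol occupies columns 13-14; 1-letter-element names shorter
  # than 4 characters are indented by one space.
  ifelse(nchar(name) >= 4 | nchar(element) == 2,
         formatC(name, width = -4), paste0(" ", formatC(name, width = -3)))
}

#' Write a structure in PDB format
#'
#' Coordinates are written with 3 decimals (the format's precision), so a
#' read/write round trip is exact to 0.001 Angstrom.
#'
#' @param structure a `tsa_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$is_hetero, "HETATM", "ATOM"),
                   a$serial, .pdb_atom_name(a$name, a$element), a$alt_loc,
                   a$res_name, a$chain_id, a$res_seq, a$i_code,
                   a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  if (!is.null(structure$cell)) {
    cl <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                  structure$cell[1], structure$cell[2], structure$cell[3],
                  structure$cell[4], structure$cell[5], structure$cell[6],
                  if (is.null(structure$space_group)) "P 1"
                  else structure$space_group)
    lines <- c(cl, lines)
  }
  ok <- tryCatch({ writeLines(c(lines, "END"), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write PDB file: ", path)
  invisible(path)
}
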