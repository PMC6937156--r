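# Kabsch rigid-body superposition on alpha-carbons and the two derived
# geometry tables: per-atom displacements between superposed complexes and
# ligand-to-subsite distances within one complex.

#' Rigid transform constructor
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector (Angstrom).
#' @return object of class `tsa_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation has determinant -1 (reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "tsa_transform")
}

#' @export
print.tsa_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<tsa_transform> rotation %.2f deg, translation |t| = %.3f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param x an n x 3 coordinate matrix, a length-3 vector, or a
#'   `tsa_structure` (all atoms are moved).
#' @param transform a `tsa_transform`.
#' @return object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; tr <- transform$translation
  if (inherits(x, "tsa_structure")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(R), 2, tr, "+")
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  if (is.matrix(x)) return(sweep(x %*% t(R), 2, tr, "+"))
  as.numeric(R %*% x + tr)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform "apply b, then a".
#'
#' @param a,b,transform `tsa_transform` objects.
#' @return a `tsa_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Euclidean distance between two positions
#' @param a,b length-3 numeric vectors (Angstrom).
#' @return distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite position")
  sqrt(sum((a - b)^2))
}

#' Pair alpha-carbons of two structures by residue identity
#'
#' Pairing key is (chain, res_seq, i_code): every residue number present in
#' both structures with a Calpha (after altloc resolution) contributes one
#' pair, in the reference structure's residue order. Residue-name mismatches
#' at a shared number are tolerated (mutant models) but reported via a
#' message.
#'
#' @param ref,mobile `tsa_structure` objects.
#' @return list with matrices `ref_xyz`, `mobile_xyz` (n x 3) and data.frame
#'   `residues` (chain_id, res_seq, i_code).
#' @export
pair_calpha <- function(ref, mobile) {
  ca_r <- calpha_coords(ref)
  ca_m <- calpha_coords(mobile)
  key_r <- paste(ca_r$chain_id, ca_r$res_seq, ca_r$i_code, sep = "|")
  key_m <- paste(ca_m$chain_id, ca_m$res_seq, ca_m$i_code, sep = "|")
  common <- key_r %in% key_m
  if (sum(common) < 3)
    stop("insufficient pairs: only ", sum(common),
         " shared Calpha residues (need >= 3)")
  ca_r <- ca_r[common, , drop = FALSE]
  idx_m <- match(paste(ca_r$chain_id, ca_r$res_seq, ca_r$i_code, sep = "|"),
                 key_m)
  ca_m <- ca_m[idx_m, , drop = FALSE]
  mism <- ca_r$res_name != ca_m$res_name
  if (any(mism))
    message("pair_calpha: residue-name mismatch at ",
            paste(ca_r$res_seq[mism], collapse = ", "),
            " (", ref$label, " vs ", mobile$label, ")")
  list(ref_xyz = as.matrix(ca_r[, c("x", "y", "z")]),
       mobile_xyz = as.matrix(ca_m[, c("x", "y", "z")]),
       residues = ca_r[, c("chain_id", "res_seq", "i_code")])
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinate sets: centroids are aligned, the rotation comes from the
#' SVD of the covariance matrix with the determinant corrected to +1 so a
#' reflection is never returned.
#'
#' @param ref_xyz,mobile_xyz n x 3 matrices of paired coordinates (n >= 3,
#'   not collinear).
#' @param residues optional data.frame identifying the pairs (carried into
#'   the result).
#' @return object of class `tsa_superposition`: `transform` (maps mobile onto
#'   ref), `rmsd` (Angstrom), `n_pairs`, `paired_residues`.
#' @export
kabsch_superpose <- function(ref_xyz, mobile_xyz, residues = NULL) {
  ref_xyz <- as.matrix(ref_xyz); mobile_xyz <- as.matrix(mobile_xyz)
  if (!all(dim(ref_xyz) == dim(mobile_xyz)))
    stop("coordinate sets differ in size")
  n <- nrow(ref_xyz)
  if (n < 3) stop("insufficient pairs: need >= 3, got ", n)
  cen_r <- colMeans(ref_xyz); cen_m <- colMeans(mobile_xyz)
  P <- sweep(mobile_xyz, 2, cen_m)   # mobile, centred
  Q <- sweep(ref_xyz, 2, cen_r)      # reference, centred
  # collinear/coincident point sets leave the rotation underdetermined
  if (sum(svd(Q)$d > 1e-8 * max(1, max(abs(Q)))) < 2 ||
      sum(svd(P)$d > 1e-8 * max(1, max(abs(P)))) < 2)
    stop("degenerate geometry: paired points are collinear or coincident")
  H <- crossprod(P, Q)               # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cen_r - R %*% cen_m)
  dev <- P %*% t(R) - Q
  res <- list(transform = rigid_transform(R, tr),
              rmsd = sqrt(mean(rowSums(dev^2))),
              n_pairs = n,
              paired_residues = residues)
  class(res) <- "tsa_superposition"
  res
}

#' @export
print.tsa_superposition <- function(x, ...) {
  cat(sprintf("<tsa_superposition> %d pairs, rmsd %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Superpose two structures on all shared alpha-carbons
#'
#' Runs [pair_calpha()] then [kabsch_superpose()]. All shared Calpha are
#' used — no outlier trimming or iterative rejection.
#'
#' @param ref,mobile `tsa_structure` objects.
#' @return a `tsa_superposition`.
#' @export
superpose_structures <- function(ref, mobile) {
  p <- pair_calpha(ref, mobile)
  kabsch_superpose(p$ref_xyz, p$mobile_xyz, residues = p$residues)
}

#' Default displacement label set
#'
#' The atoms tracked between superposed complexes: the ligand's sulfamoyl
#' group (S18, N17, N19, O20, O21), Calpha C13, carboxylate C14/O15/O16, the
#' Tyr255 hydroxyl and the Glu277 carboxylate.
#'
#' @return data.frame with columns label, ligand (logical), name, res_seq,
#'   res_name.
#' @export
default_displacement_labels <- function() {
  lig <- c("S18", "N17", "N19", "O20", "O21", "C14", "O16", "O15", "C13")
  rbind(
    data.frame(label = lig, ligand = TRUE, name = lig, res_seq = NA_integer_,
               res_name = NA_character_, stringsAsFactors = FALSE),
    data.frame(label = c("Tyr255 OH", "Glu277 CD", "Glu277 OE1", "Glu277 OE2"),
               ligand = FALSE, name = c("OH", "CD", "OE1", "OE2"),
               res_seq = c(255L, 277L, 277L, 277L),
               res_name = c("TYR", "GLU", "GLU", "GLU"),
               stringsAsFactors = FALSE))
}

#' Per-atom displacements between superposed complexes
#'
#' Superposes `mobile` onto `ref` on all shared Calpha, then reports the
#' Euclidean displacement of each labelled atom between the reference and the
#' transformed mobile structure.
#'
#' @param ref,mobile `tsa_structure` objects.
#' @param labels data.frame as returned by [default_displacement_labels()]
#'   (the default).
#' @param superposition optional precomputed `tsa_superposition` (mobile onto
#'   ref); computed if NULL.
#' @return data.frame of class `tsa_displacement_table` with columns label,
#'   displacement (Angstrom, full precision), plus the superposition as an
#'   attribute.
#' @export
displacement_table <- function(ref, mobile, labels = default_displacement_labels(),
                               superposition = NULL) {
  if (is.null(superposition)) superposition <- superpose_structures(ref, mobile)
  tf <- superposition$transform
  disp <- vapply(seq_len(nrow(labels)), function(i) {
    l <- labels[i, ]
    get1 <- function(s, which_label) {
      tryCatch({
        if (isTRUE(l$ligand)) resolve_atom(s, l$name, ligand = TRUE)
        else resolve_atom(s, l$name, res_seq = l$res_seq,
                          res_name = if (is.na(l$res_name)) NULL else l$res_name)
      }, error = function(e)
        stop("missing atom for label '", l$label, "' in ", which_label,
             " structure (", s$label, "): ", conditionMessage(e)))
    }
    pa <- atom_position(get1(ref, "reference"))
    pb <- apply_transform(atom_position(get1(mobile, "mobile")), tf)
    atom_distance(pa, pb)
  }, numeric(1))
  out <- data.frame(label = labels$label, displacement = disp,
                    stringsAsFactors = FALSE)
  attr(out, "superposition") <- superposition
  class(out) <- c("tsa_displacement_table", "data.frame")
  out
}

#' Default ligand-to-subsite distance pairs
#'
#' The 16 catalytic-subsite contacts tabulated for the N-sulfamoyl
#' complexes: ligand carboxylate and sulfamoyl atoms against Arg129, Asn146,
#' Arg147, Thr205, Tyr255, Glu277 side-chain atoms and the catalytic zinc.
#' For some complexes the Tyr255 OH partner is the other carboxylate oxygen;
#' pass `tyr255_o = "O15"` to swap row 10.
#'
#' @param tyr255_o ligand oxygen partnering Tyr255 OH in row 10 ("O16"
#'   default, "O15" for the SLeu complex).
#' @return data.frame with columns ligand_atom, partner_res_name,
#'   partner_res_seq, partner_name, metal.
#' @export
default_subsite_pairs <- function(tyr255_o = c("O16", "O15")) {
  tyr255_o <- match.arg(tyr255_o)
  df <- data.frame(
    ligand_atom = c("O16", "O15", "O21", "O21", "O15", "O15", "O16", "N19",
                    "N17", tyr255_o, "N19", "N17", "O20", "S18", "O20", "O21"),
    partner_res_name = c("ARG", "ARG", "ARG", "ARG", "ASN", "ARG", "ARG",
                         "THR", "TYR", "TYR", "GLU", "GLU", "GLU",
                         NA, NA, NA),
    partner_res_seq = c(129L, 129L, 129L, 129L, 146L, 147L, 147L, 205L, 255L,
                        255L, 277L, 277L, 277L, NA, NA, NA),
    partner_name = c("NH2", "NH2", "NH1", "NH2", "ND2", "NH1", "NH2", "O",
                     "OH", "OH", "OE1", "OE2", "OE1", NA, NA, NA),
    metal = c(rep(NA_character_, 13), "ZN", "ZN", "ZN"),
    stringsAsFactors = FALSE)
  df
}

.partner_label <- function(pairs) {
  ifelse(!is.na(pairs$metal), paste0(pairs$metal, "2+"),
         paste0(pairs$partner_res_name, pairs$partner_res_seq, " ",
                pairs$partner_name))
}

#' Ligand-to-subsite distance table for one complex
#'
#' @param structure a `tsa_structure` containing a ligand het group and the
#'   catalytic zinc.
#' @param pairs data.frame as from [default_subsite_pairs()] (the default).
#' @param ligand_res_name optional het code naming the ligand group.
#' @return data.frame of class `tsa_distance_table` with columns ligand_atom,
#'   partner, distance (Angstrom, full precision).
#' @export
distance_table <- function(structure, pairs = default_subsite_pairs(),
                           ligand_res_name = NULL) {
  dist <- vapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    la <- tryCatch(resolve_atom(structure, p$ligand_atom, ligand = TRUE,
                                res_name = ligand_res_name),
                   error = function(e)
                     stop("row ", i, " (", p$ligand_atom, "): ",
                          conditionMessage(e)))
    pa <- tryCatch({
      if (!is.na(p$metal)) resolve_atom(structure, NA, metal = p$metal)
      else resolve_atom(structure, p$partner_name, res_seq = p$partner_res_seq,
                        res_name = p$partner_res_name)
    }, error = function(e)
      stop("row ", i, " (", .partner_label(p), "): ", conditionMessage(e)))
    atom_distance(atom_position(la), atom_position(pa))
  }, numeric(1))
  out <- data.frame(ligand_atom = pairs$ligand_atom,
                    partner = .partner_label(pairs),
                    distance = dist, stringsAsFactors = FALSE)
  class(out) <- c("tsa_distance_table", "data.frame")
  out
}
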