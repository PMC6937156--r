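# Seeded simulators: progress curves, initial rates, rigidly transformed
# coordinate pairs, toy active-site complexes, and synthetic stand-in models
# of the two deposited inhibitor complexes (built by constrained
# construction; see synthetic_subsite_models).

# Run expr with a deterministic RNG state, restoring the caller's state.
# Mersenne-Twister + Inversion are pinned so fixtures are stable across
# releases.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Random proper rotation and rigid transform
#'
#' Rotation drawn uniformly (QR of a Gaussian matrix, sign-corrected to
#' det +1); translation components i.i.d. normal.
#'
#' @param seed integer seed.
#' @param translation_sd sd of translation components, Angstrom.
#' @return a `tsa_transform`.
#' @export
random_rigid_transform <- function(seed = 0, translation_sd = 10) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    rigid_transform(Q, stats::rnorm(3, sd = translation_sd))
  })
}

#' Simulate a progress curve under competitive inhibition
#'
#' Substrate depletion follows the integrated Michaelis-Menten law with the
#' apparent KM scaled by (1 + I/K_I); additive Gaussian noise (a
#' spectrophotometric absorbance noise expressed in substrate units) is then
#' applied and clipped to (0, s0].
#'
#' @param params list with Vmax (M/s) and KM (M), e.g. a `tsa_mm_fit`.
#' @param K_I inhibition constant, M (ignored when I = 0).
#' @param I inhibitor concentration, M.
#' @param s0 initial substrate concentration, M.
#' @param times observation times, s.
#' @param noise_sd additive noise sd, M.
#' @param seed integer seed.
#' @return a `tsa_progress_curve`; the generating truth is in `$meta`.
#' @export
simulate_progress_curve <- function(params, K_I = Inf, I = 0, s0, times,
                                    noise_sd = 0, seed = 0) {
  if (I < 0) stop("negative inhibitor concentration")
  if (I > 0 && (!is.finite(K_I) || K_I <= 0))
    stop("finite positive K_I required when I > 0")
  scale <- if (I > 0) 1 + I / K_I else 1
  s <- closed_form_progress(s0, params$Vmax, params$KM, times, KM_scale = scale)
  if (noise_sd > 0) {
    s <- with_seed(seed, s + stats::rnorm(length(s), sd = noise_sd))
    s <- pmin(pmax(s, 1e-9 * s0), s0)
  }
  progress_curve(times, s, s0 = s0, I = I,
                 meta = list(Vmax = params$Vmax, KM = params$KM, K_I = K_I,
                             noise_sd = noise_sd, seed = seed))
}

#' Simulate Michaelis-Menten initial rates
#'
#' v = Vmax s/(KM + s) with multiplicative Gaussian noise.
#'
#' @param params list with Vmax (M/s) and KM (M).
#' @param substrate_concs substrate concentrations, M.
#' @param rel_noise relative (multiplicative) noise sd.
#' @param seed integer seed.
#' @return data.frame with columns substrate_M, rate_M_s.
#' @export
simulate_initial_rates <- function(params, substrate_concs, rel_noise = 0,
                                   seed = 0) {
  s <- as.numeric(substrate_concs)
  if (any(s <= 0)) stop("non-positive substrate concentrations")
  v <- params$Vmax * s / (params$KM + s)
  if (rel_noise > 0)
    v <- with_seed(seed, v * (1 + stats::rnorm(length(s), sd = rel_noise)))
  data.frame(substrate_M = s, rate_M_s = pmax(v, 0))
}

#' Generate a rigidly related structure pair
#'
#' The mobile structure is the template transformed by `transform` with
#' isotropic Gaussian jitter (sd per coordinate) added to every atom —
#' mimicking two independently refined models of the same protein.
#'
#' @param template a `tsa_structure`, or NULL to generate a random Calpha
#'   cloud.
#' @param n_atoms cloud size when template is NULL.
#' @param transform a `tsa_transform` (default identity).
#' @param jitter_sd per-coordinate jitter sd, Angstrom.
#' @param seed integer seed (drives both the cloud and the jitter).
#' @return list(ref, mobile) of `tsa_structure` objects.
#' @export
make_structure_pair <- function(template = NULL, n_atoms = 100,
                                transform = rigid_transform(),
                                jitter_sd = 0, seed = 0) {
  if (is.null(template)) {
    if (n_atoms < 3) stop("need n_atoms >= 3")
    xyz <- with_seed(seed, matrix(stats::rnorm(3 * n_atoms, sd = 10), ncol = 3))
    template <- new_structure(data.frame(
      serial = seq_len(n_atoms), name = "CA", alt_loc = "",
      res_name = "ALA", chain_id = "A", res_seq = seq_len(n_atoms),
      i_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b_factor = 0, element = "C", is_hetero = FALSE,
      stringsAsFactors = FALSE), label = "sim-ref")
  }
  mobile <- apply_transform(template, transform)
  mobile$label <- "sim-mobile"
  if (jitter_sd > 0) {
    n <- nrow(mobile$atoms)
    jit <- with_seed(seed + 1L, matrix(stats::rnorm(3 * n, sd = jitter_sd),
                                       ncol = 3))
    mobile$atoms$x <- mobile$atoms$x + jit[, 1]
    mobile$atoms$y <- mobile$atoms$y + jit[, 2]
    mobile$atoms$z <- mobile$atoms$z + jit[, 3]
  }
  list(ref = template, mobile = mobile)
}

#' Build a minimal toy complex at exact positions
#'
#' @param spec data.frame with columns name, res_name, res_seq, x, y, z,
#'   hetero (logical); optional chain_id (default "A"), element (guessed),
#'   alt_loc, i_code, occupancy.
#' @param label structure label.
#' @return a `tsa_structure`.
#' @export
make_toy_complex <- function(spec, label = "toy") {
  if (is.null(spec$chain_id)) spec$chain_id <- "A"
  if (is.null(spec$alt_loc)) spec$alt_loc <- ""
  if (is.null(spec$i_code)) spec$i_code <- ""
  if (is.null(spec$occupancy)) spec$occupancy <- 1
  if (is.null(spec$element))
    spec$element <- .guess_element(spec$name, spec$res_name)
  addr <- paste(spec$chain_id, spec$res_seq, spec$i_code, spec$name,
                spec$alt_loc)
  if (anyDuplicated(addr))
    stop("duplicate atom address: ", addr[duplicated(addr)][1])
  new_structure(data.frame(
    serial = seq_len(nrow(spec)), name = spec$name, alt_loc = spec$alt_loc,
    res_name = spec$res_name, chain_id = spec$chain_id,
    res_seq = as.integer(spec$res_seq), i_code = spec$i_code,
    x = spec$x, y = spec$y, z = spec$z, occupancy = spec$occupancy,
    b_factor = 0, element = spec$element, is_hetero = spec$hetero,
    stringsAsFactors = FALSE), label = label)
}

# ---- synthetic stand-ins for the deposited complexes ----------------------

# Free atoms of one active-site model, in a fixed order.
.site_atoms <- function() {
  data.frame(
    key = c("S18", "N17", "N19", "O20", "O21", "C13", "C14", "O15", "O16",
            "ARG129.NH1", "ARG129.NH2", "ASN146.ND2", "ARG147.NH1",
            "ARG147.NH2", "THR205.O", "TYR255.OH", "GLU277.CD",
            "GLU277.OE1", "GLU277.OE2"),
    name = c("S18", "N17", "N19", "O20", "O21", "C13", "C14", "O15", "O16",
             "NH1", "NH2", "ND2", "NH1", "NH2", "O", "OH", "CD", "OE1", "OE2"),
    res_name = c(rep(NA, 9), "ARG", "ARG", "ASN", "ARG", "ARG", "THR", "TYR",
                 "GLU", "GLU", "GLU"),
    res_seq = c(rep(NA, 9), 129, 129, 146, 147, 147, 205, 255, 277, 277, 277),
    stringsAsFactors = FALSE)
}

# Rough chemically plausible starting coordinates (Zn at the origin).
.site_template <- function() {
  rbind(
    S18 = c(3.10, 0.60, 0.40),
    N17 = c(2.55, 1.95, -0.30),
    N19 = c(3.60, -0.70, -0.60),
    O20 = c(4.30, 1.20, 1.00),
    O21 = c(2.20, 0.00, 1.50),
    C13 = c(1.70, 2.80, 0.30),
    C14 = c(0.90, 3.40, -0.85),
    O15 = c(1.20, 3.30, -2.05),
    O16 = c(-0.20, 4.00, -0.55),
    ARG129.NH1 = c(1.00, -1.40, 3.30),
    ARG129.NH2 = c(0.00, 1.00, 3.60),
    ASN146.ND2 = c(1.40, 5.30, -3.60),
    ARG147.NH1 = c(0.80, 5.80, -1.80),
    ARG147.NH2 = c(-2.00, 5.50, -2.20),
    THR205.O = c(5.50, -2.90, -1.40),
    TYR255.OH = c(0.60, 1.10, -2.40),
    GLU277.CD = c(4.60, 3.50, -2.40),
    GLU277.OE1 = c(5.30, 2.60, -1.80),
    GLU277.OE2 = c(3.90, 3.30, -3.45))
}

# Intra-ligand / intra-residue bond restraints keeping the models
# chemically sensible (lengths in Angstrom).
.site_bonds <- function() {
  data.frame(
    a = c("S18", "S18", "S18", "S18", "N17", "C13", "C14", "C14",
          "GLU277.CD", "GLU277.CD"),
    b = c("N17", "N19", "O20", "O21", "C13", "C14", "O15", "O16",
          "GLU277.OE1", "GLU277.OE2"),
    target = c(1.63, 1.60, 1.44, 1.44, 1.47, 1.53, 1.25, 1.25, 1.25, 1.25),
    stringsAsFactors = FALSE)
}

# Solve for two active-site coordinate sets satisfying (i) each complex's
# ligand-subsite distance targets, (ii) the cross-complex displacement
# targets, and (iii) soft bond restraints, by L-BFGS-B least squares.
.solve_site_pair <- function(dist_a, dist_b, displacement, seed) {
  atoms <- .site_atoms()
  n <- nrow(atoms)
  idx <- function(key) match(key, atoms$key)
  zn_a <- 2L * n + 1L; zn_b <- 2L * n + 2L
  cons <- list()
  addc <- function(i, j, t, w = 1) cons[[length(cons) + 1L]] <<- c(i, j, t, w)
  dist_key <- function(d) ifelse(!is.na(d$metal), NA,
                                 paste0(d$partner_res, d$partner_seq, ".",
                                        d$partner_atom))
  for (set in list(list(d = dist_a, off = 0L, zn = zn_a),
                   list(d = dist_b, off = n, zn = zn_b))) {
    d <- set$d
    for (k in seq_len(nrow(d))) {
      i <- idx(d$ligand_atom[k]) + set$off
      j <- if (!is.na(d$metal[k])) set$zn
           else idx(paste0(d$partner_res[k], d$partner_seq[k], ".",
                           d$partner_atom[k])) + set$off
      addc(i, j, d$distance[k])
    }
    bonds <- .site_bonds()
    for (k in seq_len(nrow(bonds)))
      addc(idx(bonds$a[k]) + set$off, idx(bonds$b[k]) + set$off,
           bonds$target[k])
  }
  for (k in seq_len(nrow(displacement))) {
    i <- idx(displacement$key[k])
    addc(i, i + n, displacement$displacement[k])
  }
  C <- do.call(rbind, cons)
  ia <- C[, 1]; ib <- C[, 2]; tg <- C[, 3]; w <- C[, 4]
  template <- .site_template()[atoms$key, , drop = FALSE]
  lam <- 1e-6
  objective <- function(p) {
    X <- rbind(matrix(p, ncol = 3), 0, 0)
    dv <- X[ia, , drop = FALSE] - X[ib, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    sum(w * (d - tg)^2) + lam * sum((p - p0)^2)
  }
  gradient <- function(p) {
    X <- rbind(matrix(p, ncol = 3), 0, 0)
    dv <- X[ia, , drop = FALSE] - X[ib, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dv^2)), 1e-12)
    coef <- 2 * w * (d - tg) / d
    G <- matrix(0, 2L * n + 2L, 3)
    for (k in seq_along(d)) {
      g <- coef[k] * dv[k, ]
      G[ia[k], ] <- G[ia[k], ] + g
      G[ib[k], ] <- G[ib[k], ] - g
    }
    as.numeric(G[seq_len(2L * n), ]) + 2 * lam * (p - p0)
  }
  best <- NULL
  for (trial in 0:7) {
    pert <- with_seed(seed + trial, matrix(stats::rnorm(3 * n, sd = 0.25),
                                           ncol = 3))
    start <- rbind(template, template + pert +
                     matrix(0.15, n, 3) * (trial %% 2))
    p0 <- as.numeric(start)
    opt <- stats::optim(p0, objective, gradient, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 10))
    X <- rbind(matrix(opt$par, ncol = 3), 0, 0)
    viol <- max(abs(sqrt(rowSums((X[ia, , drop = FALSE] -
                                    X[ib, , drop = FALSE])^2)) - tg))
    if (is.null(best) || viol < best$viol)
      best <- list(X = X, viol = viol)
    if (best$viol < 1e-5) break
  }
  if (best$viol > 5e-4)
    stop("synthetic site construction failed: max constraint violation ",
         signif(best$viol, 3), " A")
  list(A = best$X[seq_len(n), , drop = FALSE],
       B = best$X[n + seq_len(n), , drop = FALSE],
       atoms = atoms)
}

# Shared Calpha scaffold: a coarse helix plus Calpha for the active-site
# residues (identical in both models, so superposition is exact).
.scaffold_calpha <- function(site_xyz, atoms) {
  i <- 1:90
  helix <- cbind(18 + 10 * cos(i / 1.7), 10 * sin(i / 1.7), 1.5 * i - 60)
  sc <- data.frame(name = "CA", res_name = "ALA", res_seq = i,
                   x = helix[, 1], y = helix[, 2], z = helix[, 3],
                   hetero = FALSE, element = "C", stringsAsFactors = FALSE)
  prot <- atoms[!is.na(atoms$res_seq), ]
  for (rs in unique(prot$res_seq)) {
    rows <- which(prot$res_seq == rs)
    cen <- colMeans(site_xyz[match(prot$key[rows], atoms$key), , drop = FALSE])
    u <- cen / max(sqrt(sum(cen^2)), 1e-6)
    sc <- rbind(sc, data.frame(name = "CA", res_name = prot$res_name[rows[1]],
                               res_seq = rs, x = cen[1] + 5 * u[1],
                               y = cen[2] + 5 * u[2], z = cen[3] + 5 * u[3],
                               hetero = FALSE, element = "C",
                               stringsAsFactors = FALSE))
  }
  sc
}

.assemble_site_model <- function(xyz, atoms, scaffold, ligand_code, label) {
  prot <- atoms[!is.na(atoms$res_seq), ]
  side <- data.frame(name = prot$name, res_name = prot$res_name,
                     res_seq = prot$res_seq,
                     x = xyz[match(prot$key, atoms$key), 1],
                     y = xyz[match(prot$key, atoms$key), 2],
                     z = xyz[match(prot$key, atoms$key), 3],
                     hetero = FALSE,
                     element = substr(prot$name, 1, 1),
                     stringsAsFactors = FALSE)
  lig <- atoms[is.na(atoms$res_seq), ]
  ligd <- data.frame(name = lig$name, res_name = ligand_code, res_seq = 401L,
                     x = xyz[match(lig$key, atoms$key), 1],
                     y = xyz[match(lig$key, atoms$key), 2],
                     z = xyz[match(lig$key, atoms$key), 3],
                     hetero = TRUE, element = substr(lig$name, 1, 1),
                     stringsAsFactors = FALSE)
  extra <- data.frame(
    name = c("ZN", "O", "O", "HA"),
    res_name = c("ZN", "HOH", "HOH", "ALA"),
    res_seq = c(400L, 501L, 502L, 1L),
    x = c(0, 8.5, -7.2, scaffold$x[1] + 0.9),
    y = c(0, -6.0, 9.1, scaffold$y[1] + 0.4),
    z = c(0, 4.4, -3.3, scaffold$z[1] + 0.3),
    hetero = c(TRUE, TRUE, TRUE, FALSE),
    element = c("ZN", "O", "O", "H"), stringsAsFactors = FALSE)
  spec <- rbind(scaffold, side, ligd, extra)
  make_toy_complex(spec, label = label)
}

#' Synthetic stand-ins for the two deposited inhibitor complexes
#'
#' The deposited crystal structures of the CPT+SGlu and CPT+SLeu complexes
#' (PDB 6SN6, 6GO2) cannot be redistributed or fetched offline, so this
#' constructor builds SYNTHETIC stand-in models whose active sites satisfy,
#' by constrained least-squares construction, the published ligand-subsite
#' distance tables of both complexes and the published per-atom displacement
#' column between them. The two models share an identical Calpha scaffold;
#' the second model is returned in a rotated+translated frame (seeded random
#' rigid transform) so that superposition has real work to do. These are
#' stand-ins for testing the measurement pipeline — they are not the
#' deposited coordinates and carry "-synthetic" labels.
#'
#' @param seed integer seed (frame transform and solver starts).
#' @return list with `sglu` and `sleu` (`tsa_structure`, labels
#'   "6SN6-synthetic" / "6GO2-synthetic"), `true_transform` (the transform
#'   applied to the SLeu model's frame), and `targets` (the constraint
#'   tables used).
#' @export
synthetic_subsite_models <- function(seed = 1) {
  ref <- subsite_distance_reference()
  dist_a <- ref[ref$ligand == "SGlu", ]
  dist_b <- ref[ref$ligand == "SLeu", ]
  disp <- superposition_displacement_reference()
  disp <- data.frame(key = .displacement_key(disp$label),
                     displacement = disp$SGlu_SLeu,
                     stringsAsFactors = FALSE)
  sol <- .solve_site_pair(dist_a, dist_b, disp, seed)
  scaffold <- .scaffold_calpha(sol$A, sol$atoms)
  sglu <- .assemble_site_model(sol$A, sol$atoms, scaffold, "SGL",
                               "6SN6-synthetic")
  sleu <- .assemble_site_model(sol$B, sol$atoms, scaffold, "SLE",
                               "6GO2-synthetic")
  tf <- random_rigid_transform(seed + 1000L, translation_sd = 15)
  sleu <- apply_transform(sleu, tf)
  list(sglu = sglu, sleu = sleu, true_transform = tf,
       targets = list(sglu = dist_a, sleu = dist_b, displacement = disp))
}

# Map displacement-table labels to internal atom keys.
.displacement_key <- function(label) {
  ifelse(grepl(" ", label),
         paste0(toupper(sub("([A-Za-z]+)([0-9]+) .*", "\\1", label)),
                sub("[A-Za-z]+([0-9]+) .*", "\\1", label), ".",
                sub(".* ", "", label)),
         label)
}
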