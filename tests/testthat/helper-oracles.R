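# Independent oracles and hand-built fixtures used across the suite.

# Adaptive step-doubling RK4 integration of ds/dt = -Vmax s/(KM' + s),
# independent of the Lambert-W closed form it checks.
ode_progress <- function(s0, Vmax, KM, times, KM_scale = 1, tol = 1e-12) {
  KMp <- KM * KM_scale
  f <- function(s) -Vmax * s / (KMp + s)
  rk4 <- function(s, h) {
    k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- numeric(length(times))
  s <- s0; t <- 0
  for (i in seq_along(times)) {
    target <- times[i]
    h <- max((target - t) / 50, 1e-9)
    while (t < target - 1e-12 * max(target, 1)) {
      h <- min(h, target - t)
      s1 <- rk4(s, h)
      s2 <- rk4(rk4(s, h / 2), h / 2)
      err <- abs(s2 - s1) / max(abs(s2), s0 * 1e-12)
      if (err < tol || h < 1e-10 * max(target, 1)) {
        s <- s2; t <- t + h
        if (err < tol / 16) h <- h * 2
      } else h <- h / 2
    }
    out[i] <- s
  }
  out
}

# Dense grid-search least-squares oracle for the Michaelis-Menten fit;
# three refinement passes around the best grid node.
mm_grid_oracle <- function(s, v, vmax_range, km_range, n = 60) {
  ssr <- function(Vmax, KM) sum((v - Vmax * s / (KM + s))^2)
  lo <- c(vmax_range[1], km_range[1]); hi <- c(vmax_range[2], km_range[2])
  for (pass in 1:4) {
    vg <- seq(lo[1], hi[1], length.out = n)
    kg <- seq(lo[2], hi[2], length.out = n)
    grid <- expand.grid(Vmax = vg, KM = kg)
    ss <- mapply(ssr, grid$Vmax, grid$KM)
    b <- grid[which.min(ss), ]
    dv <- diff(vg)[1]; dk <- diff(kg)[1]
    lo <- c(max(b$Vmax - 2 * dv, 1e-12), max(b$KM - 2 * dk, 1e-12))
    hi <- c(b$Vmax + 2 * dv, b$KM + 2 * dk)
  }
  list(Vmax = b$Vmax, KM = b$KM)
}

# Two-record PDB fixture: one protein CA, one zinc.
tiny_pdb_text <- function() {
  c("ATOM      1  CA  ALA A  10      11.104  13.207   9.456  1.00 12.30           C",
    "HETATM    2 ZN    ZN A 400       0.000   1.250  -3.800  1.00  9.10          ZN",
    "END")
}

# Fixture with A/B altloc copies, a hydrogen, a water and a 4-atom ligand.
altloc_pdb_text <- function() {
  c("ATOM      1  N   TYR A 255       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  TYR A 255       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  OH ATYR A 255       4.100   2.000   1.000  0.60 10.00           O",
    "ATOM      4  OH BTYR A 255       4.300   2.100   0.900  0.40 10.00           O",
    "ATOM      5  HA  TYR A 255       1.800   0.900   0.500  1.00 10.00           H",
    "ATOM      6  CA  GLY A 256       4.800   1.200   3.300  1.00 10.00           C",
    "ATOM      7  CA  ALA A 257       7.900  -1.000   4.100  1.00 10.00           C",
    "HETATM    8  S18 SLE A 401       3.000   0.000   0.000  1.00 10.00           S",
    "HETATM    9  N17 SLE A 401       3.500   1.500   0.200  1.00 10.00           N",
    "HETATM   10  O20 SLE A 401       2.600  -0.900   1.100  1.00 10.00           O",
    "HETATM   11  O21 SLE A 401       2.200  -0.500  -1.200  1.00 10.00           O",
    "HETATM   12 ZN    ZN A 400       0.000   0.000   2.100  1.00 10.00          ZN",
    "HETATM   13  O   HOH A 501       8.000   8.000   8.000  1.00 20.00           O",
    "END")
}

# Minimal mmCIF carrying the same content as tiny_pdb_text().
tiny_mmcif_text <- function() {
  c("data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA . ALA A 10 ? 11.104 13.207 9.456 1.00 12.30",
    "HETATM 2 ZN ZN . ZN A 400 ? 0.000 1.250 -3.800 1.00 9.10",
    "#")
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Default kinetic "stated world" shared by kinetics tests: s0 = KM, four
# inhibitor levels at {0, 0.3, 1, 3} x K_I (the canonical K_I-determination
# ratios), 40 time points spanning the retained conversion window.
kin_world <- function() {
  list(params = list(Vmax = 1e-6, KM = 1e-4), s0 = 1e-4,
       K_I = 8.94e-6, levels = c(0, 0.3, 1, 3) * 8.94e-6, n_t = 40)
}

# Simulate the default 4-level design and fit K_I once. Each curve is
# sampled uniformly in time between 5% and 95% conversion — exactly the
# window the linearization filter retains.
run_ki_pipeline <- function(noise_sd, seed, world = kin_world()) {
  lins <- lapply(seq_along(world$levels), function(j) {
    I <- world$levels[j]
    scale <- 1 + I / world$K_I
    tspan <- vapply(c(0.05, 0.95), function(cv)
      time_to_conversion(world$s0, world$params$Vmax, world$params$KM, cv,
                         KM_scale = scale), numeric(1))
    times <- seq(tspan[1], tspan[2], length.out = world$n_t)
    cv <- simulate_progress_curve(world$params, world$K_I, I, world$s0,
                                  times, noise_sd = noise_sd,
                                  seed = seed * 101L + j)
    linearize_and_fit(cv)
  })
  fit_inhibition(lins)
}
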