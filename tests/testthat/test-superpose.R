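test_that("atom_distance agrees with brute-force sum of squares", {
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(42)
  for (i in 1:1000) {
    a <- rnorm(3, sd = 20); b <- rnorm(3, sd = 20)
    bf <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
    expect_equal(atom_distance(a, b), bf, tolerance = 1e-12)
  }
  expect_error(atom_distance(c(NA, 0, 0), c(0, 0, 0)), "non-finite")
})

test_that("rigid transforms compose, invert and reject reflections", {
  tf <- random_rigid_transform(7)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  id <- compose_transforms(invert_transform(tf), tf)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("kabsch recovers identity and known transforms", {
  set.seed(1)
  xyz <- matrix(rnorm(150, sd = 8), ncol = 3)
  sup <- kabsch_superpose(xyz, xyz)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sup$n_pairs, 50)
  for (seed in 1:5) {
    tf <- random_rigid_transform(seed)
    moved <- apply_transform(xyz, tf)
    sup <- kabsch_superpose(xyz, moved)
    # recovered transform composed with the applied one is the identity
    comp <- compose_transforms(sup$transform, tf)
    expect_equal(comp$rotation, diag(3), tolerance = 1e-8)
    expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-8)
    expect_lt(sup$rmsd, 1e-8)
  }
})

test_that("mirrored clouds still give a proper rotation (det +1)", {
  set.seed(2)
  xyz <- matrix(rnorm(120, sd = 5), ncol = 3)
  mirrored <- xyz %*% diag(c(-1, 1, 1))
  sup <- kabsch_superpose(xyz, mirrored)
  expect_equal(det(sup$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0) # a reflection cannot be absorbed
})

test_that("kabsch rejects degenerate and mismatched input", {
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(kabsch_superpose(diag(3), diag(3)[1:2, ]), "differ in size")
  expect_error(kabsch_superpose(diag(3)[1:2, ], diag(3)[1:2, ]),
               "insufficient pairs")
})

test_that("returned rotation is a local RMSD minimum", {
  set.seed(3)
  xyz <- matrix(rnorm(90, sd = 6), ncol = 3)
  pair <- make_structure_pair(n_atoms = 30, transform = random_rigid_transform(3),
                              jitter_sd = 0.3, seed = 3)
  p <- pair_calpha(pair$ref, pair$mobile)
  sup <- kabsch_superpose(p$ref_xyz, p$mobile_xyz)
  rmsd_under <- function(R) {
    P <- sweep(p$mobile_xyz, 2, colMeans(p$mobile_xyz))
    Q <- sweep(p$ref_xyz, 2, colMeans(p$ref_xyz))
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  axis_rot <- function(u, ang) {
    u <- u / sqrt(sum(u^2))
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  }
  set.seed(99)
  for (i in 1:100) {
    Rp <- axis_rot(rnorm(3), 1e-3) %*% sup$transform$rotation
    expect_gte(rmsd_under(Rp), sup$rmsd - 1e-12)
  }
})

test_that("pair_calpha uses residue-number intersection", {
  pair <- make_structure_pair(n_atoms = 40, seed = 5)
  p <- pair_calpha(pair$ref, pair$mobile)
  expect_equal(nrow(p$residues), 40)
  # drop residues 1-5 from the mobile: they vanish from the pairing
  mob <- pair$mobile
  mob$atoms <- mob$atoms[!(mob$atoms$res_seq %in% 1:5), ]
  p2 <- pair_calpha(pair$ref, mob)
  expect_equal(nrow(p2$residues), 35)
  expect_false(any(p2$residues$res_seq %in% 1:5))
  mob$atoms <- mob$atoms[mob$atoms$res_seq %in% 6:7, ]
  expect_error(pair_calpha(pair$ref, mob), "insufficient pairs")
})

test_that("displacement_table: self-comparison is zero, single moved atom shows", {
  m <- synthetic_subsite_models(seed = 2)
  st <- m$sglu
  disp <- displacement_table(st, st)
  expect_true(all(abs(disp$displacement) < 1e-10))
  # move exactly one side-chain atom by (0.3, 0.4, 0): that row 0.50
  st2 <- st
  i <- which(st2$atoms$name == "OH" & st2$atoms$res_seq == 255)
  st2$atoms$x[i] <- st2$atoms$x[i] + 0.3
  st2$atoms$y[i] <- st2$atoms$y[i] + 0.4
  disp2 <- displacement_table(st, st2)
  expect_equal(disp2$displacement[disp2$label == "Tyr255 OH"], 0.5,
               tolerance = 1e-9)
  expect_true(all(abs(disp2$displacement[disp2$label != "Tyr255 OH"]) < 1e-10))
  # unresolvable label names the structure
  st3 <- st
  st3$atoms <- st3$atoms[st3$atoms$name != "OH", ]
  expect_error(displacement_table(st, st3), "missing atom.*mobile")
})

test_that("distance_table measures constructed geometry exactly", {
  spec <- data.frame(
    name = c("ZN", "S18", "N17", "O20", "OH", "CA", "CA", "CA"),
    res_name = c("ZN", "SLE", "SLE", "SLE", "TYR", "TYR", "GLY", "ALA"),
    res_seq = c(400, 401, 401, 401, 255, 255, 256, 257),
    x = c(0, 3.08, 3.5, 2.2, 5.0, 6, 9, 12),
    y = c(0, 0, 1.2, -1.0, 2.0, 3, 1, -2),
    z = c(0, 0, 0.4, 0.8, 1.0, 2, 4, 0),
    hetero = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  st <- make_toy_complex(spec)
  pairs <- data.frame(ligand_atom = "S18", partner_res_name = NA,
                      partner_res_seq = NA, partner_name = NA, metal = "ZN")
  tab <- distance_table(st, pairs)
  expect_equal(tab$distance, 3.08)
  expect_equal(tab$partner, "ZN2+")
  # symmetry: measuring the partner against the ligand gives the same value
  d_ba <- atom_distance(atom_position(resolve_atom(st, NA, metal = "ZN")),
                        atom_position(resolve_atom(st, "S18", ligand = TRUE)))
  expect_equal(d_ba, tab$distance)
  bad <- data.frame(ligand_atom = "S99", partner_res_name = NA,
                    partner_res_seq = NA, partner_name = NA, metal = "ZN")
  expect_error(distance_table(st, bad), "row 1.*S99")
})

test_that("frame invariance: rigidly moving both structures changes nothing", {
  m <- synthetic_subsite_models(seed = 3)
  tf <- random_rigid_transform(11)
  a2 <- apply_transform(m$sglu, tf)
  b2 <- apply_transform(m$sleu, tf)
  d1 <- distance_table(m$sglu, default_subsite_pairs("O16"))
  d2 <- distance_table(a2, default_subsite_pairs("O16"))
  expect_equal(d2$distance, d1$distance, tolerance = 1e-9)
  disp1 <- displacement_table(m$sglu, m$sleu)
  disp2 <- displacement_table(a2, b2)
  expect_equal(disp2$displacement, disp1$displacement, tolerance = 1e-9)
})

test_that("mean squared Calpha displacement equals rmsd^2", {
  pair <- make_structure_pair(n_atoms = 60, transform = random_rigid_transform(8),
                              jitter_sd = 0.4, seed = 8)
  p <- pair_calpha(pair$ref, pair$mobile)
  sup <- kabsch_superpose(p$ref_xyz, p$mobile_xyz)
  moved <- apply_transform(p$mobile_xyz, sup$transform)
  msd <- mean(rowSums((moved - p$ref_xyz)^2))
  expect_equal(msd, sup$rmsd^2, tolerance = 1e-12)
})
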