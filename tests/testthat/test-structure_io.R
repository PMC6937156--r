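test_that("PDB parsing captures all fields and round-trips exactly", {
  f <- write_lines_tmp(tiny_pdb_text())
  st <- read_structure(f, dialect = "pdb")
  expect_s3_class(st, "tsa_structure")
  expect_equal(n_atoms(st), 2)
  a <- st$atoms
  expect_equal(a$name, c("CA", "ZN"))
  expect_equal(a$element, c("C", "ZN"))
  expect_equal(a$is_hetero, c(FALSE, TRUE))
  expect_equal(a$res_seq, c(10L, 400L))
  expect_equal(a$x, c(11.104, 0))
  expect_equal(a$b_factor, c(12.30, 9.10))

  # write -> re-read: identical atom fields
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(st, f2)
  st2 <- read_structure(f2)
  expect_equal(st2$atoms, st$atoms)
})

test_that("mmCIF dialect maps the same fields as PDB", {
  fp <- write_lines_tmp(tiny_pdb_text())
  fc <- write_lines_tmp(tiny_mmcif_text(), ext = ".cif")
  sp <- read_structure(fp)
  sc <- read_structure(fc) # dialect guessed from extension
  expect_equal(sc$atoms, sp$atoms)
})

test_that("parse errors and empty structures are reported by name", {
  f <- write_lines_tmp(c("REMARK nothing here", "END"))
  expect_error(read_structure(f), "empty structure")
  bad <- tiny_pdb_text()
  substr(bad[1], 31, 38) <- "  xx.xxx"
  fb <- write_lines_tmp(bad)
  expect_error(read_structure(fb), "parse error.*line 1")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("altloc copies are retained and resolved per policy", {
  st <- read_structure(write_lines_tmp(altloc_pdb_text()))
  expect_equal(sum(st$atoms$name == "OH"), 2) # both records retained
  # highest occupancy wins (A: 0.60 vs B: 0.40)
  oh <- resolve_atom(st, "OH", res_seq = 255)
  expect_equal(oh$alt_loc, "A")
  expect_equal(resolve_atom(st, "OH", res_seq = 255, altloc = "first")$alt_loc, "A")
  expect_equal(resolve_atom(st, "OH", res_seq = 255, altloc = "explicit",
                            altloc_char = "B")$alt_loc, "B")
  # determinism across repeated resolution
  expect_identical(resolve_atom(st, "OH", res_seq = 255),
                   resolve_atom(st, "OH", res_seq = 255))
  # occupancy tie broken by smallest altloc character
  st2 <- st
  st2$atoms$occupancy[st2$atoms$name == "OH"] <- 0.5
  expect_equal(resolve_atom(st2, "OH", res_seq = 255)$alt_loc, "A")
})

test_that("atom queries resolve uniquely or fail with a named error", {
  st <- read_structure(write_lines_tmp(altloc_pdb_text()))
  expect_equal(resolve_atom(st, "CA", res_seq = 255, chain = "A")$res_name, "TYR")
  expect_error(resolve_atom(st, "XX9"), "missing atom.*XX9")
  expect_error(resolve_atom(st, "CA", res_seq = 999), "missing atom")
  # ligand flag resolves within the >= 3-atom non-water het group
  expect_equal(resolve_atom(st, "S18", ligand = TRUE)$res_name, "SLE")
  # metal by element; water and zinc are not ligand candidates
  expect_equal(resolve_atom(st, NA, metal = "ZN")$res_seq, 400L)
  expect_equal(ligand_group(st)$res_name, "SLE")
})

test_that("hydrogens and hetero CA never enter Calpha selections", {
  st <- read_structure(write_lines_tmp(altloc_pdb_text()))
  ca <- calpha_coords(st)
  expect_equal(nrow(ca), 3) # Tyr255, Gly256, Ala257 (HA hydrogen excluded)
  # a hetero calcium ion named CA must not appear
  ion <- st$atoms[1, ]
  ion$name <- "CA"; ion$res_name <- "CA"; ion$element <- "CA"
  ion$is_hetero <- TRUE; ion$res_seq <- 999L; ion$serial <- 99L
  st$atoms <- rbind(st$atoms, ion)
  expect_equal(nrow(calpha_coords(st)), 3)
})

test_that("write_table renders distances to 2 decimals, kinetics to 3 sig figs", {
  f <- tempfile(fileext = ".tsv")
  rows <- data.frame(ligand_atom = "S18", partner = "Zn", distance = 3.08)
  write_table(rows, f)
  expect_equal(readLines(f)[2], "S18\tZn\t3.08")
  # 2-decimal rounding is half-up, not half-even
  write_table(data.frame(distance = c(0.125, 2.675)), f)
  expect_equal(readLines(f)[2:3], c("0.13", "2.68"))
  write_table(data.frame(K_I = 8.94e-6), f)
  expect_equal(readLines(f)[2], "8.94e-06")
  # empty row list -> header-only file
  write_table(rows[0, ], f)
  expect_equal(readLines(f), "ligand_atom\tpartner\tdistance")
  # round trip preserves printed precision
  write_table(data.frame(label = "a", distance = 3.0849), f)
  expect_equal(read_table(f)$distance, 3.08)
})

test_that("structure invariants hold: finite coords, occupancy range", {
  at <- read_structure(write_lines_tmp(tiny_pdb_text()))$atoms
  at$x[1] <- NA
  expect_error(new_structure(at), "non-finite")
  at2 <- read_structure(write_lines_tmp(tiny_pdb_text()))$atoms
  at2$occupancy[1] <- 1.2
  expect_error(new_structure(at2), "occupancy")
})
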