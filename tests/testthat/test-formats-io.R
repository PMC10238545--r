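# Structure and tabular readers/writers.

test_that("PDB write/read round-trips atoms, numbering and coordinates", {
  st <- fix_truth60()$ground
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, f)
  st2 <- read_structure(f, chain = "A")
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(st2$atoms$atom, st$atoms$atom)
  expect_equal(st2$atoms$resno, st$atoms$resno)
  expect_equal(as.matrix(st2$atoms[c("x", "y", "z")]),
               as.matrix(st$atoms[c("x", "y", "z")]),
               tolerance = 1.5e-3, ignore_attr = TRUE)
})

test_that("alternate locations resolve to the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_altloc_pdb(f)
  st <- read_structure(f, chain = "A")
  expect_equal(length(unique(st$atoms$resno)), 3L)
  # one CA per residue; residue 2 keeps the 0.70-occupancy B location
  ca2 <- st$atoms[st$atoms$resno == 2 & st$atoms$atom == "CA", ]
  expect_equal(nrow(ca2), 1L)
  expect_equal(ca2$x, 4.020)
  # HETATM kept separately, never in the atom table
  expect_equal(nrow(st$het), 1L)
  expect_false(any(st$atoms$resname == "HOH"))
})

test_that("mmCIF files are read through the same interface", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_MINI", "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 10.00 ? 1 ALA A C 1"),
    f)
  st <- read_structure(f, chain = "A")
  expect_equal(st$atoms$atom, c("N", "CA", "C"))
  expect_equal(st$atoms$x[2], 1.458)
})

test_that("structure reader rejects missing files and empty chains", {
  expect_error(read_structure("no/such/file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "empty chain|no ATOM")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_altloc_pdb(f2)
  expect_error(read_structure(f2, chain = "Z"), "empty chain")
})

test_that("structure model validates invariants", {
  a <- data.frame(chain = "A", resno = c(1, 1), resname = "ALA",
                  atom = c("N", "N"), element = "N", x = 0, y = 0, z = 0)
  expect_error(structure_model(a), "duplicate")
  a2 <- data.frame(chain = "A", resno = 1, resname = "ALA",
                   atom = "N", element = "N", x = Inf, y = 0, z = 0)
  expect_error(structure_model(a2), "finite")
})

test_that("RDC tables parse, validate and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_fixture(f)
  tab <- read_rdc_table(f)
  expect_s3_class(tab, "rdc_table")
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$type, c("NH", "NH", "CAHA", "HNC"))
  expect_equal(tab$value[1], 5.2)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_fixture(f2, duplicate = TRUE)
  expect_error(read_rdc_table(f2), "duplicate.*5 NH pf1")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_rdc_fixture(f3, bad_error_row = TRUE)
  w <- capture_warnings(tab3 <- read_rdc_table(f3))
  expect_length(w, 1L)
  expect_equal(nrow(tab3), 3L)
})

test_that("RDC reader demands required columns but accepts a mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(resid = 5, type = "NH", medium = "pf1",
                   value = 3, error = 0.5)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rdc_table(f), "missing required column")
  tab <- read_rdc_table(f, col_map = c(residue = "resid"))
  expect_equal(tab$residue, 5L)
  expect_error(read_rdc_table(f, col_map = c(residue = "nope")),
               "not in file")
})

test_that("unknown coupling types are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(residue = 5, type = "CACB", medium = "pf1",
                   value = 3, error = 0.5)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rdc_table(f), "unknown RDC coupling type")
})

test_that("dispersion tables keep replicates and convert intensities", {
  f <- withr::local_tempfile(fileext = ".tsv")
  grid <- expand.grid(residue = 7, temperature = c(293.15, 298.15, 303.15),
                      nu_cpmg = c(100, 200, 400, 500, 800, 1000))
  grid$r2eff <- 12; grid$sigma <- 0.3
  utils::write.table(grid, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_dispersion_table(f)
  expect_equal(nrow(tab), 18L)
  expect_true(all(tab$rep == 1))

  # repeated points stay individual records
  grid2 <- rbind(grid, grid[grid$nu_cpmg %in% c(100, 400, 1000), ])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(grid2, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab2 <- read_dispersion_table(f2)
  expect_equal(nrow(tab2), 27L)
  expect_equal(sum(tab2$rep == 2), 9L)

  # intensity input converts through the constant-time relation
  f3 <- withr::local_tempfile(fileext = ".tsv")
  df3 <- data.frame(residue = 7, temperature = 298.15, nu_cpmg = 100,
                    intensity = exp(-0.24) * 50, ref_intensity = 50)
  utils::write.table(df3, f3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab3 <- read_dispersion_table(f3)
  expect_equal(tab3$r2eff, 12, tolerance = 1e-9)

  df3$intensity <- -1
  utils::write.table(df3, f3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_dispersion_table(f3), "positive")
})

test_that("replicate spread yields the pooled per-point sigma", {
  d <- data.frame(residue = 7, temperature = 298.15,
                  nu_cpmg = c(100, 100, 100, 200, 400),
                  r2eff = c(10.0, 10.6, 10.3, 9.0, 8.0),
                  sigma = NA_real_)
  class(d) <- c("dispersion_table", "data.frame")
  out <- sigma_from_replicates(d)
  m <- mean(c(10.0, 10.6, 10.3))
  expect_equal(out$sigma,
               rep(sqrt(sum((c(10.0, 10.6, 10.3) - m)^2) / 2), 5))
})

test_that("region selections expand to inclusive residue sets", {
  rs <- region_selection()
  expect_equal(region_residues(rs), c(30:38, 59:76))
  expect_error(region_selection(a = c(5, 3)), "last >= first")
  expect_equal(region_residues(NULL), integer(0))
  expect_true(all(c(7, 13, 150) %in% reporting_residues()))
  expect_false(30 %in% reporting_residues())
})
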