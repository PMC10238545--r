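# Shared fixtures, built lazily once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# mid-sized two-state truth for refinement tests
fix_truth60 <- function() memo("tr60", synthetic_truth(n_residues = 60,
                                                       seed = 4))

# full-sized study-condition truth for acceptance
fix_truth166 <- function() memo("tr166", synthetic_truth(seed = 1))

fix_rdc60 <- function() memo("rdc60",
  simulate_rdc_sets(fix_truth60(), completeness = 1))

fix_dih60 <- function() memo("dih60",
  dihedral_restraints_from(fix_truth60()$minor))

# small default two-site parameter set
fix_params <- function(...) {
  args <- utils::modifyList(list(pb = 0.15, kex = 1000, dw_ppm = 2,
                                 r2a = 10), list(...))
  do.call(two_site_params, args)
}

# hand-written 3-residue PDB with an altloc pair on residue 2 CA
write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      6  CA AALA A   2       4.011   2.801   0.100  0.30 10.00           C",
    "ATOM      7  CA BALA A   2       4.020   2.810   0.200  0.70 10.00           C",
    "ATOM      8  C   ALA A   2       5.480   2.600   0.000  1.00 10.00           C",
    "ATOM      9  O   ALA A   2       6.020   1.500   0.000  1.00 10.00           O",
    "ATOM     10  N   ALA A   3       6.100   3.760   0.000  1.00 10.00           N",
    "ATOM     11  CA  ALA A   3       7.540   3.850   0.000  1.00 10.00           C",
    "ATOM     12  C   ALA A   3       8.100   5.260   0.000  1.00 10.00           C",
    "HETATM   13  O   HOH A 201       9.000   9.000   9.000  1.00 20.00           O",
    "END")
  writeLines(lines, path)
  path
}

write_rdc_fixture <- function(path, bad_error_row = FALSE,
                              duplicate = FALSE) {
  df <- data.frame(residue = c(5, 6, 7, 8),
                   type = c("NH", "NH", "CAHA", "HNC"),
                   medium = "pf1",
                   value = c(5.2, -3.1, 10.4, 1.2),
                   error = c(0.5, 0.5, 1.0, 0.2))
  if (bad_error_row) df$error[2] <- 0
  if (duplicate) df$residue[2] <- 5
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
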