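# Two-state ensemble refinement: contracts, null control, recovery,
# cross-validation isolation, reporting.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_runs = 3, n_keep = 2, seed = 7,
                                 dihedral_restraints = fix_dih60()),
                            list(...))
  do.call(refinement_config, args)
}

fix_refit <- function() memo("refit60", {
  refine_two_state(fix_truth60()$ground, fix_rdc60(),
                   fix_truth60()$tensors, small_cfg(), w = 0.3)
})

test_that("configuration validates its invariants", {
  expect_error(refinement_config(max_displacement = 0), "> 0")
  expect_error(refinement_config(n_runs = 5, n_keep = 10), "exceed")
  expect_error(refine_two_state(fix_truth60()$ground, fix_rdc60(),
                                fix_truth60()$tensors, small_cfg(),
                                w = 0), "in \\(0, 1\\)")
})

test_that("the ground conformer is never touched and runs sort by energy", {
  tr <- fix_truth60()
  before <- tr$ground$atoms
  rf <- fix_refit()
  expect_identical(tr$ground$atoms, before)
  expect_identical(rf$ensemble$conformers[[1]]$atoms, before)
  expect_false(is.unsorted(rf$energies))
  expect_equal(length(rf$kept), 2L)
})

test_that("minimization is monotone and honors the displacement cap", {
  tr <- fix_truth60()
  rf <- fix_refit()
  expect_true(all(rf$energies <= rf$energy0))
  X0 <- as.matrix(tr$ground$atoms[c("x", "y", "z")])
  for (cf in rf$conformers) {
    X <- as.matrix(cf$atoms[c("x", "y", "z")])
    expect_lt(max(sqrt(rowSums((X - X0)^2))), 3.0 + 0.2)
  }
})

test_that("the N = 2 objective reduces to N = 1 as w approaches zero", {
  tr <- fix_truth60()
  cfg <- small_cfg()
  sys <- exstate:::.make_refine_system(tr$ground, fix_rdc60(),
                                       tr$tensors, cfg)
  set.seed(2)
  x1 <- as.numeric(sys$X0 + rnorm(length(sys$X0), 0, 0.3))
  x2 <- as.numeric(sys$X0 + rnorm(length(sys$X0), 0, 0.3))
  e1 <- exstate:::.refine_energy(x1, sys, 1e-6, cfg)
  e2 <- exstate:::.refine_energy(x2, sys, 1e-6, cfg)
  # at w -> 0 the RDC term depends on the minor coordinates only to
  # first order in w
  expect_equal(e1$rdc, e2$rdc, tolerance = 1e-5)
})

test_that("two-state truth is recovered as a correlated displacement pattern", {
  tr <- fix_truth60()
  rf <- memo("refit60_rec", {
    refine_two_state(tr$ground, fix_rdc60(), tr$tensors,
                     small_cfg(n_runs = 4, n_keep = 2), w = 0.3)
  })
  profs <- vapply(rf$conformers, function(cf)
    per_residue_displacement(cf, tr$ground), numeric(60))
  prof <- rowMeans(profs)
  expect_gt(cor(prof, tr$displacement[rownames(profs)]), 0.6)
})

test_that("one-state data leaves the refined minor at the ground state", {
  tr <- fix_truth60()
  rdc0 <- simulate_rdc_sets(tr, weights = c(1, 0), completeness = 1)
  rf <- refine_two_state(tr$ground, rdc0, tr$tensors,
                         refinement_config(n_runs = 2, n_keep = 1,
                                           seed = 3,
                                           dihedral_restraints =
                                             dihedral_restraints_from(
                                               tr$ground)),
                         w = 0.3)
  prof <- per_residue_displacement(rf$conformers[[1]], tr$ground)
  expect_lt(median(prof), 0.4)
})

test_that("held-out sets are fully isolated from the refinement", {
  tr <- fix_truth60()
  rdc <- fix_rdc60()
  hold <- rdc$medium == "pf1" & rdc$type == "NH"
  rf1 <- refine_two_state(tr$ground, rdc[!hold, ], tr$tensors,
                          small_cfg(), w = 0.3)
  rdcP <- rdc
  set.seed(99)
  rdcP$value[hold] <- sample(rdcP$value[hold])
  rf2 <- refine_two_state(tr$ground, rdcP[!hold, ], tr$tensors,
                          small_cfg(), w = 0.3)
  expect_identical(rf1$energies, rf2$energies)
  expect_identical(rf1$conformers[[1]]$atoms, rf2$conformers[[1]]$atoms)
})

test_that("cross-validation reports R-free and the N = 1 reference", {
  tr <- fix_truth60()
  sets <- data.frame(medium = "pf1", type = c("NH", "CAHA"))
  cv <- crossval_rfree(tr$ground, fix_rdc60(), tr$tensors,
                       small_cfg(), 0.3, sets = sets)
  expect_equal(nrow(cv), 2L)
  expect_true(all(cv$r_free >= 0 & cv$r_n1 >= 0))
  one_set <- fix_rdc60()
  one_set <- one_set[one_set$medium == "pf1" & one_set$type == "NH", ]
  expect_error(crossval_rfree(tr$ground, one_set, tr$tensors,
                              small_cfg(), 0.3), "at least two")
})

test_that("population grid validates input and flags flat diagnostics", {
  tr <- fix_truth60()
  expect_error(population_grid_search(tr$ground, fix_rdc60(),
                                      tr$tensors, small_cfg(),
                                      grid = numeric(0)), "empty")
  expect_error(population_grid_search(tr$ground, fix_rdc60(),
                                      tr$tensors, small_cfg(),
                                      grid = c(0.3, 0.7)),
               "\\(0, 0.5\\]")
})

test_that("the reporting ensemble summarizes the kept runs", {
  rf <- fix_refit()
  rep <- select_reporting_ensemble(rf)
  expect_equal(length(rep$conformers), 2L)
  expect_false(is.unsorted(rep$energies))
  st <- ensemble_rmsd_stats(rep$conformers, fix_truth60()$ground)
  expect_equal(rep$mean_rmsd, st$mean_rmsd, tolerance = 1e-9)
  expect_equal(rep$rmsd_to_ground, st$range, tolerance = 1e-9)
  expect_error(select_reporting_ensemble(rf, n_keep = 50), "fewer")
})

test_that("the RDC weight calibrator lands inside the no-overfit band", {
  tr <- fix_truth60()
  cfg <- calibrate_rdc_weight(tr$ground, fix_rdc60(), tr$tensors,
                              small_cfg(k_rdc = 8), 0.3)
  sig_nh <- median(fix_rdc60()$error[fix_rdc60()$type == "NH"])
  nh <- attr(cfg, "nh_rmsd")
  expect_gte(nh, 0.9 * sig_nh)
  expect_lte(nh, 2.2 * sig_nh)
})
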