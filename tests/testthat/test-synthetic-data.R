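# The synthetic-trajectory generator: ground truth, determinism, topology.

test_that("specification validation rejects infeasible inputs", {
  s20 <- strrep("A", 20)
  expect_error(synthetic_spec(s20, data.frame(start = 5, end = 25,
                                              occupancy = 1)), "within")
  expect_error(synthetic_spec(s20, data.frame(start = c(2, 8),
                                              end = c(10, 15),
                                              occupancy = 1)), "overlap")
  expect_error(synthetic_spec(s20, data.frame(start = 2, end = 10,
                                              occupancy = 1.4)), "\\[0, 1\\]")
  expect_error(synthetic_spec(s20, data.frame(start = 2, end = 10,
                                              occupancy = 0.5),
                              n_frames = 0), "n_frames")
})

test_that("full occupancy without noise is assigned helical every frame", {
  spec <- synthetic_spec(strrep("A", 20),
                         data.frame(start = 5, end = 15, occupancy = 1),
                         noise_sigma = 0, n_frames = 4, seed = 2)
  syn <- synthesize_trajectory(spec)
  rec <- assign_trajectory(syn$trajectory)
  interior <- syn$truth$residue[syn$truth$role == "interior"]
  expect_true(all(rec$helix_mask[, interior]))
  # zero occupancy: never helical anywhere in the segment
  spec0 <- synthetic_spec(strrep("A", 20),
                          data.frame(start = 5, end = 15, occupancy = 0),
                          n_frames = 50, seed = 3)
  syn0 <- synthesize_trajectory(spec0)
  rec0 <- assign_trajectory(syn0$trajectory)
  expect_false(any(rec0$helix_mask[, 5:15]))
})

test_that("uncorrelated frames recover occupancy at binomial accuracy", {
  spec <- synthetic_spec(strrep("A", 20),
                         data.frame(start = 2, end = 19, occupancy = 0.8,
                                    persistence = 0),
                         n_frames = 2000, seed = 5)
  syn <- synthesize_trajectory(spec)
  occ <- helix_occupancy(assign_trajectory(syn$trajectory))
  tol <- 3 * sqrt(0.8 * 0.2 / 2000)
  interior <- syn$truth$role == "interior"
  # deep interior residues track the segment state within binomial error
  deep <- which(interior)[5:12]
  expect_true(all(abs(occ[deep] - 0.8) <= tol + 0.02))
})

test_that("identical seeds reproduce byte-identical trajectories", {
  spec <- synthetic_spec("GADVEGADVE",
                         data.frame(start = 3, end = 8, occupancy = 0.6),
                         n_frames = 30, seed = 9)
  a <- synthesize_trajectory(spec)
  b <- synthesize_trajectory(spec)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$states, b$states)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_trajectory(a$trajectory, f1); write_trajectory(b$trajectory, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every frame shares one topology and obeys builder invariants", {
  spec <- synthetic_spec("GADVEL",
                         data.frame(start = 2, end = 5, occupancy = 0.5),
                         n_frames = 20, seed = 7)
  traj <- synthesize_trajectory(spec)$trajectory
  expect_equal(dim(traj$coords)[1], nrow(traj$atoms))
  # bonded N-CA distance is the template value in every frame
  iN <- which(traj$atoms$elety == "N" & traj$atoms$resid == 3)
  iCA <- which(traj$atoms$elety == "CA" & traj$atoms$resid == 3)
  d <- sqrt(colSums((traj$coords[iN, , ] - traj$coords[iCA, , ])^2))
  expect_true(all(abs(d - 1.458) < 1e-9))
})

test_that("pure coil sampling is essentially never called helical", {
  spec <- synthetic_spec(strrep("A", 20),
                         data.frame(start = integer(0), end = integer(0),
                                    occupancy = numeric(0)),
                         n_frames = 500, seed = 11)
  rec <- assign_trajectory(synthesize_trajectory(spec)$trajectory)
  expect_lt(mean(rec$helix_mask), 0.01)
})

test_that("the set experiment writes a reproducible manifest", {
  dir1 <- tempfile(); dir2 <- tempfile()
  r1 <- synthetic_set_experiment(c("GADV", "GADVE"), n_peptides = 2,
                               n_frames = 10, seed = 3, out_dir = dir1)
  r2 <- synthetic_set_experiment(c("GADV", "GADVE"), n_peptides = 2,
                               n_frames = 10, seed = 3, out_dir = dir2)
  expect_equal(nrow(r1$manifest), 4)
  expect_equal(table(r1$manifest$set),
               table(c("GADV", "GADV", "GADVE", "GADVE")), ignore_attr = TRUE)
  expect_true(all(file.exists(file.path(dir1,
                                        paste0(r1$manifest$id, ".pdb")))))
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_identical(readLines(file.path(dir1, paste0(r1$manifest$id[1], ".pdb"))),
                   readLines(file.path(dir2, paste0(r2$manifest$id[1], ".pdb"))))
  expect_error(synthetic_set_experiment(c("GADV"), propensity_map = c(G = 1),
                                      n_peptides = 1, n_frames = 5),
               "lacks entries")
})
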