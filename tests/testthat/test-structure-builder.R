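# Internal-coordinate construction and multi-model PDB round-trips.

test_that("canonical helix dihedrals give canonical helix geometry", {
  conf <- ideal_helix()
  ca <- conf$xyz[conf$atoms$elety == "CA", ]
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  rise <- mean(abs(diff(stats::prcomp(ca)$x[, 1])))
  expect_true(abs(rise - 1.5) < 0.15)
})

test_that("construction reproduces its input internal coordinates", {
  conf <- build_conformation("GADVEL", rep(-70, 6), rep(140, 6))
  at <- function(e, r) conf$xyz[conf$atoms$elety == e & conf$atoms$resid == r, ]
  # N-CA bond equals the template value essentially exactly
  expect_equal(sqrt(sum((at("N", 3) - at("CA", 3))^2)), 1.458,
               tolerance = 1e-9)
  expect_equal(dihedral_angle(at("C", 2), at("N", 3), at("CA", 3), at("C", 3)),
               -70, tolerance = 1e-6)
  expect_equal(dihedral_angle(at("N", 3), at("CA", 3), at("C", 3), at("N", 4)),
               140, tolerance = 1e-6)
  # every bonded backbone distance within 0.1 A of template values
  tpl <- residue_templates()
  bb <- tpl[tpl$residue == "*", ]
  for (r in 2:5) {
    expect_lt(abs(sqrt(sum((at("C", r - 1) - at("N", r))^2)) -
                    bb$bond[bb$atom == "N"]), 0.1)
    expect_lt(abs(sqrt(sum((at("CA", r) - at("C", r))^2)) -
                    bb$bond[bb$atom == "C"]), 0.1)
  }
})

test_that("residue chemistry follows the charged-termini convention", {
  conf <- build_conformation("GADVE", rep(-57, 5), rep(-47, 5))
  atoms <- conf$atoms
  # glycine has no CB
  expect_false(any(atoms$elety == "CB" & atoms$resid == 1))
  expect_true(any(atoms$elety == "CB" & atoms$resid == 2))
  # ammonium N-terminus: three hydrogens on residue 1, no backbone H
  expect_equal(sum(atoms$resid == 1 & atoms$element == "H"), 3)
  # deprotonated carboxylates: two oxygens, no H on D/E side chains
  expect_equal(sum(atoms$resid == 3 & atoms$elety %in% c("OD1", "OD2")), 2)
  expect_equal(sum(atoms$resid == 5 & atoms$elety %in% c("OE1", "OE2")), 2)
  expect_true("OXT" %in% atoms$elety[atoms$resid == 5])
  # polarity rule: N, O and (amide) H polar, C apolar
  expect_true(all(atoms$is_polar[atoms$element %in% c("N", "O", "H")]))
  expect_false(any(atoms$is_polar[atoms$element == "C"]))
})

test_that("amide hydrogens follow the assigner's reconstruction", {
  conf <- ideal_helix()
  at <- function(e, r) conf$xyz[conf$atoms$elety == e & conf$atoms$resid == r, ]
  h5 <- place_amide_hydrogen(conf, 5)
  expect_equal(sqrt(sum((h5 - at("N", 5))^2)), 1.01, tolerance = 1e-9)
  expect_equal(h5, unname(at("H", 5)), tolerance = 1e-9)
  # interior residues point their N-H at the i-4 carbonyl
  for (i in 6:15)
    expect_lt(sqrt(sum((at("H", i) - at("O", i - 4))^2)), 2.5)
  hs <- place_amide_hydrogen(conf, 1)
  expect_equal(dim(hs), c(3L, 3L))
  expect_true(all(abs(sqrt(rowSums((hs - matrix(at("N", 1), 3, 3,
                                                byrow = TRUE))^2)) - 1.01)
                  < 1e-9))
})

test_that("construction is rigid-motion covariant and clash-free", {
  conf <- build_conformation("ADVELG", rep(-70, 6), rep(150, 6))
  moved <- rigid_transform(conf$xyz)
  # internal coordinates are untouched by a rigid motion
  i <- which(conf$atoms$elety == "CA")
  expect_equal(
    dihedral_angle(moved[i[1], ], moved[i[2], ], moved[i[3], ], moved[i[4], ]),
    dihedral_angle(conf$xyz[i[1], ], conf$xyz[i[2], ], conf$xyz[i[3], ],
                   conf$xyz[i[4], ]),
    tolerance = 1e-9)
  # nonbonded heavy-atom clash guard on helix and extended fixtures
  for (fix in list(ideal_helix(), extended_chain())) {
    heavy <- which(fix$atoms$element != "H")
    xyz <- fix$xyz[heavy, ]
    d <- as.matrix(stats::dist(xyz))
    resid <- fix$atoms$resid[heavy]
    # nonbonded = different residue or more than two bonds apart; screen by
    # excluding pairs within the same or adjacent residue
    far <- abs(outer(resid, resid, "-")) > 1
    expect_gt(min(d[far]), 1.5)
  }
})

test_that("unknown residues and mismatched dihedrals are rejected", {
  expect_error(build_conformation("AXA", rep(0, 3), rep(0, 3)), "unknown residue")
  expect_error(build_conformation("AAA", rep(0, 2), rep(0, 3)), "one entry per")
  expect_error(build_conformation("AVA", rep(0, 3), rep(0, 3),
                                  chi = list(numeric(0), c(1, 2), numeric(0))),
               "expected 1 chi")
})

test_that("multi-model PDB round-trips at format precision", {
  traj <- mixed_trajectory("GADVEL", n_frames = 2, seed = 1)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f, frame_spacing = 0.5)
  expect_equal(n_frames(back), 2)
  expect_identical(back$atoms$elety, traj$atoms$elety)
  expect_identical(back$atoms$resid, traj$atoms$resid)
  expect_true(max(abs(back$coords - traj$coords)) < 5e-4)
  expect_identical(back$sequence, traj$sequence)
  expect_identical(back$atoms$is_polar, traj$atoms$is_polar)

  # single-model file reads as a one-frame trajectory
  conf <- ideal_helix("GADV")
  f1 <- tempfile(fileext = ".pdb")
  write_trajectory(conf, f1)
  expect_equal(n_frames(read_trajectory(f1)), 1)
})

test_that("a model with a missing atom is rejected with its index", {
  traj <- mixed_trajectory("GADV", n_frames = 3, seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  lines <- readLines(f)
  starts <- grep("^MODEL", lines)
  atom2 <- grep("^ATOM", lines)
  drop <- atom2[atom2 > starts[2]][1]  # first atom of MODEL 2
  writeLines(lines[-drop], f)
  expect_error(read_trajectory(f), "MODEL 2")
})
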