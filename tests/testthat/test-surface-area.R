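# Shrake-Rupley surfaces: closed forms, invariances, oracle agreement.

test_that("isolated and two-sphere areas match closed forms", {
  atoms <- data.frame(elety = "O", element = "O", resid = 1L,
                      stringsAsFactors = FALSE)
  one <- manual_conformation(atoms, matrix(c(0, 0, 0), 1, 3))
  s1 <- shrake_rupley(one, probe_radius = 1.4, n_points = 960)
  exact <- 4 * pi * (1.52 + 1.4)^2
  expect_lt(abs(s1$sasa - exact) / exact, 0.02)

  atoms2 <- data.frame(elety = c("C", "O"), element = c("C", "O"),
                       resid = c(1L, 2L), stringsAsFactors = FALSE)
  d <- 2.5
  two <- manual_conformation(atoms2, rbind(c(0, 0, 0), c(d, 0, 0)))
  s2 <- shrake_rupley(two, 1.4, 960)
  r1 <- 1.70 + 1.4; r2 <- 1.52 + 1.4
  closed <- two_sphere_exposed(r1, r2, d) + two_sphere_exposed(r2, r1, d)
  expect_lt(abs(s2$sasa - closed) / closed, 0.03)
})

test_that("an enclosed atom reports zero area", {
  # small sphere at the centre of an octahedral cage of large spheres
  atoms <- data.frame(elety = rep("C", 7), element = rep("C", 7),
                      resid = 1:7, stringsAsFactors = FALSE)
  cage <- rbind(c(0, 0, 0),
                2.2 * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  conf <- manual_conformation(atoms, cage)
  conf$atoms$vdw_radius <- c(0.3, rep(2.5, 6))
  s <- shrake_rupley(conf, probe_radius = 0, n_points = 960)
  expect_equal(s$per_atom_area[1], 0)
})

test_that("surface areas are rigid-motion invariant within lattice tolerance", {
  conf <- ideal_helix("GADVEL")
  a <- shrake_rupley(conf)
  moved <- conf
  moved$xyz <- rigid_transform(conf$xyz)
  b <- shrake_rupley(moved)
  expect_lt(abs(a$sasa - b$sasa) / a$sasa, 0.01)
  expect_lt(abs(a$psa - b$psa) / a$psa, 0.01)
})

test_that("removing an atom never decreases remaining areas", {
  conf <- ideal_helix("GADV")
  full <- shrake_rupley(conf)
  drop <- which(conf$atoms$elety == "CB")[1]
  pruned <- conf
  pruned$atoms <- conf$atoms[-drop, ]
  pruned$xyz <- conf$xyz[-drop, , drop = FALSE]
  less <- shrake_rupley(pruned)
  expect_true(all(less$per_atom_area >= full$per_atom_area[-drop] - 1e-9))
})

test_that("polar area is bounded by total area and duplicates are flagged", {
  conf <- ideal_helix("DVEGAL")
  s <- shrake_rupley(conf)
  expect_true(all(s$per_atom_area >= 0))
  expect_equal(s$sasa, sum(s$per_atom_area))
  expect_lte(s$psa, s$sasa)
  expect_gte(s$psa_ratio, 0); expect_lte(s$psa_ratio, 1)

  dup <- conf
  dup$xyz[5, ] <- dup$xyz[4, ]
  expect_warning(sd <- shrake_rupley(dup), "coincident")
  expect_equal(sd$per_atom_area[5], 0)
})

test_that("trajectory averaging is the arithmetic mean of frames", {
  c1 <- ideal_helix("GADVE")
  c2 <- extended_chain("GADVE")
  arr <- array(0, dim = c(nrow(c1$xyz), 3, 2))
  arr[, , 1] <- c1$xyz; arr[, , 2] <- c2$xyz
  traj <- peptraj:::new_trajectory(c1$sequence, c1$atoms, arr, 0.5)
  avg <- trajectory_surface(traj)
  s1 <- shrake_rupley(c1); s2 <- shrake_rupley(c2)
  expect_equal(avg$sasa, (s1$sasa + s2$sasa) / 2, tolerance = 1e-9)
  expect_equal(avg$psa, (s1$psa + s2$psa) / 2, tolerance = 1e-9)
  # ratio of means, not mean of ratios
  expect_equal(avg$psa_ratio, (s1$psa + s2$psa) / (s1$sasa + s2$sasa),
               tolerance = 1e-9)
  # identical frames reproduce the single-frame result
  arr2 <- array(rep(c1$xyz, 3), dim = c(nrow(c1$xyz), 3, 3))
  traj2 <- peptraj:::new_trajectory(c1$sequence, c1$atoms, arr2, 0.5)
  expect_equal(trajectory_surface(traj2)$sasa, s1$sasa, tolerance = 1e-9)
})

test_that("totals agree with the reference surface library", {
  set.seed(17)
  for (k in 1:5) {
    seq <- paste(sample(c("G", "A", "D", "V", "E", "L"), 8, TRUE),
                 collapse = "")
    conf <- build_conformation(seq, runif(8, -150, -50), runif(8, -60, 160))
    mine <- shrake_rupley(conf, n_points = 960)
    ref <- biotite_sasa(conf$xyz, conf$atoms$vdw_radius)
    expect_lt(abs(mine$sasa - ref) / ref, 0.03)
  }
})
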