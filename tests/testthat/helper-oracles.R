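# Independent oracles and shared fixtures for the suite.

# Horn's quaternion method for optimal superposition RMSD — an independent
# check on the SVD-based Kabsch implementation.
quaternion_rmsd <- function(reference, mobile) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lambda) / nrow(X)
  sqrt(max(0, msd))
}

# Exposed spherical area of a sphere with radius R overlapped by a sphere of
# radius r whose centre is d away (spherical-cap closed form).
two_sphere_exposed <- function(R, r, d) {
  x <- (d^2 - r^2 + R^2) / (2 * d)
  4 * pi * R^2 - 2 * pi * R * (R - x)
}

rigid_transform <- function(xyz, angles = c(0.3, -1.1, 2.0),
                            shift = c(5, -3, 8)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  sweep(xyz %*% t(Rz %*% Ry %*% Rx), 2, -shift)
}

ideal_helix <- function(sequence = strrep("A", 20)) {
  n <- nchar(sequence)
  build_conformation(sequence, rep(-57, n), rep(-47, n))
}

extended_chain <- function(sequence = strrep("A", 20)) {
  n <- nchar(sequence)
  build_conformation(sequence, rep(180, n), rep(180, n))
}

# mixed helical/coil conformations sharing one topology; returns a trajectory
mixed_trajectory <- function(sequence, n_frames, seed) {
  set.seed(seed)
  n <- nchar(sequence)
  phi <- matrix(0, n_frames, n)
  psi <- matrix(0, n_frames, n)
  for (f in seq_len(n_frames)) {
    helical <- rep(FALSE, n)
    if (f > 1 && n > 6) {  # frame 1 pure coil
      st <- sample(seq_len(n - 5), 1)
      helical[st:min(n, st + sample(4:9, 1))] <- TRUE
    }
    phi[f, ] <- ifelse(helical, -57, sample(c(-120, -75), n, TRUE)) +
      rnorm(n, 0, 8)
    psi[f, ] <- ifelse(helical, -47, sample(c(130, 145), n, TRUE)) +
      rnorm(n, 0, 8)
  }
  peptraj:::build_trajectory_frames(sequence, phi, psi)
}

# per-frame label matrix from the reference assigner (mdtraj, via python)
mdtraj_dssp <- function(trajectory) {
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".txt")
  write_trajectory(trajectory, pdb)
  script <- system.file("python", "dssp_oracle.py", package = "peptraj")
  status <- system2("python", c(script, pdb, out))
  stopifnot(status == 0)
  do.call(rbind, strsplit(readLines(out), ""))
}

# total SASA from the reference surface library (biotite, via python), using
# exactly the supplied radii
biotite_sasa <- function(xyz, radii, probe = 1.4, n_points = 1000) {
  csv <- tempfile(fileext = ".csv")
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = radii)
  utils::write.csv(df, csv, row.names = FALSE)
  script <- system.file("python", "sasa_oracle.py", package = "peptraj")
  out <- system2("python", c(script, csv, probe, n_points), stdout = TRUE)
  as.numeric(out[length(out)])
}

# conformation whose donor N-H lies along +x with one acceptor O per extra
# residue, each placed at a requested X-H...X' angle and H...X' distance
hbond_fixture <- function(acc_angles_deg, acc_dists) {
  n_acc <- length(acc_angles_deg)
  atoms <- data.frame(
    elety = c("N", "H", rep("O", n_acc)),
    element = c("N", "H", rep("O", n_acc)),
    resid = c(1L, 1L, seq_len(n_acc) + 1L),
    stringsAsFactors = FALSE)
  H <- c(1.01, 0, 0)
  xyz <- rbind(c(0, 0, 0), H)
  for (k in seq_len(n_acc)) {
    th <- acc_angles_deg[k] * pi / 180
    az <- 2 * pi * (k - 1) / max(1, n_acc)
    u <- c(-cos(th), sin(th) * cos(az), sin(th) * sin(az))
    xyz <- rbind(xyz, H + acc_dists[k] * u)
  }
  manual_conformation(atoms, xyz)
}

# bare-bones conformation with hand-placed atoms (for H-bond boundary
# geometries); `atoms` rows: elety, element, resid
manual_conformation <- function(atoms, xyz) {
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$resid3 <- "GLY"
  atoms$vdw_radius <- unname(peptraj:::VDW_RADII[atoms$element])
  atoms$is_polar <- atoms$element %in% c("N", "O", "H")
  peptraj:::new_conformation(rep("G", max(atoms$resid)), atoms, xyz)
}
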