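# Molecular containers and the internal-coordinate peptide builder.

new_conformation <- function(sequence, atoms, xyz, id = NULL, set = NULL) {
  structure(list(sequence = sequence, atoms = atoms, xyz = xyz,
                 id = id, set = set),
            class = "pept_conformation")
}

new_trajectory <- function(sequence, atoms, coords, frame_spacing,
                           id = NULL, set = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (!is.numeric(frame_spacing) || frame_spacing <= 0)
    stop("frame_spacing must be a positive number of picoseconds")
  structure(list(sequence = sequence, atoms = atoms, coords = coords,
                 frame_spacing = frame_spacing, id = id, set = set),
            class = "pept_trajectory")
}

#' @export
print.pept_conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d residues (%s), %d atoms\n",
              length(x$sequence), paste(x$sequence, collapse = ""),
              nrow(x$atoms)))
  invisible(x)
}

#' @export
print.pept_trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d residues, %d atoms, %d frames @ %.3g ps spacing\n",
    length(x$sequence), nrow(x$atoms), n_frames(x), x$frame_spacing))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A trajectory object.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame of a trajectory as a conformation
#' @param trajectory A trajectory object.
#' @param i Frame index (1-based).
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  new_conformation(trajectory$sequence, trajectory$atoms,
                   trajectory$coords[, , i, drop = TRUE],
                   id = trajectory$id, set = trajectory$set)
}

#' Build a peptide conformation from backbone and side-chain dihedrals
#'
#' Places heavy atoms and polar (amide/ammonium) hydrogens by sequential
#' internal-coordinate construction using the shipped geometry templates.
#' Aspartate/glutamate side chains and the C-terminal carboxylate are built
#' deprotonated (two oxygens at 1.25 Angstrom, no hydrogen); the N-terminus is
#' an ammonium group with three hydrogens. The backbone amide hydrogen of
#' residues 2..n is reconstructed 1.01 Angstrom from N along the preceding
#' peptide bond's C=O direction, the convention the secondary-structure
#' assigner uses.
#'
#' @param sequence Residue sequence: a single string or character vector of
#'   one-letter codes drawn from G, A, D, V, E, L.
#' @param phi,psi Numeric vectors of backbone dihedrals in degrees, one per
#'   residue (`phi[1]` and the torsion component of `psi[n]` beyond the
#'   carboxylate orientation are conventional).
#' @param chi Optional list of per-residue side-chain torsions (degrees); each
#'   element must match the residue's rotatable-bond count. `NULL` uses the
#'   template rotamers.
#' @param id,set Optional labels carried through the pipeline.
#' @return A conformation object: atom table plus an n x 3 coordinate matrix
#'   in Angstrom.
#' @examples
#' helix <- build_conformation(strrep("A", 10), rep(-57, 10), rep(-47, 10))
#' helix
#' @export
build_conformation <- function(sequence, phi, psi, chi = NULL,
                               id = NULL, set = NULL) {
  sequence <- as_residue_vector(sequence)
  n <- length(sequence)
  if (length(phi) != n || length(psi) != n)
    stop(sprintf("phi and psi must each have one entry per residue (%d)", n))
  prog <- build_program(sequence, chi)
  arr <- build_frames_cpp(prog$prog_i, prog$prog_d,
                          matrix(phi, nrow = 1), matrix(psi, nrow = 1),
                          nrow(prog$atoms))
  new_conformation(sequence, prog$atoms, arr[, , 1], id = id, set = set)
}

# Build many frames sharing one topology (used by the synthetic generator).
# phi, psi: nframes x nres matrices in degrees.
build_trajectory_frames <- function(sequence, phi, psi, chi = NULL,
                                    frame_spacing = 0.5, id = NULL,
                                    set = NULL) {
  sequence <- as_residue_vector(sequence)
  stopifnot(ncol(phi) == length(sequence), all(dim(phi) == dim(psi)))
  prog <- build_program(sequence, chi)
  arr <- build_frames_cpp(prog$prog_i, prog$prog_d, phi, psi,
                          nrow(prog$atoms))
  new_trajectory(sequence, prog$atoms, arr, frame_spacing, id = id, set = set)
}

#' Reconstruct the backbone amide hydrogen of a residue
#'
#' For residues 2..n the hydrogen is placed 1.01 Angstrom from N along the
#' unit vector from the preceding carbonyl oxygen to its carbon (the standard
#' assigner's reconstruction). For residue 1 the three ammonium hydrogens are
#' returned as a 3 x 3 matrix (tetrahedral, staggered about the CA-N bond).
#'
#' @param conformation A conformation object.
#' @param residue_index 1-based residue position.
#' @return A length-3 coordinate vector, or a 3 x 3 matrix for residue 1.
#' @export
place_amide_hydrogen <- function(conformation, residue_index) {
  atoms <- conformation$atoms
  xyz <- conformation$xyz
  at <- function(elety, resid) {
    ix <- atom_index0(atoms, elety, resid) + 1L
    if (ix == 0L) stop(sprintf("missing atom %s in residue %d", elety, resid))
    xyz[ix, ]
  }
  i <- residue_index
  if (i == 1L) {
    refC <- at("C", 1L); refCA <- at("CA", 1L); refN <- at("N", 1L)
    hs <- t(vapply(NTERM_H_TORSIONS, function(tor) {
      nerf_point(refC, refCA, refN, NH_BOND, NTERM_H_ANGLE, tor)
    }, numeric(3)))
    rownames(hs) <- c("H1", "H2", "H3")
    return(hs)
  }
  N <- at("N", i); Cp <- at("C", i - 1L); Op <- at("O", i - 1L)
  v <- Cp - Op
  unname(N + NH_BOND * v / sqrt(sum(v^2)))
}

# single NeRF placement in R (used for terminal hydrogens and tests)
nerf_point <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  unname(c + (-bond * cos(th)) * bc +
           (bond * sin(th) * cos(chi)) * m +
           (bond * sin(th) * sin(chi)) * n)
}

#' Dihedral angle defined by four points
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees in (-180, 180], IUPAC sign convention.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum((c(b1[2] * v[3] - b1[3] * v[2],
              b1[3] * v[1] - b1[1] * v[3],
              b1[1] * v[2] - b1[2] * v[1])) * w)
  atan2(y, x) * 180 / pi
}

# coordinates of one named atom per residue (n_res x 3), e.g. all CA
atom_coords <- function(x, elety = "CA") {
  atoms <- x$atoms
  ix <- vapply(seq_along(x$sequence),
               function(i) atom_index0(atoms, elety, i) + 1L, integer(1))
  if (any(ix == 0L)) stop("atom ", elety, " missing from some residue")
  if (inherits(x, "pept_trajectory")) x$coords[ix, , , drop = FALSE]
  else x$xyz[ix, , drop = FALSE]
}

# indices helper used by analysis stages (0-based vectors per residue)
backbone_indices0 <- function(atoms, nres) {
  list(
    N = vapply(seq_len(nres), function(i) atom_index0(atoms, "N", i), integer(1)),
    CA = vapply(seq_len(nres), function(i) atom_index0(atoms, "CA", i), integer(1)),
    C = vapply(seq_len(nres), function(i) atom_index0(atoms, "C", i), integer(1)),
    O = vapply(seq_len(nres), function(i) atom_index0(atoms, "O", i), integer(1)),
    H = vapply(seq_len(nres), function(i) atom_index0(atoms, "H", i), integer(1))
  )
}
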