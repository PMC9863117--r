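# Shrake-Rupley solvent-accessible surface area and the polar-surface
# hydrophilicity index.

#' Shrake-Rupley accessible surface area of a conformation
#'
#' Samples a deterministic golden-section spiral of `n_points` on each atom's
#' expanded sphere (van der Waals radius + probe); a point is accessible if it
#' lies outside every other atom's expanded sphere. Per-atom accessible area
#' is `4*pi*(r+probe)^2 * accessible/n_points`. Polar area (PSA) sums the
#' areas of polar atoms: N, O, and hydrogens bonded to N/O.
#'
#' Exactly coincident atom coordinates are flagged with a warning and the
#' duplicate atom is excluded from the computation (it reports zero area and
#' does not occlude its twin).
#'
#' @param conformation A conformation object.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom (>= 64).
#' @param include_hydrogens Include hydrogen spheres in the computation
#'   (`TRUE`, the default, counts polar-H area in PSA; `FALSE` computes a
#'   heavy-atom-only surface).
#' @return List with `per_atom_area`, `sasa`, `psa`, `psa_ratio`.
#' @export
shrake_rupley <- function(conformation, probe_radius = 1.4, n_points = 960L,
                          include_hydrogens = TRUE) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 64) stop("n_points must be at least 64")
  atoms <- conformation$atoms
  xyz <- conformation$xyz
  keep <- rep(TRUE, nrow(atoms))
  if (!include_hydrogens) keep <- atoms$element != "H"
  dup <- duplicated(round(xyz, 10)) & keep
  if (any(dup)) {
    warning(sprintf("%d atom(s) with coincident coordinates excluded",
                    sum(dup)))
    keep <- keep & !dup
  }
  area <- sasa_atoms_cpp(xyz, atoms$vdw_radius, probe_radius,
                         as.integer(n_points), keep)
  sasa <- sum(area)
  psa <- sum(area[atoms$is_polar])
  list(per_atom_area = area, sasa = sasa, psa = psa,
       psa_ratio = if (sasa > 0) psa / sasa else NA_real_)
}

#' Trajectory-averaged surface areas
#'
#' Arithmetic mean over (optionally strided) frames of total and polar
#' accessible area; the reported `psa_ratio` is the ratio of the trajectory
#' means (not the mean of per-frame ratios).
#'
#' @param window A trajectory object.
#' @inheritParams shrake_rupley
#' @param stride Analyse every `stride`-th frame.
#' @return List with `sasa`, `psa`, `psa_ratio`, and the per-analysed-frame
#'   matrix `per_frame` (columns `sasa`, `psa`).
#' @export
trajectory_surface <- function(window, probe_radius = 1.4, n_points = 960L,
                               stride = 1L, include_hydrogens = TRUE) {
  frames <- seq.int(1L, n_frames(window), by = as.integer(stride))
  atoms <- window$atoms
  radii <- atoms$vdw_radius
  polar <- atoms$is_polar
  coords <- window$coords
  if (!include_hydrogens) {
    keep <- atoms$element != "H"
    coords <- coords[keep, , , drop = FALSE]
    radii <- radii[keep]
    polar <- polar[keep]
  }
  m <- sasa_frames_cpp(coords, frames - 1L, radii, polar,
                       probe_radius, as.integer(n_points))
  colnames(m) <- c("sasa", "psa")
  sasa <- mean(m[, 1]); psa <- mean(m[, 2])
  list(sasa = sasa, psa = psa,
       psa_ratio = if (sasa > 0) psa / sasa else NA_real_,
       per_frame = m)
}
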