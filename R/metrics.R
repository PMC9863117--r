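# Per-peptide trajectory classifiers: analysis window, superposition, RMSF,
# hydrogen bonds, and the orchestrating metrics stage.

#' Select the final analysis window of a trajectory
#'
#' Returns the last `window_ns` nanoseconds of frames given the trajectory's
#' frame spacing; a 200 ns trajectory written every 0.5 ps windows to the
#' last 20,000 frames at `window_ns = 10`.
#'
#' @param trajectory A trajectory object.
#' @param window_ns Window length in nanoseconds.
#' @return A trajectory containing the final frames.
#' @export
analysis_window <- function(trajectory, window_ns) {
  nf <- n_frames(trajectory)
  nw <- as.integer(round(window_ns * 1000 / trajectory$frame_spacing))
  if (nw < 1) stop("window_ns too small: selects no frames")
  if (nw > nf)
    stop(sprintf("window of %g ns needs %d frames but trajectory has %d",
                 window_ns, nw, nf))
  keep <- seq.int(nf - nw + 1L, nf)
  new_trajectory(trajectory$sequence, trajectory$atoms,
                 trajectory$coords[, , keep, drop = FALSE],
                 trajectory$frame_spacing, id = trajectory$id,
                 set = trajectory$set)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' @param reference,mobile Point matrices (n x 3, n >= 3, not collinear).
#' @return List with `rotation` (proper, det +1), `translation`, `rmsd`, and
#'   `aligned` (mobile mapped onto the reference frame).
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)) || ncol(reference) != 3)
    stop("reference and mobile must be equal-sized n x 3 matrices")
  if (nrow(reference) < 3) stop("at least 3 points are required")
  cr <- sweep(reference, 2, colMeans(reference))
  if (min(svd(cr)$d) < 1e-10 * max(svd(cr)$d))
    stop("degenerate (collinear) reference points")
  fit <- kabsch_cpp(reference, mobile)
  fit$aligned <- sweep(mobile %*% fit$rotation, 2, -fit$translation)
  fit
}

#' Iterated average structure of a trajectory window
#'
#' Superposes all frames (all-CA, unweighted) on the running mean, recomputes
#' the mean, and repeats until the mean shifts by less than `tol` Angstrom
#' (RMS per atom) or `max_iter` iterations.
#'
#' @param window A trajectory object (>= 2 frames).
#' @param tol Convergence threshold in Angstrom.
#' @param max_iter Iteration cap.
#' @return n_res x 3 matrix of average CA coordinates.
#' @export
average_structure <- function(window, tol = 1e-6, max_iter = 10L) {
  ca <- atom_coords(window, "CA")
  if (dim(ca)[3] < 2) stop("average structure needs at least 2 frames")
  ref <- ca[, , 1, drop = TRUE]
  for (it in seq_len(max_iter)) {
    al <- superpose_frames_cpp(ca, ref)$coords
    m <- apply(al, c(1, 2), mean)
    shift <- sqrt(mean((m - ref)^2))
    ref <- m
    if (shift < tol) break
  }
  ref
}

#' Per-residue CA root-mean-square fluctuation
#'
#' Each frame is superposed (all CA, unweighted) onto the converged average
#' structure; `RMSF_i = sqrt(mean_f |r_i(f) - rbar_i|^2)`. Residues with
#' `RMSF < rigid_cutoff` (strict) are flagged rigid.
#'
#' @param window A trajectory object (>= 2 frames).
#' @param rigid_cutoff Rigidity threshold in Angstrom (default 4.0).
#' @return Data frame with `residue`, `rmsf_ca`, `is_rigid`.
#' @export
rmsf <- function(window, rigid_cutoff = 4.0) {
  ca <- atom_coords(window, "CA")
  avg <- average_structure(window)
  vals <- rmsf_from_coords(ca, avg)
  data.frame(residue = seq_along(vals), rmsf_ca = vals,
             is_rigid = vals < rigid_cutoff)
}

#' RMSF of a coordinate ensemble about a reference
#'
#' Lower-level entry used by [rmsf()] and by synthetic-scaffold checks: every
#' frame of `coords` (n x 3 x frames) is superposed on `reference` and the
#' per-point fluctuation about the reference is returned.
#'
#' @param coords n x 3 x frames array.
#' @param reference n x 3 matrix; defaults to the iterated ensemble mean.
#' @return Numeric vector of per-point RMSF in Angstrom.
#' @export
rmsf_from_coords <- function(coords, reference = NULL) {
  if (is.null(reference)) {
    ref <- coords[, , 1, drop = TRUE]
    for (it in 1:10) {
      al <- superpose_frames_cpp(coords, ref)$coords
      m <- apply(al, c(1, 2), mean)
      if (sqrt(mean((m - ref)^2)) < 1e-6) { ref <- m; break }
      ref <- m
    }
    reference <- ref
  }
  al <- superpose_frames_cpp(coords, reference)$coords
  dev2 <- (al - array(reference, dim = dim(al)))^2
  # mean over frames of the squared 3D deviation per point
  sqrt(apply(dev2, 1, sum) / dim(al)[3])
}

# donor (heavy, H) pairs and acceptor candidates for the geometric H-bond
# stage; donors are N/O carrying a hydrogen, acceptors all N/O
hbond_participants <- function(atoms, backbone_only = FALSE) {
  hs <- which(atoms$element == "H")
  donors <- NULL
  if (length(hs)) {
    # hydrogens are named H/H1-H3 and always sit on their residue's N
    heavy_n <- vapply(hs, function(h)
      which(atoms$elety == "N" & atoms$resid == atoms$resid[h])[1], integer(1))
    donors <- cbind(heavy_n, hs)
  }
  acceptors <- which(atoms$element %in% c("N", "O"))
  if (backbone_only) {
    bb_names <- c("N", "O", "OXT")
    donors <- donors[atoms$elety[donors[, 1]] %in% bb_names, , drop = FALSE]
    acceptors <- acceptors[atoms$elety[acceptors] %in% bb_names]
  }
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds in one conformation
#'
#' Geometric criterion: a donor X-H and acceptor X' form a bond when the
#' X-H...X' angle is at least `min_angle` degrees and the H...X' distance is
#' at most `max_dist` Angstrom. Donors are N/O atoms carrying a hydrogen;
#' acceptors are all N/O atoms; intra-residue pairs are excluded. No minimum
#' sequence separation is imposed beyond the same-residue rule.
#'
#' @param conformation A conformation object.
#' @param min_angle Angle cutoff in degrees (default 120).
#' @param max_dist H-to-acceptor distance cutoff in Angstrom (default 3.5).
#' @param backbone_only Restrict donors/acceptors to backbone N/O/OXT.
#' @return Data frame of qualifying triples (1-based atom indices
#'   `donor_heavy`, `hydrogen`, `acceptor`), sorted canonically.
#' @export
detect_hbonds <- function(conformation, min_angle = 120, max_dist = 3.5,
                          backbone_only = FALSE) {
  parts <- hbond_participants(conformation$atoms, backbone_only)
  if (is.null(parts$donors) || nrow(parts$donors) == 0)
    return(data.frame(donor_heavy = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  tr <- hbond_triples_cpp(conformation$xyz, parts$donors - 1L,
                          parts$acceptors - 1L,
                          as.integer(conformation$atoms$resid),
                          min_angle, max_dist)
  out <- data.frame(donor_heavy = tr[, 1] + 1L, hydrogen = tr[, 2] + 1L,
                    acceptor = tr[, 3] + 1L)
  out[order(out$donor_heavy, out$hydrogen, out$acceptor), , drop = FALSE]
}

#' Mean hydrogen-bond count over a trajectory window
#'
#' Arithmetic mean over frames of the number of qualifying donor-H-acceptor
#' triples (see [detect_hbonds()]).
#'
#' @inheritParams detect_hbonds
#' @param window A trajectory object.
#' @export
mean_hbond_count <- function(window, min_angle = 120, max_dist = 3.5,
                             backbone_only = FALSE) {
  parts <- hbond_participants(window$atoms, backbone_only)
  if (is.null(parts$donors) || nrow(parts$donors) == 0) return(0)
  counts <- hbond_count_cpp(window$coords, parts$donors - 1L,
                            parts$acceptors - 1L,
                            as.integer(window$atoms$resid),
                            min_angle, max_dist)
  mean(counts)
}

#' Full per-peptide metrics over the analysis window
#'
#' Orchestrates the pipeline: window selection, frame-wise secondary-structure
#' assignment, helix occupancy (helix residues at occupancy >=
#' `occupancy_threshold`), RMSF/rigidity about the iterated average structure,
#' geometric hydrogen-bond counting, and (optionally) trajectory-averaged
#' surface areas. `helix_content` is the mean of the helix mask over frames
#' and residues.
#'
#' @param trajectory A trajectory object.
#' @param window_ns Analysis window in ns; `NULL` analyses all frames.
#' @param occupancy_threshold Helix-residue occupancy boundary (inclusive).
#' @param rigid_cutoff RMSF rigidity threshold in Angstrom (strict `<`).
#' @param surface Compute SASA/PSA (the slowest stage)?
#' @param surface_stride Analyse every k-th frame of the window in the
#'   surface stage.
#' @param probe_radius,n_points Shrake-Rupley parameters.
#' @param hbond_min_angle,hbond_max_dist,backbone_only H-bond criterion.
#' @return List with `peptide` (one-row data frame) and `residues`
#'   (per-residue data frame).
#' @export
peptide_metrics <- function(trajectory, window_ns = NULL,
                            occupancy_threshold = 0.5, rigid_cutoff = 4.0,
                            surface = TRUE, surface_stride = 1L,
                            probe_radius = 1.4, n_points = 960L,
                            hbond_min_angle = 120, hbond_max_dist = 3.5,
                            backbone_only = FALSE) {
  window <- if (is.null(window_ns)) trajectory
            else analysis_window(trajectory, window_ns)
  rec <- assign_trajectory(window)
  occ <- helix_occupancy(rec)
  helix_res <- occ >= occupancy_threshold
  fluct <- rmsf(window, rigid_cutoff)
  mh <- mean_hbond_count(window, hbond_min_angle, hbond_max_dist,
                         backbone_only)
  res <- data.frame(residue = seq_along(occ),
                    helix_occupancy = occ,
                    is_helix_residue = helix_res,
                    rmsf_ca = fluct$rmsf_ca,
                    is_rigid = fluct$is_rigid)
  pep <- data.frame(
    id = if (is.null(trajectory$id)) NA_character_ else trajectory$id,
    set = if (is.null(trajectory$set)) NA_character_ else trajectory$set,
    n_helix_residues = sum(helix_res),
    n_rigid_residues = sum(fluct$is_rigid),
    mean_hbonds = mh,
    helix_content = mean(rec$helix_mask),
    mean_rmsf_ca = mean(fluct$rmsf_ca),
    sasa = NA_real_, psa = NA_real_, psa_ratio = NA_real_,
    stringsAsFactors = FALSE)
  if (surface) {
    surf <- trajectory_surface(window, probe_radius, n_points,
                               stride = surface_stride)
    pep$sasa <- surf$sasa
    pep$psa <- surf$psa
    pep$psa_ratio <- surf$psa_ratio
  }
  list(peptide = pep, residues = res)
}
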