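# Kabsch-Sander secondary-structure assignment and the helix mask.

SS_LEVELS <- c("-", "H", "G", "I", "E", "B", "T", "S")
HELIX_LABELS <- c("H", "G", "I")

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic proxy energy between the amide N-H of `donor_residue` and the
#' carbonyl C=O of `acceptor_residue`:
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol, clamped at
#' -9.9. A backbone hydrogen bond is declared when `E < -0.5` kcal/mol.
#' Residue pairs closer than two positions along the chain are not valid
#' backbone H-bond candidates. If the donor lacks an amide hydrogen (the
#' chain-start residue) the pair is reported as non-bonded (`NA` energy) with
#' a warning rather than an error, so one bad residue cannot abort a frame.
#'
#' @param conformation A conformation object.
#' @param donor_residue,acceptor_residue 1-based residue indices.
#' @return Energy in kcal/mol (`NA` if donor atoms are missing).
#' @export
backbone_hbond_energy <- function(conformation, donor_residue,
                                  acceptor_residue) {
  if (abs(donor_residue - acceptor_residue) < 2)
    stop("donor and acceptor must be at least 2 residues apart")
  atoms <- conformation$atoms
  xyz <- conformation$xyz
  ix <- function(elety, resid) atom_index0(atoms, elety, resid) + 1L
  hN <- ix("H", donor_residue)
  if (hN == 0L) {
    warning(sprintf(
      "residue %d has no amide hydrogen; pair reported as non-bonded",
      donor_residue))
    return(NA_real_)
  }
  ks_energy_cpp(xyz[ix("N", donor_residue), ], xyz[hN, ],
                xyz[ix("C", acceptor_residue), ],
                xyz[ix("O", acceptor_residue), ])
}

ss_codes_to_labels <- function(codes) {
  m <- matrix(SS_LEVELS[codes + 1L], nrow = nrow(codes))
  m
}

#' Assign secondary structure to a single conformation
#'
#' Implements the hydrogen-bond pattern rules of the Kabsch-Sander assigner:
#' n-turns at offsets 3/4/5, minimal helices from two consecutive turns
#' (G/H/I by offset), bridges and ladders (E, B) including single-bulge
#' linking, turns (T) and bends (S), with priority H > E > B > G > I > T > S.
#' The amide hydrogen is taken from the conformation when present and
#' reconstructed from the preceding carbonyl otherwise. Chains shorter than
#' three residues carry no pattern and return all `"-"`.
#'
#' @param conformation A conformation object with complete backbone.
#' @return Character vector of per-residue labels from
#'   `{H, G, I, E, B, T, S, -}`.
#' @export
assign_frame <- function(conformation) {
  traj <- new_trajectory(conformation$sequence, conformation$atoms,
                         array(conformation$xyz,
                               dim = c(dim(conformation$xyz), 1L)),
                         frame_spacing = 1)
  rec <- assign_trajectory(traj)
  rec$labels[1, ]
}

#' Assign secondary structure across a trajectory
#'
#' Frame-wise Kabsch-Sander assignment; the helix mask marks labels in
#' `{H, G, I}` (alpha, 3-10 and pi helices all count as helix; turns do not).
#'
#' @param trajectory A trajectory object.
#' @return An object of class `ss_record` with fields `labels`
#'   (frames x residues character matrix) and `helix_mask` (logical matrix of
#'   the same shape).
#' @export
assign_trajectory <- function(trajectory) {
  atoms <- trajectory$atoms
  nres <- length(trajectory$sequence)
  bb <- backbone_indices0(atoms, nres)
  miss <- vapply(c("N", "CA", "C", "O"),
                 function(k) any(bb[[k]] < 0), logical(1))
  if (any(miss))
    stop("incomplete backbone: missing ",
         paste(c("N", "CA", "C", "O")[miss], collapse = ", "))
  coords <- trajectory$coords
  if (any(bb$H[-1] < 0)) {
    # reconstruct missing amide hydrogens so the assignment stays total
    coords <- reconstruct_amide_h(trajectory, bb)
    bb <- coords$bb
    coords <- coords$coords
  }
  codes <- dssp_cpp(coords, bb$N, bb$CA, bb$C, bb$O, bb$H)
  labels <- ss_codes_to_labels(codes)
  structure(list(labels = labels,
                 helix_mask = matrix(labels %in% HELIX_LABELS,
                                     nrow = nrow(labels)),
                 sequence = trajectory$sequence,
                 frame_spacing = trajectory$frame_spacing),
            class = "ss_record")
}

# append reconstructed H atoms for residues 2..n lacking one
reconstruct_amide_h <- function(trajectory, bb) {
  coords <- trajectory$coords
  natoms <- dim(coords)[1]
  nres <- length(bb$N)
  need <- which(bb$H < 0)
  need <- need[need > 1L]
  if (!length(need)) return(list(coords = coords, bb = bb))
  nf <- dim(coords)[3]
  extra <- array(0, dim = c(length(need), 3L, nf))
  for (k in seq_along(need)) {
    i <- need[k]
    N <- coords[bb$N[i] + 1L, , , drop = TRUE]
    Cp <- coords[bb$C[i - 1L] + 1L, , , drop = TRUE]
    Op <- coords[bb$O[i - 1L] + 1L, , , drop = TRUE]
    if (nf == 1L) { N <- matrix(N, 3); Cp <- matrix(Cp, 3); Op <- matrix(Op, 3) }
    v <- Cp - Op
    vn <- sqrt(colSums(v^2))
    extra[k, , ] <- N + NH_BOND * sweep(v, 2, vn, "/")
  }
  new_coords <- array(0, dim = c(natoms + length(need), 3L, nf))
  new_coords[seq_len(natoms), , ] <- coords
  new_coords[natoms + seq_along(need), , ] <- extra
  bb$H[need] <- natoms + seq_along(need) - 1L
  list(coords = new_coords, bb = bb)
}

#' @export
print.ss_record <- function(x, ...) {
  cat(sprintf("<secondary structure> %d frames x %d residues; helix %0.1f%%\n",
              nrow(x$labels), ncol(x$labels), 100 * mean(x$helix_mask)))
  invisible(x)
}

#' Per-residue helix occupancy
#'
#' Fraction of frames in which each residue carries a helical label
#' (H, G or I).
#'
#' @param record An `ss_record`.
#' @export
helix_occupancy <- function(record) {
  stopifnot(inherits(record, "ss_record"))
  colMeans(record$helix_mask)
}

#' Export a secondary-structure record
#'
#' Writes the per-frame label matrix as CSV (rows = frames, columns =
#' residues) and, optionally, a compact per-residue helix-occupancy JSON.
#'
#' @param record An `ss_record`.
#' @param csv_path Label-matrix CSV path.
#' @param json_path Optional occupancy JSON path.
#' @export
export_ss_record <- function(record, csv_path, json_path = NULL) {
  m <- as.data.frame(record$labels)
  names(m) <- paste0("res", seq_len(ncol(record$labels)))
  write.csv(m, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    occ <- helix_occupancy(record)
    jsonlite::write_json(
      list(residue = seq_along(occ), helix_occupancy = round(occ, 6)),
      json_path, auto_unbox = FALSE)
  }
  invisible(csv_path)
}
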