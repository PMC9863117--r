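# Multi-model PDB trajectory input/output (bio3d behind the surface).

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, standard ATOM records, consistent atom
#' ordering across models. Coordinates are stored at the PDB format's
#' 3-decimal precision.
#'
#' @param trajectory A trajectory (or single conformation) object.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  if (inherits(trajectory, "pept_conformation")) {
    trajectory <- new_trajectory(
      trajectory$sequence, trajectory$atoms,
      array(trajectory$xyz, dim = c(dim(trajectory$xyz), 1L)),
      frame_spacing = 1, id = trajectory$id, set = trajectory$set)
  }
  atoms <- trajectory$atoms
  nf <- n_frames(trajectory)
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.vector(t(trajectory$coords[, , f])),
                  numeric(3L * nrow(atoms))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resid, resid = atoms$resid3,
                   elety = atoms$elety, chain = rep("A", nrow(atoms)),
                   elesy = atoms$element)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Models must share one atom count and ordering; a mismatch is rejected with
#' the offending MODEL index. Atom polarity (for the polar-surface stage) is
#' re-derived from the file: N and O atoms are polar, hydrogens are polar when
#' their nearest heavy atom is N or O.
#'
#' @param path Multi-model PDB file.
#' @param frame_spacing Time between frames in ps (PDB carries no time axis;
#'   the study protocol wrote frames every 0.5 ps).
#' @return A trajectory object.
#' @export
read_trajectory <- function(path, frame_spacing = 0.5) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("malformed multi-model PDB: MODEL/ENDMDL records do not pair")
    counts <- mapply(function(s, e)
      sum(grepl("^ATOM  |^HETATM", lines[s:e])), model_starts, ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf(
        "inconsistent atom count in MODEL %d (%d atoms, expected %d)",
        bad, counts[bad], counts[1]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  element[missing_el] <- substr(gsub("[0-9]", "", trimws(at$elety[missing_el])),
                                1, 1)
  element <- trimws(element)
  nres <- length(unique(at$resno))
  resid <- match(at$resno, sort(unique(at$resno)))
  atoms <- data.frame(eleno = seq_len(nrow(at)), elety = trimws(at$elety),
                      element = element, resid = resid,
                      resid3 = trimws(at$resid),
                      vdw_radius = unname(VDW_RADII[element]),
                      is_polar = element %in% c("N", "O"),
                      stringsAsFactors = FALSE)
  if (anyNA(atoms$vdw_radius))
    stop("unsupported element(s): ",
         paste(unique(element[is.na(atoms$vdw_radius)]), collapse = ", "))
  nf <- nrow(pdb$xyz)
  coords <- array(0, dim = c(nrow(atoms), 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  # hydrogens: polar iff nearest heavy atom (first frame) is N or O
  hs <- which(atoms$element == "H")
  if (length(hs)) {
    heavy <- which(atoms$element != "H")
    for (h in hs) {
      d2 <- colSums((t(coords[heavy, , 1, drop = TRUE]) - coords[h, , 1])^2)
      atoms$is_polar[h] <- atoms$element[heavy[which.min(d2)]] %in% c("N", "O")
    }
  }
  seq1 <- vapply(seq_len(nres), function(i)
    bio3d::aa321(atoms$resid3[match(i, atoms$resid)]), character(1))
  new_trajectory(seq1, atoms, coords, frame_spacing)
}
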