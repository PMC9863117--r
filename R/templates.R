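# Residue geometry templates and assembly of the internal-coordinate build
# program executed by the compiled NeRF engine.

.pept_cache <- new.env(parent = emptyenv())

# one-letter -> three-letter residue codes covered by the builder
AA3 <- c(G = "GLY", A = "ALA", D = "ASP", V = "VAL", E = "GLU", L = "LEU")
AA1 <- setNames(names(AA3), AA3)

# Bondi van der Waals radii (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, H = 1.20)

# constants the builder owns (termini + amide H; see template file header)
NH_BOND <- 1.01
NTERM_H_ANGLE <- 109.5
NTERM_H_TORSIONS <- c(60, 180, 300)
CARBOXYLATE_CO <- 1.25
OXT_ANGLE <- 117.0

TORSION_CODES <- c(fixed = 0L, phi = 1L, psi = 2L, psi_prev = 3L)

#' Residue geometry templates
#'
#' Internal-coordinate placement rules (bond length, bond angle, torsion rule)
#' for every atom of the supported residue types, as shipped in
#' `inst/extdata/residue_templates.tsv`. Backbone rows (residue `"*"`) apply
#' to all residue types.
#'
#' @return A data frame with one row per template atom.
#' @export
residue_templates <- function() {
  if (is.null(.pept_cache$templates)) {
    path <- system.file("extdata", "residue_templates.tsv", package = "peptraj")
    .pept_cache$templates <- read.delim(path, comment.char = "#",
                                        stringsAsFactors = FALSE)
  }
  .pept_cache$templates
}

#' Default side-chain torsions
#'
#' @return A data frame of default chi angles (degrees) per residue type;
#'   `NA` where a residue has fewer rotatable side-chain bonds.
#' @export
chi_defaults <- function() {
  if (is.null(.pept_cache$chi)) {
    path <- system.file("extdata", "chi_defaults.tsv", package = "peptraj")
    .pept_cache$chi <- read.delim(path, comment.char = "#",
                                  stringsAsFactors = FALSE)
  }
  .pept_cache$chi
}

# number of rotatable side-chain torsions per residue type
n_chi <- function(res1) {
  c(G = 0L, A = 0L, V = 1L, L = 2L, D = 2L, E = 3L)[res1]
}

as_residue_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(as.character(sequence))
  bad <- setdiff(unique(sequence), names(AA3))
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  sequence
}

# Atom table for a peptide: heavy atoms plus amide/ammonium hydrogens, in
# storage order N, CA, C, O, side chain, [OXT], hydrogens per residue.
peptide_topology <- function(sequence) {
  sequence <- as_residue_vector(sequence)
  n <- length(sequence)
  tpl <- residue_templates()
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- AA3[[sequence[i]]]
    side <- tpl[tpl$residue == res3, c("atom", "element")]
    nm <- c("N", "CA", "C", "O", side$atom)
    el <- c("N", "C", "C", "O", side$element)
    if (i == n) { nm <- c(nm, "OXT"); el <- c(el, "O") }
    if (i == 1L) { nm <- c(nm, "H1", "H2", "H3"); el <- c(el, "H", "H", "H") }
    else { nm <- c(nm, "H"); el <- c(el, "H") }
    rows[[i]] <- data.frame(elety = nm, element = el, resid = i,
                            resid3 = res3, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$vdw_radius <- VDW_RADII[atoms$element]
  # polar = N, O, and hydrogens bonded to N/O (every H here sits on a nitrogen)
  atoms$is_polar <- atoms$element %in% c("N", "O", "H")
  rownames(atoms) <- NULL
  atoms[, c("eleno", "elety", "element", "resid", "resid3",
            "vdw_radius", "is_polar")]
}

# index of atom `elety` in residue `resid` (0-based for the C++ engines)
atom_index0 <- function(atoms, elety, resid) {
  ix <- which(atoms$elety == elety & atoms$resid == resid)
  if (!length(ix)) return(-1L)
  ix[1] - 1L
}

# Fold caller/default chi angles into one offset table per residue.
resolve_chi <- function(sequence, chi) {
  n <- length(sequence)
  defs <- chi_defaults()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    need <- n_chi(sequence[i])
    d <- defs[defs$residue == AA3[[sequence[i]]], c("chi1", "chi2", "chi3")]
    vals <- as.numeric(d)[seq_len(need)]
    if (!is.null(chi)) {
      supplied <- chi[[i]]
      if (length(supplied) != need)
        stop(sprintf("residue %d (%s): expected %d chi angle(s), got %d",
                     i, sequence[i], need, length(supplied)))
      if (need > 0L) vals <- as.numeric(supplied)
    }
    out[[i]] <- vals
  }
  out
}

# Build-program assembly: one row per placed atom, in dependency order.
# Columns of prog_i: target, ref1, ref2, ref3 (0-based atom indices),
# ttype, resid (1-based), special opcode. prog_d: bond, angle (rad),
# torsion offset (rad).
build_program <- function(sequence, chi = NULL) {
  sequence <- as_residue_vector(sequence)
  n <- length(sequence)
  atoms <- peptide_topology(sequence)
  tpl <- residue_templates()
  bb <- tpl[tpl$residue == "*", ]
  bbrow <- function(a) bb[bb$atom == a, ]
  chiv <- resolve_chi(sequence, chi)

  pi_ <- list(); pd_ <- list(); k <- 0L
  add <- function(target, refs, bond, angle, ttype, offset, resid, special = 0L) {
    k <<- k + 1L
    pi_[[k]] <<- c(target, refs, ttype, resid, special)
    pd_[[k]] <<- c(bond, angle * pi / 180, offset * pi / 180)
  }
  ai <- function(elety, resid) atom_index0(atoms, elety, resid)

  caRow <- bbrow("CA"); cRow <- bbrow("C"); nRow <- bbrow("N"); oRow <- bbrow("O")

  for (i in seq_len(n)) {
    res3 <- AA3[[sequence[i]]]
    if (i == 1L) {
      add(ai("N", 1L), c(-1L, -1L, -1L), 0, 0, 0L, 0, 1L, special = 1L)
      add(ai("CA", 1L), c(-1L, -1L, ai("N", 1L)), caRow$bond, 0, 0L, 0, 1L,
          special = 2L)
      add(ai("C", 1L), c(-1L, ai("N", 1L), ai("CA", 1L)), cRow$bond,
          cRow$angle, 0L, 0, 1L, special = 3L)
    } else {
      p <- i - 1L
      add(ai("N", i), c(ai("N", p), ai("CA", p), ai("C", p)), nRow$bond,
          nRow$angle, TORSION_CODES[["psi_prev"]], nRow$offset, i)
      add(ai("CA", i), c(ai("CA", p), ai("C", p), ai("N", i)), caRow$bond,
          caRow$angle, TORSION_CODES[["fixed"]], caRow$offset, i)
      add(ai("C", i), c(ai("C", p), ai("N", i), ai("CA", i)), cRow$bond,
          cRow$angle, TORSION_CODES[["phi"]], cRow$offset, i)
    }
    # carbonyl / C-terminal carboxylate oxygen
    obond <- if (i == n) CARBOXYLATE_CO else oRow$bond
    add(ai("O", i), c(ai("N", i), ai("CA", i), ai("C", i)), obond,
        oRow$angle, TORSION_CODES[["psi"]], oRow$offset, i)
    # side chain
    side <- tpl[tpl$residue == res3, ]
    if (nrow(side)) {
      used_chi <- 0L
      for (r in seq_len(nrow(side))) {
        row <- side[r, ]
        refs <- vapply(c(row$ref1, row$ref2, row$ref3),
                       function(a) ai(a, i), integer(1))
        tt <- row$torsion_type
        offset <- row$offset
        if (grepl("^chi", tt)) {
          ci <- as.integer(sub("chi", "", tt))
          offset <- offset + chiv[[i]][ci]
          tt <- "fixed"
        }
        add(ai(row$atom, i), refs, row$bond, row$angle,
            TORSION_CODES[[tt]], offset, i)
      }
    }
    if (i == n)
      add(ai("OXT", i), c(ai("N", i), ai("CA", i), ai("C", i)),
          CARBOXYLATE_CO, OXT_ANGLE, TORSION_CODES[["psi"]], 0, i)
    if (i == 1L) {
      for (hh in 1:3)
        add(ai(paste0("H", hh), 1L),
            c(ai("C", 1L), ai("CA", 1L), ai("N", 1L)), NH_BOND,
            NTERM_H_ANGLE, TORSION_CODES[["fixed"]], NTERM_H_TORSIONS[hh], 1L)
    } else {
      add(ai("H", i), c(ai("N", i), ai("C", i - 1L), ai("O", i - 1L)),
          NH_BOND, 0, 0L, 0, i, special = 4L)
    }
  }
  prog_i <- do.call(rbind, pi_)
  storage.mode(prog_i) <- "integer"
  prog_d <- do.call(rbind, pd_)
  list(atoms = atoms, prog_i = prog_i, prog_d = prog_d)
}
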