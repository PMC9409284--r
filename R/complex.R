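# Bridging annotated structures and the energy machinery: parameter lookup
# for protein atoms, side-chain connectivity, and receptor-ligand complexes.

.SIDE_CHAIN_BONDS <- list(
  ALA = list(c("CA", "CB")),
  GLY = list(),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  THR = list(c("CA", "CB"), c("CB", "OG1")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")))

# assign force-field types and charges to protein atoms via the residue table
.protein_params <- function(atoms, model) {
  key <- paste(atoms$resid, atoms$elety)
  rp <- model$residue_params
  m <- match(key, paste(rp$resid, rp$elety))
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("no residue parameters for atom '", atoms$elety[bad], "' of ",
         atoms$resid[bad], " ", atoms$resno[bad], call. = FALSE)
  }
  list(type = rp$type[m], charge = rp$charge[m])
}

# bonds within a structure: template side-chain bonds + CA-CA pseudo-bonds
# between consecutive residues (exclusion bookkeeping for the toy backbone)
.structure_bonds <- function(atoms) {
  out <- list()
  for (rn in unique(atoms$resno)) {
    idx <- which(atoms$resno == rn)
    resid <- atoms$resid[idx[1L]]
    tmpl <- .SIDE_CHAIN_BONDS[[resid]]
    if (is.null(tmpl)) next
    for (b in tmpl) {
      i <- idx[match(b[1L], atoms$elety[idx])]
      j <- idx[match(b[2L], atoms$elety[idx])]
      if (!is.na(i) && !is.na(j)) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  ca <- which(atoms$elety == "CA")
  ca <- ca[order(atoms$resno[ca])]
  if (length(ca) > 1L) {
    adj <- diff(atoms$resno[ca]) == 1L
    for (p in which(adj)) out[[length(out) + 1L]] <- c(ca[p], ca[p + 1L])
  }
  if (!length(out)) matrix(integer(), 0L, 2L) else do.call(rbind, out)
}

# chi-1 torsion blocks (rotation about CA-CB) for mobile side chains
.sidechain_dof <- function(atoms, resnos) {
  out <- list()
  for (rn in resnos) {
    idx <- which(atoms$resno == rn)
    ca <- idx[match("CA", atoms$elety[idx])]
    cb <- idx[match("CB", atoms$elety[idx])]
    tail <- setdiff(idx, c(ca, cb))
    if (is.na(ca) || is.na(cb) || !length(tail)) next
    out[[length(out) + 1L]] <- list(type = "torsion", a = ca, b = cb,
                                    moving = tail)
  }
  out
}

#' Build a receptor(-ligand) conformation from a channel structure
#'
#' Protein atoms are typed and charged through the packaged residue table;
#' hetero atoms are not supported here (dock ligands through a
#' `ligand_topology` instead).  Backbone is fixed; side chains of the
#' residues in `mobile_sidechains` get chi-1 torsion DOF.  A ligand, when
#' given, contributes a rigid-body block plus its rotatable torsions and is
#' tagged as unit `"ligand"`.
#'
#' @param structure A `channel_structure`.
#' @param model An `energy_model` (parameter source).
#' @param ligand Optional `ligand_topology`.
#' @param ligand_xyz Optional pose coordinates for the ligand (defaults to
#'   its reference coordinates).
#' @param mobile_sidechains Residue numbers whose side chains move (default
#'   none).
#' @param mobile_residues Residue numbers given per-residue rigid
#'   translation blocks (used by morphing; default none).
#' @return A [conformation()].
#' @export
build_complex <- function(structure, model = default_energy_model(),
                          ligand = NULL, ligand_xyz = NULL,
                          mobile_sidechains = integer(),
                          mobile_residues = integer()) {
  a <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  pp <- .protein_params(a, model)
  atoms <- data.frame(name = a$elety, element = a$elesy, type = pp$type,
                      charge = pp$charge, resno = a$resno, unit = "receptor",
                      stringsAsFactors = FALSE)
  xyz <- as.matrix(a[c("x", "y", "z")])
  bonds <- .structure_bonds(data.frame(resno = a$resno, resid = a$resid,
                                       elety = a$elety))
  dof <- .sidechain_dof(data.frame(resno = a$resno, elety = a$elety),
                        mobile_sidechains)
  for (rn in mobile_residues) {
    idx <- which(a$resno == rn)
    if (length(idx))
      dof[[length(dof) + 1L]] <- list(type = "rigid", atoms = idx,
                                      translate_only = TRUE)
  }
  tor_terms <- NULL; xb <- NULL
  if (!is.null(ligand)) {
    off <- nrow(atoms)
    lx <- if (is.null(ligand_xyz)) ligand$xyz else as.matrix(ligand_xyz)
    atoms <- rbind(atoms,
                   data.frame(name = ligand$atoms$name,
                              element = ligand$atoms$element,
                              type = ligand$atoms$type,
                              charge = ligand$atoms$charge,
                              resno = max(a$resno) + 1L, unit = "ligand",
                              stringsAsFactors = FALSE))
    xyz <- rbind(xyz, lx)
    bonds <- rbind(bonds, ligand$bonds + off)
    dof <- c(dof, list(list(type = "rigid", atoms = off + seq_len(nrow(lx)))),
             lapply(ligand$torsions, function(t)
               list(type = "torsion", a = t$a + off, b = t$b + off,
                    moving = t$moving + off)))
    tt <- ligand$tor_terms
    tt[c("i", "j", "k", "l")] <- tt[c("i", "j", "k", "l")] + off
    tor_terms <- tt
    if (nrow(ligand$xb_donors)) xb <- ligand$xb_donors + off
  }
  conformation(atoms, xyz, bonds = bonds, dof = dof, tor_terms = tor_terms,
               xb_donors = xb)
}

#' Pore axis of a channel structure
#'
#' Unit vector from the selectivity-filter region (centroid of the P-loop
#' turn C-alphas) to the activation gate (centroid of the deepest inner-helix
#' C-alphas), i.e. oriented extracellular to cytoplasmic.
#'
#' @param structure An annotated `channel_structure` with p and i segments.
#' @return List with `axis` (unit 3-vector) and `origin` (filter centroid).
#' @export
pore_axis <- function(structure) {
  p <- select_atoms(structure, atom_selection(segment = "p"))
  i <- select_atoms(structure, atom_selection(segment = "i"))
  if (!nrow(p) || !nrow(i))
    stop("pore axis needs annotated p and i segments", call. = FALSE)
  xyz <- coords(structure)
  turn <- p[p$index > max(p$index) - 3L, , drop = FALSE]  # re-entrant turn
  sf <- colMeans(xyz[turn$idx, , drop = FALSE])
  deep <- i[i$index > max(i$index) - 3L, , drop = FALSE]
  gate <- colMeans(xyz[deep$idx, , drop = FALSE])
  ax <- gate - sf
  list(axis = ax / sqrt(sum(ax^2)), origin = sf)
}
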