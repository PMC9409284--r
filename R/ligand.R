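#' Ligand topologies
#'
#' A ligand topology bundles heavy-atom records (name, element, force-field
#' type, partial charge), reference 3D coordinates, the bond list with
#' orders, the rotatable-bond degrees of freedom, torsion energy terms,
#' declared halogen-bond donors (C-X pairs), and symmetry-equivalent atom
#' permutations used for symmetry-corrected RMSD.
#'
#' @name ligand_topology
NULL

.new_ligand <- function(atoms, xyz, bonds, torsions, tor_terms, xb_donors,
                        symmetry, kind) {
  structure(list(atoms = atoms, xyz = as.matrix(xyz),
                 bonds = matrix(as.integer(bonds[, 1:2]), ncol = 2L),
                 orders = as.integer(bonds[, 3L]),
                 torsions = torsions, tor_terms = tor_terms,
                 xb_donors = matrix(as.integer(xb_donors), ncol = 2L),
                 symmetry = symmetry, kind = kind),
            class = "ligand_topology")
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat("<ligand_topology> '", x$kind, "': ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", length(x$torsions), " rotatable torsions\n",
      sep = "")
  invisible(x)
}

# hexagonal aromatic ring attached at `a1`, growing away from `from`
.aromatic_ring <- function(a1, from, rcc = 1.39) {
  dir <- (a1 - from) / sqrt(sum((a1 - from)^2))
  ctr <- a1 + rcc * dir
  e1 <- -dir
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * dir) * dir
  e2 <- e2 / sqrt(sum(e2^2))
  th <- (0:5) * pi / 3
  t(vapply(th, function(t) ctr + rcc * (cos(t) * e1 + sin(t) * e2),
           numeric(3)))
}

#' Build a toy pyrethroid-like ligand
#'
#' Two flavors mirroring the two pyrethroid classes: `"type1"` carries two
#' chlorine sigma-hole donors on a dihalovinyl group and no nitrile (a
#' permethrin-like Type I compound); `"type2"` carries two bromine donors
#' plus an alpha-carbon nitrile dipole (a deltamethrin-like Type II
#' compound).  Both share the ester core: a gem-dimethyl "acid" half with
#' the dihalovinyl arm, an ester bridge, and an "alcohol" half bearing an
#' aromatic ring.  Heavy atoms only (united-atom hydrogens); four rotatable
#' torsions; atoms typed for the packaged force field.
#'
#' @param kind `"type1"` or `"type2"`.
#' @return A `ligand_topology`.
#' @export
make_toy_ligand <- function(kind = c("type2", "type1")) {
  kind <- match.arg(kind)
  halogen <- if (kind == "type2") "Br" else "Cl"
  xtype <- if (kind == "type2") "BR" else "CL"
  cx <- if (kind == "type2") 1.90 else 1.77
  CF <- c(0, 0, 0)
  OE <- c(1.40, 0, 0)
  CC <- c(2.10, 1.16, 0)
  O1 <- c(1.55, 2.24, 0)
  C1 <- c(3.62, 1.25, 0)
  CM1 <- c(4.10, 2.05, 1.25)
  CM2 <- c(4.10, 2.05, -1.25)
  CV2 <- c(4.35, -0.10, 0)
  CV1 <- c(5.66, -0.25, 0)
  ux1 <- c(0.59, 0.81, 0); ux2 <- c(0.47, -0.88, 0)
  X1 <- CV1 + cx * ux1 / sqrt(sum(ux1^2))
  X2 <- CV1 + cx * ux2 / sqrt(sum(ux2^2))
  A1 <- c(-0.75, 1.20, -0.55)
  ring <- .aromatic_ring(A1, CF)
  xyz <- rbind(CF, OE, CC, O1, C1, CM1, CM2, CV2, CV1, X1, X2, ring)
  nm <- c("CF", "OE", "CC", "O1", "C1", "CM1", "CM2", "CV2", "CV1",
          "X1", "X2", paste0("A", 1:6))
  el <- c("C", "O", "C", "O", "C", "C", "C", "C", "C", halogen, halogen,
          rep("C", 6))
  ty <- c("CT", "OS", "CO", "OC", "CT", "CT", "CT", "CT", "CT", xtype, xtype,
          rep("CAr", 6))
  q <- c(0.15, -0.30, 0.45, -0.45, 0, 0, 0, 0, 0.20, -0.10, -0.10,
         0.15, 0, 0, 0, 0, 0)
  bonds <- rbind(
    c(1, 2, 1), c(2, 3, 1), c(3, 4, 2), c(3, 5, 1), c(5, 6, 1), c(5, 7, 1),
    c(5, 8, 1), c(8, 9, 2), c(9, 10, 1), c(9, 11, 1), c(1, 12, 1),
    c(12, 13, 2), c(13, 14, 1), c(14, 15, 2), c(15, 16, 1), c(16, 17, 2),
    c(17, 12, 1))
  if (kind == "type2") {
    CNC <- c(-0.45, -0.85, 1.20)
    NN <- CNC + 1.16 * (CNC - CF) / sqrt(sum((CNC - CF)^2))
    xyz <- rbind(xyz, CNC, NN)
    nm <- c(nm, "CNC", "NN"); el <- c(el, "C", "N"); ty <- c(ty, "CN", "NC")
    # a strongly polarized nitrile-like dipole (the Type II hallmark)
    q <- c(q, 0.32, -0.60)
    q[1] <- q[1] + 0.28  # alpha carbon compensates the nitrile dipole
    bonds <- rbind(bonds, c(1, 18, 1), c(18, 19, 3))
  }
  rownames(xyz) <- NULL
  atoms <- data.frame(name = nm, element = el, type = ty, charge = q,
                      formal = 0L, stringsAsFactors = FALSE)
  ringidx <- 12:17
  nit <- if (kind == "type2") c(18L, 19L) else integer()
  torsions <- list(
    list(a = 5L, b = 8L, moving = c(9L, 10L, 11L)),          # dihalovinyl arm
    list(a = 3L, b = 5L, moving = c(6L, 7L, 8L, 9L, 10L, 11L)),  # acid half
    list(a = 2L, b = 1L, moving = c(ringidx, nit)),          # ester to alcohol
    list(a = 1L, b = 12L, moving = 13:17))                   # ring spin
  tor_terms <- data.frame(
    i = c(9L, 8L, 3L, 2L), j = c(8L, 5L, 2L, 1L),
    k = c(5L, 3L, 1L, 12L), l = c(3L, 2L, 12L, 13L),
    n = c(3, 3, 3, 2), V = c(1.0, 1.0, 1.0, 1.0),
    gamma = c(0, 0, 0, 180))
  sym_ring <- seq_len(nrow(atoms)); sym_ring[c(13, 17)] <- c(17, 13)
  sym_ring[c(14, 16)] <- c(16, 14)
  sym_me <- seq_len(nrow(atoms)); sym_me[c(6, 7)] <- c(7, 6)
  sym_x <- seq_len(nrow(atoms)); sym_x[c(10, 11)] <- c(11, 10)
  .new_ligand(atoms, xyz, bonds, torsions, tor_terms,
              xb_donors = rbind(c(9L, 10L), c(9L, 11L)),
              symmetry = list(sym_ring, sym_me, sym_x), kind = kind)
}

#' Symmetry-corrected heavy-atom RMSD between two poses of one ligand
#'
#' @param ligand A `ligand_topology` (supplies symmetry permutations).
#' @param xyz_a,xyz_b Coordinate matrices for the same atom ordering.
#' @return Minimum RMSD (A) over all combinations of the declared
#'   symmetry-equivalent permutations, without refitting.
#' @export
ligand_rmsd <- function(ligand, xyz_a, xyz_b) {
  xyz_a <- as.matrix(xyz_a); xyz_b <- as.matrix(xyz_b)
  perms <- list(seq_len(nrow(xyz_a)))
  for (s in ligand$symmetry) {
    perms <- c(perms, lapply(perms, function(p) p[s]))
    perms <- unique(perms)
  }
  min(vapply(perms, function(p)
    sqrt(mean(rowSums((xyz_a[p, , drop = FALSE] - xyz_b)^2))), 0))
}

#' Write a ligand to SDF (V2000)
#'
#' Atom names, force-field types, partial charges and the ligand kind travel
#' in SDF data fields so the topology survives a round trip.
#'
#' @param ligand A `ligand_topology`.
#' @param path Output path.
#' @param xyz Optional coordinates to write instead of the reference ones.
#' @return `path`, invisibly.
#' @export
ligand_to_sdf <- function(ligand, path, xyz = NULL) {
  if (is.null(xyz)) xyz <- ligand$xyz
  n <- nrow(ligand$atoms)
  ab <- cbind(as.matrix(xyz), matrix(0, n, 1L))
  rownames(ab) <- paste(ligand$atoms$element, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", "C5")
  bb <- cbind(ligand$bonds, ligand$orders, matrix(0L, nrow(ligand$bonds), 4L))
  colnames(bb) <- paste0("C", 1:7)
  rownames(bb) <- as.character(seq_len(nrow(bb)))
  h <- c(Molecule_Name = ligand$kind, Source = "pyrenav", Comment = "",
         Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                               n, nrow(ligand$bonds)))
  db <- c(kind = ligand$kind,
          atom_names = paste(ligand$atoms$name, collapse = " "),
          atom_types = paste(ligand$atoms$type, collapse = " "),
          charges = paste(format(ligand$atoms$charge), collapse = " "),
          formal = paste(ligand$atoms$formal, collapse = " "))
  sdf <- methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                      header = h, atomblock = ab, bondblock = bb,
                      datablock = db)
  set <- methods::new(methods::getClass("SDFset",
                                        where = asNamespace("ChemmineR")),
                      SDF = list(sdf), ID = ligand$kind)
  ChemmineR::write.SDF(set, path)
  invisible(path)
}

#' Read a ligand from SDF
#'
#' Reconstructs a `ligand_topology` from an SDF written by [ligand_to_sdf()]
#' (data fields restore names/types/charges); plain SDFs get element-derived
#' names and default typing.
#'
#' @param path Path to an SDF file.
#' @return A `ligand_topology`.
#' @export
ligand_from_sdf <- function(path) {
  set <- ChemmineR::read.SDFset(path)
  sdf <- set[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  db <- ChemmineR::datablock(sdf)
  n <- nrow(ab)
  el <- sub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  kind <- if ("kind" %in% names(db)) unname(db[["kind"]]) else "custom"
  if (all(c("atom_names", "atom_types", "charges") %in% names(db))) {
    nm <- strsplit(db[["atom_names"]], " +")[[1]]
    ty <- strsplit(db[["atom_types"]], " +")[[1]]
    q <- as.numeric(strsplit(trimws(db[["charges"]]), " +")[[1]])
    fo <- if ("formal" %in% names(db))
      as.integer(strsplit(trimws(db[["formal"]]), " +")[[1]]) else rep(0L, n)
  } else {
    nm <- paste0(el, seq_len(n))
    ty <- ifelse(el == "O", "OS", ifelse(el == "N", "NC",
          ifelse(el == "Br", "BR", ifelse(el == "Cl", "CL", "CT"))))
    q <- rep(0, n); fo <- rep(0L, n)
  }
  atoms <- data.frame(name = nm, element = el, type = ty, charge = q,
                      formal = fo, stringsAsFactors = FALSE)
  bonds <- cbind(bb[, 1L], bb[, 2L], bb[, 3L])
  # halogen-bond donors: C-X bonds with X = Cl/Br/I
  xb <- matrix(integer(), 0L, 2L)
  for (p in seq_len(nrow(bonds))) {
    i <- bonds[p, 1L]; j <- bonds[p, 2L]
    if (el[j] %in% c("Cl", "Br", "I") && el[i] == "C") xb <- rbind(xb, c(i, j))
    if (el[i] %in% c("Cl", "Br", "I") && el[j] == "C") xb <- rbind(xb, c(j, i))
  }
  template <- if (kind %in% c("type1", "type2")) make_toy_ligand(kind) else NULL
  .new_ligand(atoms, xyz, bonds,
              torsions = if (is.null(template)) list() else template$torsions,
              tor_terms = if (is.null(template))
                data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), n = numeric(), V = numeric(),
                           gamma = numeric()) else template$tor_terms,
              xb_donors = xb,
              symmetry = if (is.null(template)) list() else template$symmetry,
              kind = kind)
}
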