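#' Conformations: molecular systems in generalized coordinates
#'
#' A conformation holds a Cartesian coordinate set together with its degrees
#' of freedom: rotations about declared rotatable bonds (torsions) and
#' rigid-body position/orientation of mobile units.  Bond lengths and bond
#' angles are fixed by construction — every move is a rigid rotation or
#' translation of a subset of atoms — except angles declared elastic, which
#' carry harmonic energy terms instead.  The Cartesian rebuild from a DOF
#' vector is deterministic: blocks are applied in declaration order to the
#' stored reference coordinates.
#'
#' @param atoms Data.frame with columns `name`, `element`, `type`, `charge`,
#'   `resno`, `unit` (e.g. `"receptor"`/`"ligand"`).
#' @param xyz n x 3 coordinate matrix.
#' @param bonds Integer matrix of bonded atom pairs (1-based), used to build
#'   the 1-2/1-3 nonbonded exclusion list.
#' @param dof List of DOF blocks: `list(type = "torsion", a, b, moving)` (all
#'   atoms in `moving` rotate about the a->b bond) or `list(type = "rigid",
#'   atoms)` (3 translations + 3 rotations about the unit centroid).
#' @param tor_terms Data.frame of torsion energy terms: `i, j, k, l, n, V,
#'   gamma` (periodicity, barrier kcal/mol, phase degrees).
#' @param angle_terms Data.frame of elastic angles: `i, j, k, theta0`
#'   (degrees), `k` (kcal/mol/rad^2).
#' @param xb_donors Integer matrix of halogen-bond donors, columns (C, X).
#' @return An object of class `conformation`.
#' @export
conformation <- function(atoms, xyz, bonds = NULL, dof = list(),
                         tor_terms = NULL, angle_terms = NULL,
                         xb_donors = NULL) {
  need <- c("name", "element", "type", "charge", "resno", "unit")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(atoms), ncol(xyz) == 3L)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (is.null(bonds)) bonds <- matrix(integer(), 0L, 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  empty_tor <- data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), n = numeric(), V = numeric(),
                          gamma = numeric())
  empty_ang <- data.frame(i = integer(), j = integer(), k = integer(),
                          theta0 = numeric(), kang = numeric())
  conf <- structure(list(
    atoms = as.data.frame(atoms), xyz = xyz, ref_xyz = xyz,
    bonds = bonds, excl = .exclusions(bonds, nrow(xyz)),
    dof = .init_dof(dof),
    tor_terms = if (is.null(tor_terms)) empty_tor else as.data.frame(tor_terms),
    angle_terms = if (is.null(angle_terms)) empty_ang else as.data.frame(angle_terms),
    xb_donors = if (is.null(xb_donors)) matrix(integer(), 0L, 2L)
                else matrix(as.integer(xb_donors), ncol = 2L)),
    class = "conformation")
  conf
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x$atoms), " atoms, ", length(x$dof),
      " DOF blocks (", n_dof(x), " scalars)\n", sep = "")
  invisible(x)
}

.init_dof <- function(dof) {
  lapply(dof, function(b) {
    if (!b$type %in% c("torsion", "rigid")) stop("unknown DOF type", call. = FALSE)
    if (b$type == "torsion") {
      b$moving <- as.integer(b$moving)
      b$value <- b$value %||% 0
    } else {
      b$atoms <- as.integer(b$atoms)
      b$value <- b$value %||% numeric(6)
    }
    b
  })
}

# 1-2 and 1-3 exclusion pairs from the bond list (1-4 interactions are kept)
.exclusions <- function(bonds, n) {
  if (!nrow(bonds)) return(matrix(integer(), 0L, 2L))
  adj <- vector("list", n)
  for (p in seq_len(nrow(bonds))) {
    i <- bonds[p, 1L]; j <- bonds[p, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list(bonds)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) > 1L) out[[length(out) + 1L]] <- t(utils::combn(nb, 2L))
  }
  ex <- unique(t(apply(do.call(rbind, out), 1L, sort)))
  matrix(as.integer(ex), ncol = 2L)
}

#' Number of scalar degrees of freedom
#' @param conf A `conformation`.
#' @return Integer count (torsions contribute 1, rigid units 6).
#' @export
n_dof <- function(conf) {
  sum(vapply(conf$dof, function(b) if (b$type == "torsion") 1L else 6L, 1L))
}

#' Current DOF vector
#' @param conf A `conformation`.
#' @return Numeric vector of torsion values (degrees) and rigid-body values
#'   (tx, ty, tz in A; rx, ry, rz in degrees, applied in that order).
#' @export
get_dof <- function(conf) {
  unlist(lapply(conf$dof, `[[`, "value"), use.names = FALSE)
}

.rotmat_axis <- function(u, deg) {
  th <- deg * pi / 180
  u <- u / sqrt(sum(u^2))
  ca <- cos(th); sa <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
               byrow = TRUE)
  ca * diag(3) + sa * ux + (1 - ca) * tcrossprod(u)
}

.rotate_subset <- function(xyz, idx, center, axis, deg) {
  R <- .rotmat_axis(axis, deg)
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2L, center) %*% t(R),
                      2L, -center)
  xyz
}

#' Rebuild Cartesian coordinates from a DOF vector
#'
#' Starts from the stored reference coordinates and applies each DOF block in
#' order: rigid blocks rotate about the unit centroid (x, then y, then z
#' axis) and translate; torsion blocks rotate their moving set about the
#' current bond axis.  The same DOF vector always yields the same
#' coordinates.
#'
#' @param conf A `conformation`.
#' @param values Numeric DOF vector as in [get_dof()].
#' @return The conformation with rebuilt coordinates and stored values.
#' @export
set_dof <- function(conf, values) {
  if (length(values) != n_dof(conf))
    stop("expected ", n_dof(conf), " DOF values", call. = FALSE)
  xyz <- conf$ref_xyz
  pos <- 1L
  for (bi in seq_along(conf$dof)) {
    b <- conf$dof[[bi]]
    if (b$type == "torsion") {
      v <- values[pos]; pos <- pos + 1L
      if (v != 0) {
        a <- xyz[b$a, ]; bb <- xyz[b$b, ]
        xyz <- .rotate_subset(xyz, b$moving, bb, bb - a, v)
      }
      conf$dof[[bi]]$value <- v
    } else {
      v <- values[pos:(pos + 5L)]; pos <- pos + 6L
      ctr <- colMeans(xyz[b$atoms, , drop = FALSE])
      for (ax in 1:3) if (v[3L + ax] != 0)
        xyz <- .rotate_subset(xyz, b$atoms, ctr, diag(3)[ax, ], v[3L + ax])
      xyz[b$atoms, ] <- sweep(xyz[b$atoms, , drop = FALSE], 2L, -v[1:3])
      conf$dof[[bi]]$value <- v
    }
  }
  conf$xyz <- xyz
  conf
}

# incremental scalar move on one DOF block; used by the minimizers.
# scalar index: torsion blocks have 1; rigid blocks 1:6 (tx,ty,tz,rx,ry,rz).
.apply_scalar <- function(conf, bi, si, delta) {
  b <- conf$dof[[bi]]
  if (b$type == "torsion") {
    a <- conf$xyz[b$a, ]; bb <- conf$xyz[b$b, ]
    conf$xyz <- .rotate_subset(conf$xyz, b$moving, bb, bb - a, delta)
    conf$dof[[bi]]$value <- b$value + delta
  } else if (si <= 3L) {
    conf$xyz[b$atoms, si] <- conf$xyz[b$atoms, si] + delta
    conf$dof[[bi]]$value[si] <- b$value[si] + delta
  } else {
    ctr <- colMeans(conf$xyz[b$atoms, , drop = FALSE])
    conf$xyz <- .rotate_subset(conf$xyz, b$atoms, ctr, diag(3)[si - 3L, ], delta)
    conf$dof[[bi]]$value[si] <- b$value[si] + delta
  }
  conf
}

# atoms whose nonbonded terms change under a scalar move of block bi
.block_atoms <- function(conf, bi) {
  b <- conf$dof[[bi]]
  if (b$type == "torsion") b$moving else b$atoms
}
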