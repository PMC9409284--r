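#' Reduced force-field parameter set
#'
#' A deliberately small united-atom energy model: 12-6 Lennard-Jones with
#' Lorentz-Berthelot combining, Coulomb electrostatics under the
#' distance-dependent dielectric eps(r) = 4r (a common implicit-membrane
#' surrogate), three-term cosine torsions, a 10-12 well for hydrogen bonds
#' between donor and acceptor heavy atoms (replacing their Lennard-Jones
#' term), an explicitly directional halogen-bond term for C-X...A sigma-hole
#' contacts (X in Cl/Br/I, A in S/O/N) so that bromine-sulfur contacts are
#' energetically favorable rather than merely detectable, harmonic bond-angle
#' terms reserved for declared elastic angles, and harmonic positional
#' restraints.  Parameters live in packaged TSV tables and are resolved per
#' atom type at energy evaluation, so the model is a named, swappable
#' component.
#'
#' @param cutoff Nonbonded cutoff in Angstrom (default 8, no switching).
#' @param kcoul Coulomb constant in kcal A / (mol e^2).
#' @param hb_r0,hb_depth 10-12 hydrogen-bond optimum distance (A) and depth
#'   (kcal/mol).
#' @param xb_depth,xb_angle_min,xb_pad Halogen-bond well depth (kcal/mol),
#'   minimum C-X...A angle (degrees), and the amount (A) subtracted from the
#'   van der Waals radius sum to place the well optimum.
#' @return An object of class `energy_model`.
#' @export
default_energy_model <- function(cutoff = 8, kcoul = 332.0637,
                                 hb_r0 = 2.9, hb_depth = 3.0,
                                 xb_depth = 3.5, xb_angle_min = 150,
                                 xb_pad = 0.25) {
  ext <- function(f) system.file("extdata", f, package = "pyrenav", mustWork = TRUE)
  types <- utils::read.delim(ext("forcefield_types.tsv"), stringsAsFactors = FALSE)
  vdw <- utils::read.delim(ext("vdw_radii.tsv"), stringsAsFactors = FALSE)
  resp <- utils::read.delim(ext("residue_params.tsv"), stringsAsFactors = FALSE)
  stopifnot(all(types$eps >= 0), all(types$sigma > 0), cutoff > 0)
  structure(list(types = types, vdw = vdw, residue_params = resp,
                 cutoff = cutoff, kcoul = kcoul, hb_r0 = hb_r0,
                 hb_depth = hb_depth, xb_depth = xb_depth,
                 xb_angle_min = xb_angle_min, xb_pad = xb_pad,
                 restraints = data.frame(atom = integer(), x = numeric(),
                                         y = numeric(), z = numeric(),
                                         k = numeric())),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> ", nrow(x$types), " atom types, cutoff ", x$cutoff,
      " A, ", nrow(x$restraints), " restraints\n", sep = "")
  invisible(x)
}

#' Add harmonic positional restraints to an energy model
#'
#' The restraint energy is `k * |x - x0|^2` per restrained atom (so an atom
#' 2 A from its target at k = 1 contributes 4 kcal/mol); `k = 0` reproduces
#' the unrestrained model exactly.  Restraints are the mechanism of the
#' targeted state transformations: morphing pulls selected C-alpha atoms
#' toward interpolated template positions.
#'
#' @param model An `energy_model`.
#' @param targets A matrix/data.frame of target coordinates with one row per
#'   restrained atom, plus a vector of atom indices in `atom` (or rownames).
#' @param atom Integer atom indices (1-based into the conformation).
#' @param k Force constant, kcal/mol/A^2 (scalar or per-atom).
#' @return The model with restraints appended.
#' @export
with_restraints <- function(model, targets, atom = NULL, k = 10) {
  stopifnot(inherits(model, "energy_model"))
  targets <- as.matrix(targets)
  if (is.null(atom)) atom <- as.integer(rownames(targets))
  atom <- as.integer(atom)
  if (any(is.na(atom)) || length(atom) != nrow(targets))
    stop("need one atom index per target row", call. = FALSE)
  if (any(k < 0)) stop("restraint force constant must be >= 0", call. = FALSE)
  add <- data.frame(atom = atom, x = targets[, 1L], y = targets[, 2L],
                    z = targets[, 3L], k = rep_len(k, length(atom)))
  model$restraints <- rbind(model$restraints, add)
  model
}

#' Drop all restraints from a model
#' @param model An `energy_model`.
#' @return The model without restraints.
#' @export
without_restraints <- function(model) {
  model$restraints <- model$restraints[0, , drop = FALSE]
  model
}

# resolve per-atom parameters against the model's type table
.resolve_params <- function(conf, model) {
  m <- match(conf$atoms$type, model$types$type)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("no force-field parameters for atom ", bad, " ('",
         conf$atoms$name[bad], "', type '", conf$atoms$type[bad], "')",
         call. = FALSE)
  }
  mv <- match(conf$atoms$element, model$vdw$element)
  rv <- model$vdw$radius[mv]
  rv[is.na(rv)] <- 1.7
  list(eps = model$types$eps[m], sig = model$types$sigma[m],
       hbd = model$types$hbd[m], hba = model$types$hba[m], rvdw = rv)
}
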