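#' Binding-site definition
#'
#' A named set of pocket-lining residues (universal labels) plus the axis-
#' aligned sampling box derived from their side-chain centroids: the box
#' center is the centroid mean and the half-extents cover all centroids plus
#' a margin.  `PyR1`/`PyR2` are the conventional names of the two pyrethroid
#' receptor sites (domain II/III and I/II interfaces).
#'
#' @param structure An annotated `channel_structure`.
#' @param residues Character vector of universal labels lining the site.
#' @param name Site name (`"PyR1"`, `"PyR2"` or custom).
#' @param margin Box margin beyond the centroid extents (A).
#' @return A `site_definition`.
#' @export
site_definition <- function(structure, residues, name = "custom", margin = 2) {
  if (!length(residues)) stop("residue set must be non-empty", call. = FALSE)
  labs <- assign_labels(structure, structure$annotation)
  rn <- labs$resno[match(residues, labs$label)]
  if (anyNA(rn))
    stop("labels not in structure: ",
         paste(residues[is.na(rn)], collapse = ", "), call. = FALSE)
  at <- structure$atoms
  xyz <- coords(structure)
  cent <- t(vapply(rn, function(r) {
    idx <- which(at$resno == r & at$elety != "CA")
    if (!length(idx)) idx <- which(at$resno == r)
    colMeans(xyz[idx, , drop = FALSE])
  }, numeric(3)))
  center <- colMeans(cent)
  half <- apply(abs(sweep(cent, 2L, center)), 2L, max) + margin
  structure(list(name = name, residues = residues, center = center,
                 half = half, resno = rn), class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("<site_definition> ", x$name, ": ", length(x$residues),
      " residues, box half-extents ", paste(round(x$half, 1), collapse = "/"),
      " A\n", sep = "")
  invisible(x)
}

#' Docking configuration
#'
#' @param n_starts Number of random starting poses (the reference protocol
#'   uses 2000).
#' @param window Energy window above the apparent global minimum for
#'   ensemble filtering, kcal/mol (default 5).
#' @param cutoff Contact cutoff for pose selection, A (default 4).
#' @param seed Integer seed; all pose generation and refinement noise runs
#'   under it.
#' @param n_sweeps,n_mc Line-search sweeps and Monte Carlo restarts per pose
#'   during refinement.
#' @param trans_mag,rot_deg,tor_deg Refinement move magnitudes (A, degrees,
#'   degrees).
#' @return A `docking_config`.
#' @export
docking_config <- function(n_starts = 2000L, window = 5, cutoff = 4,
                           seed = 1L, n_sweeps = 5L, n_mc = 3L,
                           trans_mag = 1.2, rot_deg = 50, tor_deg = 70,
                           deep_top = 30L) {
  stopifnot(n_starts >= 0, window >= 0, cutoff > 0)
  structure(list(n_starts = as.integer(n_starts), window = window,
                 cutoff = cutoff, seed = seed, n_sweeps = as.integer(n_sweeps),
                 n_mc = as.integer(n_mc), trans_mag = trans_mag,
                 rot_deg = rot_deg, tor_deg = tor_deg,
                 deep_top = as.integer(deep_top)),
            class = "docking_config")
}

#' Pose ensembles
#'
#' An ordered collection of ligand placements with (after refinement) their
#' ligand-channel interaction energies, sorted ascending so the "apparent
#' global energy minimum" — the best energy found, with no claim of a
#' converged global optimum — is first.
#'
#' @param ligand A `ligand_topology`.
#' @param xyz List of pose coordinate matrices.
#' @param energy Interaction energies (kcal/mol; `NA` before refinement).
#' @return A `pose_ensemble`.
#' @export
pose_ensemble <- function(ligand, xyz, energy = rep(NA_real_, length(xyz))) {
  stopifnot(length(xyz) == length(energy))
  if (any(!is.na(energy))) {
    o <- order(energy)
    xyz <- xyz[o]; energy <- energy[o]
  }
  structure(list(ligand = ligand, xyz = xyz, energy = energy),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat("<pose_ensemble> ", length(x$xyz), " poses",
      if (any(!is.na(x$energy)))
        paste0(", best E_int ", round(min(x$energy), 2), " kcal/mol"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.pose_ensemble <- function(x) length(x$xyz)

# uniform random rotation (Shoemake quaternion method)
.random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# apply torsion values (degrees) to ligand reference coordinates
.ligand_with_torsions <- function(ligand, tor_values) {
  xyz <- ligand$xyz
  for (t in seq_along(ligand$torsions)) {
    tt <- ligand$torsions[[t]]
    v <- tor_values[t]
    if (v != 0)
      xyz <- .rotate_subset(xyz, tt$moving, xyz[tt$b, ],
                            xyz[tt$b, ] - xyz[tt$a, ], v)
  }
  xyz
}

#' Generate random starting poses in a site box
#'
#' Each pose gets a uniformly random ligand-centroid position inside the
#' box, a uniformly random orientation, and uniformly random rotatable
#' torsions.  Deterministic for a given seed.
#'
#' @param ligand A `ligand_topology`.
#' @param site A `site_definition`.
#' @param config A `docking_config`.
#' @return An unrefined `pose_ensemble` with exactly `n_starts` poses.
#' @export
random_start_poses <- function(ligand, site, config = docking_config()) {
  if (any(site$half <= 0)) stop("site box must have positive volume", call. = FALSE)
  span <- max(dist(ligand$xyz))
  if (span > 2 * sqrt(sum(site$half^2)))
    warning("ligand is larger than the site box diameter")
  poses <- .with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(i) {
      tv <- stats::runif(length(ligand$torsions), -180, 180)
      xyz <- .ligand_with_torsions(ligand, tv)
      xyz <- sweep(xyz, 2L, colMeans(xyz)) %*% t(.random_rotation())
      ctr <- site$center + stats::runif(3, -1, 1) * site$half
      sweep(xyz, 2L, -ctr)
    })
  })
  pose_ensemble(ligand, poses)
}

# receptor force-field arrays trimmed to a neighborhood of the site
.receptor_ff <- function(structure, model, center, radius) {
  a <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  pp <- .protein_params(a, model)
  xyz <- as.matrix(a[c("x", "y", "z")])
  keep <- sqrt(colSums((t(xyz) - center)^2)) <= radius
  ty <- match(pp$type[keep], model$types$type)
  if (anyNA(ty)) stop("untyped receptor atom near site", call. = FALSE)
  mv <- match(a$elesy[keep], model$vdw$element)
  rv <- model$vdw$radius[mv]; rv[is.na(rv)] <- 1.7
  list(xyz = xyz[keep, , drop = FALSE], eps = model$types$eps[ty],
       sig = model$types$sigma[ty], q = pp$charge[keep],
       hbd = model$types$hbd[ty], hba = model$types$hba[ty],
       racc = model$types$hba[ty], rvdw = rv,
       resno = a$resno[keep], elety = a$elety[keep])
}

# ligand force-field arrays
.ligand_ff <- function(ligand, model) {
  ty <- match(ligand$atoms$type, model$types$type)
  if (anyNA(ty))
    stop("no parameters for ligand atom '",
         ligand$atoms$name[which(is.na(ty))[1L]], "'", call. = FALSE)
  mv <- match(ligand$atoms$element, model$vdw$element)
  rv <- model$vdw$radius[mv]; rv[is.na(rv)] <- 1.7
  n <- nrow(ligand$atoms)
  conf <- conformation(
    data.frame(name = ligand$atoms$name, element = ligand$atoms$element,
               type = ligand$atoms$type, charge = ligand$atoms$charge,
               resno = 1L, unit = "ligand"),
    ligand$xyz, bonds = ligand$bonds)
  list(eps = model$types$eps[ty], sig = model$types$sigma[ty],
       q = ligand$atoms$charge, hbd = model$types$hbd[ty],
       hba = model$types$hba[ty], rvdw = rv, excl = conf$excl,
       tor = as.matrix(ligand$tor_terms[c("i", "j", "k", "l")]),
       tor_n = ligand$tor_terms$n, tor_V = ligand$tor_terms$V,
       tor_g = ligand$tor_terms$gamma * pi / 180, xb = ligand$xb_donors)
}

# refine one pose against a precomputed receptor neighborhood, trimmed to
# the pose's own vicinity (beyond cutoff + move range nothing contributes)
.refine_one <- function(ligand, lff, rff, pose_xyz, model, config) {
  ctr <- colMeans(pose_xyz)
  span <- max(sqrt(rowSums(sweep(as.matrix(pose_xyz), 2L, ctr)^2)))
  keep <- sqrt(colSums((t(rff$xyz) - ctr)^2)) <=
    span + model$cutoff + 3 * config$trans_mag
  if (any(keep) && sum(keep) < length(keep))
    rff <- list(xyz = rff$xyz[keep, , drop = FALSE], eps = rff$eps[keep],
                sig = rff$sig[keep], q = rff$q[keep], hbd = rff$hbd[keep],
                hba = rff$hba[keep], racc = rff$racc[keep],
                rvdw = rff$rvdw[keep])
  tor_a <- vapply(ligand$torsions, `[[`, 1L, "a")
  tor_b <- vapply(ligand$torsions, `[[`, 1L, "b")
  tor_m <- lapply(ligand$torsions, `[[`, "moving")
  cpp_refine_pose(as.matrix(pose_xyz), tor_a, tor_b, tor_m,
                  lff$eps, lff$sig, lff$q, lff$hbd, lff$hba, lff$excl,
                  lff$tor, lff$tor_n, lff$tor_V, lff$tor_g, lff$xb, lff$rvdw,
                  rff$xyz, rff$eps, rff$sig, rff$q, rff$hbd, rff$hba,
                  rff$racc, rff$rvdw,
                  model$cutoff, model$kcoul, model$hb_r0, model$hb_depth,
                  model$xb_depth, cos(model$xb_angle_min * pi / 180),
                  model$xb_pad,
                  config$n_sweeps, config$n_mc, config$trans_mag,
                  config$rot_deg * pi / 180, config$tor_deg * pi / 180)
}

#' Refine a pose ensemble by Monte Carlo minimization
#'
#' Each starting pose is relaxed by cyclic line searches over its rigid-body
#' and torsion coordinates with a small greedy Monte Carlo restart loop (the
#' receptor is held fixed).  The pose reported for each start is the visited
#' candidate with the lowest ligand-channel interaction energy, so
#' refinement never increases a pose's interaction energy.  The ensemble is
#' re-sorted by interaction energy.
#'
#' @param ensemble A `pose_ensemble`.
#' @param receptor A `channel_structure`.
#' @param model An `energy_model`.
#' @param config A `docking_config`.
#' @param site Optional `site_definition` used to trim the receptor to a
#'   neighborhood (otherwise inferred from the pose cloud).
#' @return The refined, sorted `pose_ensemble`.
#' @export
refine_poses <- function(ensemble, receptor, model = default_energy_model(),
                         config = docking_config(), site = NULL) {
  if (!length(ensemble$xyz)) return(ensemble)
  ligand <- ensemble$ligand
  ctr <- if (!is.null(site)) site$center
         else colMeans(do.call(rbind, lapply(ensemble$xyz, colMeans)))
  rad <- if (!is.null(site)) sqrt(sum(site$half^2)) else
    max(vapply(ensemble$xyz, function(x) max(sqrt(colSums((t(x) - ctr)^2))),
               0))
  spread <- max(dist(ligand$xyz))
  rff <- .receptor_ff(receptor, model, ctr, rad + spread + model$cutoff)
  lff <- .ligand_ff(ligand, model)
  # rescoring frame: the reported ensemble energies are true interaction
  # energies E(complex) - E(receptor) - E(ligand); the refiner's internal
  # cross-term score is a fast surrogate used only to steer the search
  conf0 <- build_complex(receptor, model, ligand = ligand)
  lig_idx <- which(conf0$atoms$unit == "ligand")
  rescore <- function(xyz) {
    conf0$xyz[lig_idx, ] <- xyz
    interaction_energy(conf0, model)
  }
  out <- .with_seed(config$seed, {
    # every pose is MC-minimized; the low-energy subset is then run to
    # convergence so the apparent global minimum is a true local minimum
    coarse <- lapply(ensemble$xyz, function(x)
      .refine_one(ligand, lff, rff, x, model, config))
    e <- vapply(coarse, `[[`, 0, "e_int")
    deep <- utils::head(order(e), max(0L, config$deep_top))
    for (i in deep) {
      for (round in 1:2) {
        kick <- .refine_one(ligand, lff, rff, coarse[[i]]$xyz, model, config)
        conv <- .relax_until(ligand, lff, rff, kick$xyz, model,
                             max_iter = 15L)
        if (conv$e_int < coarse[[i]]$e_int) coarse[[i]] <- conv
      }
      # systematic 180-degree flips about the inertia axes: elongated
      # ligands have near-degenerate flipped families, and each family's
      # bottom is only reachable from the right side
      ctr <- colMeans(coarse[[i]]$xyz)
      cen <- sweep(coarse[[i]]$xyz, 2L, ctr)
      pax <- eigen(crossprod(cen), symmetric = TRUE)$vectors
      for (axi in 1:3) {
        flip <- sweep(cen %*% t(.rotmat_axis(pax[, axi], 180)), 2L, -ctr)
        fc <- .relax_until(ligand, lff, rff, flip, model, max_iter = 10L)
        if (fc$e_int < coarse[[i]]$e_int) coarse[[i]] <- fc
      }
    }
    coarse
  })
  # report each start's better candidate (start included) under the true
  # interaction energy, so refinement never raises a pose's energy
  final_xyz <- vector("list", length(out))
  final_e <- numeric(length(out))
  for (i in seq_along(out)) {
    e_ref <- rescore(out[[i]]$xyz)
    e_sta <- rescore(as.matrix(ensemble$xyz[[i]]))
    if (e_ref <= e_sta) {
      final_xyz[[i]] <- out[[i]]$xyz; final_e[i] <- e_ref
    } else {
      final_xyz[[i]] <- as.matrix(ensemble$xyz[[i]]); final_e[i] <- e_sta
    }
  }
  pose_ensemble(ligand, final_xyz, final_e)
}

#' Energy-window ensemble filtering
#'
#' Keeps exactly the poses whose interaction energy is within `window`
#' kcal/mol above the ensemble minimum (boundary inclusive).  The minimum is
#' the apparent global minimum: the best energy in the ensemble.
#'
#' @param ensemble A refined `pose_ensemble`.
#' @param window Energy window, kcal/mol.
#' @return The filtered ensemble.
#' @export
filter_window <- function(ensemble, window = 5) {
  if (!length(ensemble$xyz)) return(ensemble)
  if (anyNA(ensemble$energy))
    stop("ensemble must be refined before filtering", call. = FALSE)
  keep <- ensemble$energy <= min(ensemble$energy) + window
  pose_ensemble(ensemble$ligand, ensemble$xyz[keep], ensemble$energy[keep])
}

#' Select the pose maximizing contacts with known sensing residues
#'
#' Counts, for every pose, the sensing residues with a side-chain heavy atom
#' within `cutoff` of any ligand heavy atom, and returns the pose with the
#' maximal count; ties break by lower interaction energy, then by ensemble
#' order.
#'
#' @param ensemble A refined `pose_ensemble`.
#' @param sensing Character vector of universal labels of experimentally
#'   known sensing residues (may be empty: then the lowest-energy pose wins).
#' @param receptor An annotated `channel_structure`.
#' @param cutoff Contact cutoff in A (default 4).
#' @return List with `pose` (coordinates), `index`, `contacts` (count),
#'   `contact_labels`, `energy`.
#' @export
select_by_sensing_contacts <- function(ensemble, sensing, receptor,
                                       cutoff = 4) {
  if (!length(ensemble$xyz)) stop("empty pose ensemble", call. = FALSE)
  counts <- integer(length(ensemble$xyz))
  labsets <- vector("list", length(ensemble$xyz))
  for (i in seq_along(ensemble$xyz)) {
    cc <- ligand_contacts(receptor, ensemble$xyz[[i]],
                          ligand = ensemble$ligand, cutoff = cutoff)
    hit <- intersect(sensing, cc$label)
    counts[i] <- length(hit)
    labsets[[i]] <- hit
  }
  e <- ifelse(is.na(ensemble$energy), Inf, ensemble$energy)
  best <- order(-counts, e, seq_along(counts))[1L]
  list(pose = ensemble$xyz[[best]], index = best, contacts = counts[best],
       contact_labels = labsets[[best]], energy = ensemble$energy[best])
}

#' Orientation flag of a pose relative to the pore axis
#'
#' Sign of the projection of the ligand's ester axis (the vector from the
#' alcohol-side alpha carbon to the acid-side quaternary carbon) onto the
#' pore axis; the two opposite binding orientations the multi-start protocol
#' finds map to opposite signs.
#'
#' @param ligand A `ligand_topology` (toy ligands: atoms `CF` and `C1`).
#' @param xyz Pose coordinates.
#' @param axis Pore axis unit vector (e.g. from [pore_axis()]).
#' @return `+1` or `-1`.
#' @export
pose_orientation <- function(ligand, xyz, axis) {
  i <- match("CF", ligand$atoms$name); j <- match("C1", ligand$atoms$name)
  if (is.na(i) || is.na(j)) return(NA_integer_)
  as.integer(sign(sum((xyz[j, ] - xyz[i, ]) * axis)))
}

#' Full multi-start docking protocol
#'
#' Random starting poses in the site box, per-pose Monte Carlo minimization,
#' energy-window filtering, and contact-driven selection — the desk-scale
#' version of the multi-start pyrethroid docking protocol.
#'
#' @param receptor An annotated `channel_structure`.
#' @param ligand A `ligand_topology`.
#' @param site A `site_definition`.
#' @param sensing Universal labels of known sensing residues used for pose
#'   selection (defaults to the site's residue list).
#' @param model An `energy_model`.
#' @param config A `docking_config`.
#' @return List with `ensemble` (refined), `filtered` (within the window),
#'   `selected` (see [select_by_sensing_contacts()]) and `orientation` per
#'   filtered pose.
#' @export
dock_ligand <- function(receptor, ligand, site, sensing = site$residues,
                        model = default_energy_model(),
                        config = docking_config()) {
  starts <- random_start_poses(ligand, site, config)
  refined <- refine_poses(starts, receptor, model, config, site = site)
  filtered <- filter_window(refined, config$window)
  selected <- select_by_sensing_contacts(filtered, sensing, receptor,
                                         config$cutoff)
  ax <- tryCatch(pore_axis(receptor)$axis, error = function(e) c(0, 0, -1))
  ori <- vapply(filtered$xyz, function(x)
    pose_orientation(ligand, x, ax), integer(1))
  list(ensemble = refined, filtered = filtered, selected = selected,
       orientation = ori)
}
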