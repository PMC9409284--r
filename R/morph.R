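#' Morph schedule
#'
#' @param n_steps Number of interpolation steps (>= 1).
#' @param k Restraint force constant, kcal/mol/A^2 (used when the backbone
#'   is relaxed under restraints rather than pinned).
#' @param tolerance Convergence tolerance: final selected-C-alpha RMSD to
#'   the target, A.
#' @param relax_backbone `FALSE` (default): restrained C-alpha atoms are
#'   pinned exactly at the interpolated targets each step (their residues
#'   translate rigidly) and only side chains relax — the fixed-backbone
#'   convention.  `TRUE`: per-residue rigid translations are minimized under
#'   harmonic restraints of constant `k` instead.
#' @param relax_sidechains Relax side-chain chi torsions of the moved
#'   residues each step.
#' @param max_sweeps Line-search sweeps per step for the relaxation.
#' @return A `morph_schedule`.
#' @export
morph_schedule <- function(n_steps = 10L, k = 10, tolerance = 0.5,
                           relax_backbone = FALSE, relax_sidechains = TRUE,
                           max_sweeps = 3L) {
  stopifnot(n_steps >= 1L, k > 0, tolerance > 0)
  structure(list(n_steps = as.integer(n_steps), k = k,
                 tolerance = tolerance, relax_backbone = relax_backbone,
                 relax_sidechains = relax_sidechains,
                 max_sweeps = as.integer(max_sweeps)),
            class = "morph_schedule")
}

#' Build morph targets from a template structure
#'
#' Pairs the selected atoms of the source with the template (by universal
#' label + atom name) and returns the template coordinates as targets.
#' Superpose the template onto the source first (e.g. on `"p1-ca"`) —
#' targets are taken in the source frame.
#'
#' @param source,template `channel_structure` objects (template already
#'   superposed onto source).
#' @param selection An `atom_selection` or shorthand (default `"pm-ca"`).
#' @return A `morph_targets` list: `atom` (row indices into the source atom
#'   table), `xyz` (target coordinates), `key` (pairing keys).
#' @export
build_targets <- function(source, template, selection = "pm-ca") {
  pr <- pair_selection(source, template, selection)
  structure(list(atom = pr$idx_a,
                 xyz = coords(template)[pr$idx_b, , drop = FALSE],
                 key = pr$key),
            class = "morph_targets")
}

# soft-restrained auxiliary set (used by deactivate_vsm for the linker
# N-ends that follow the voltage sensor at k/10)
.morph_state <- function(structure, targets) {
  list(start = coords(structure)[targets$atom, , drop = FALSE],
       target = targets$xyz)
}

#' Targeted stepwise transformation toward template positions
#'
#' At step t of n the restrained C-alpha atoms are driven to the linear
#' interpolation `start + (t/n) (target - start)`; their residues move
#' rigidly and the energy is relaxed at each step (side chains, and any
#' ligands, which are refined and scored at every step).  With
#' `relax_backbone = TRUE` the C-alphas are pulled by harmonic restraints of
#' constant `k` instead of being pinned.  Non-convergence (final
#' selected-C-alpha RMSD above the tolerance) is flagged, never silent.
#'
#' @param structure An annotated `channel_structure`.
#' @param targets A `morph_targets` from [build_targets()].
#' @param schedule A [morph_schedule()].
#' @param model An `energy_model`.
#' @param ligands Optional list of `list(ligand = <ligand_topology>, xyz =
#'   <pose>)` carried along and refined at every step.
#' @param soft Optional secondary target set (`morph_targets`) restrained at
#'   `k/10` and relaxed rather than pinned.
#' @return A `morph_trajectory`: `structures` (length `n_steps + 1`,
#'   including the start), `rmsd_to_target`, `energy`, `ligand_energy`
#'   (interaction energies per step, if ligands), `ligands` (final poses),
#'   `converged`.
#' @export
morph <- function(structure, targets, schedule = morph_schedule(),
                  model = default_energy_model(), ligands = NULL,
                  soft = NULL) {
  stopifnot(inherits(targets, "morph_targets"),
            inherits(schedule, "morph_schedule"))
  if (!length(targets$atom)) stop("no morph targets", call. = FALSE)
  at <- structure$atoms
  n <- schedule$n_steps
  start <- coords(structure)[targets$atom, , drop = FALSE]
  full_rmsd <- function(s) {
    cur <- coords(s)[targets$atom, , drop = FALSE]
    sqrt(mean(rowSums((cur - targets$xyz)^2)))
  }
  # residues whose anchors actually move; relaxation accompanies motion, so
  # a null morph (targets = current coordinates) is an exact identity
  displaced <- sqrt(rowSums((targets$xyz - start)^2)) > 1e-9
  moved_resno <- unique(at$resno[targets$atom[displaced]])
  lig_e <- if (!is.null(ligands)) matrix(NA_real_, n + 1L, length(ligands))
  structures <- vector("list", n + 1L)
  rmsd <- numeric(n + 1L)
  etot <- numeric(n + 1L)
  cur <- structure
  lig_xyz <- lapply(ligands, `[[`, "xyz")
  score_step <- function(s, step_i) {
    if (is.null(ligands)) return(invisible())
    for (li in seq_along(ligands)) {
      lg <- ligands[[li]]$ligand
      rff <- .receptor_ff(s, model, colMeans(lig_xyz[[li]]), 18)
      lff <- .ligand_ff(lg, model)
      r <- .relax_until(lg, lff, rff, lig_xyz[[li]], model, max_iter = 6L)
      lig_xyz[[li]] <<- r$xyz
      lig_e[step_i, li] <<- r$e_int
    }
  }
  total_energy <- function(s, rst_model) {
    conf <- build_complex(s, model)
    energy(conf, rst_model)[["total"]]
  }
  structures[[1L]] <- cur
  rmsd[1L] <- full_rmsd(cur)
  etot[1L] <- total_energy(cur, model)
  score_step(cur, 1L)
  for (t in seq_len(n)) {
    goal <- start + (t / n) * (targets$xyz - start)
    xyz <- coords(cur)
    if (!schedule$relax_backbone) {
      # pin: rigid translation of each restrained residue so its C-alpha
      # sits exactly at the interpolated target
      for (ri in which(displaced)) {
        shift <- goal[ri, ] - xyz[targets$atom[ri], ]
        ridx <- which(at$resno == at$resno[targets$atom[ri]])
        xyz[ridx, ] <- sweep(xyz[ridx, , drop = FALSE], 2L, -shift)
      }
      cur <- set_coords(cur, xyz)
    }
    rst <- with_restraints(model, goal, atom = targets$atom, k = schedule$k)
    if (!is.null(soft)) {
      sgoal <- .morph_state(structure, soft)
      sg <- sgoal$start + (t / n) * (sgoal$target - sgoal$start)
      rst <- with_restraints(rst, sg, atom = soft$atom, k = schedule$k / 10)
    }
    mobile_rigid <- integer()
    if (schedule$relax_backbone) mobile_rigid <- moved_resno
    if (!is.null(soft)) mobile_rigid <- union(mobile_rigid,
                                              unique(at$resno[soft$atom]))
    if ((schedule$relax_sidechains && length(moved_resno)) ||
        length(mobile_rigid)) {
      conf <- build_complex(cur, model,
                            mobile_sidechains = if (schedule$relax_sidechains)
                              moved_resno else integer(),
                            mobile_residues = mobile_rigid)
      res <- local_minimize(conf, rst, tol = 1e-3,
                            max_sweeps = schedule$max_sweeps,
                            trans_window = 0.6, tor_window = 40)
      if (!is.finite(res$energy))
        stop("non-finite energy at morph step ", t, call. = FALSE)
      cur <- set_coords(cur, res$conformation$xyz)
    }
    structures[[t + 1L]] <- cur
    rmsd[t + 1L] <- full_rmsd(cur)
    etot[t + 1L] <- total_energy(cur, rst)
    score_step(cur, t + 1L)
  }
  converged <- rmsd[n + 1L] <= schedule$tolerance
  if (!converged)
    warning("morph did not converge: final RMSD ",
            round(rmsd[n + 1L], 3), " A > tolerance ", schedule$tolerance,
            " A", call. = FALSE)
  structure(list(structures = structures, rmsd_to_target = rmsd,
                 energy = etot, ligand_energy = lig_e,
                 ligands = if (!is.null(ligands))
                   Map(function(l, x) list(ligand = l$ligand, xyz = x),
                       ligands, lig_xyz),
                 converged = converged, schedule = schedule),
            class = "morph_trajectory")
}

#' @export
print.morph_trajectory <- function(x, ...) {
  cat("<morph_trajectory> ", length(x$structures), " frames, final RMSD ",
      round(x$rmsd_to_target[length(x$rmsd_to_target)], 3), " A",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Deactivate a voltage-sensing module in silico
#'
#' Shifts the S4 C-alpha atoms of one domain stepwise in the cytoplasmic
#' direction (along the pore axis) by `displacement`, MC-relaxing at every
#' step; the N-terminal end of that domain's S4-S5 linker helix is
#' soft-restrained (at `k/10`) toward a correspondingly shifted position so
#' it can follow the sensor down.
#'
#' @param structure An annotated `channel_structure` whose annotation
#'   includes an `s` (S4) segment for `domain`.
#' @param domain Domain number 1-4.
#' @param displacement Cytoplasmic displacement in A (default 4.5).
#' @param schedule A [morph_schedule()].
#' @param model An `energy_model`.
#' @param ligands Optional ligand poses carried along (see [morph()]).
#' @return A `morph_trajectory`; the final structure is tagged
#'   `open_pm_deactivated_vsm`.
#' @export
deactivate_vsm <- function(structure, domain, displacement = 4.5,
                           schedule = morph_schedule(),
                           model = default_energy_model(), ligands = NULL) {
  domain <- as.integer(domain)
  if (!domain %in% 1:4) stop("domain must be 1-4", call. = FALSE)
  ann <- structure$annotation
  if (is.null(ann) || !any(ann$segment == "s" & ann$domain == domain))
    stop("domain ", domain, " has no annotated S4 segment", call. = FALSE)
  ax <- pore_axis(structure)$axis  # extracellular -> cytoplasmic
  at <- structure$atoms
  labs <- assign_labels(structure, ann)
  s4_res <- labs$resno[labs$domain == domain & labs$segment == "s"]
  s4_ca <- which(at$resno %in% s4_res & at$elety == "CA")
  xyz <- coords(structure)
  targets <- structure(list(
    atom = s4_ca,
    xyz = sweep(xyz[s4_ca, , drop = FALSE], 2L, -displacement * ax),
    key = paste0("s4-", at$resno[s4_ca])), class = "morph_targets")
  k_res <- sort(labs$resno[labs$domain == domain & labs$segment == "k"])
  soft <- NULL
  if (length(k_res)) {
    kn <- utils::head(k_res, 3L)  # N-end of the linker helix
    kidx <- which(at$resno %in% kn & at$elety == "CA")
    soft <- structure(list(
      atom = kidx,
      xyz = sweep(xyz[kidx, , drop = FALSE], 2L, -displacement * ax),
      key = paste0("k-", at$resno[kidx])), class = "morph_targets")
  }
  out <- if (displacement == 0) {
    morph(structure, targets, schedule, model, ligands = ligands)
  } else {
    morph(structure, targets, schedule, model, ligands = ligands,
          soft = soft)
  }
  last <- length(out$structures)
  out$structures[[last]]$state <- "open_pm_deactivated_vsm"
  out
}
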